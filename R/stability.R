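# Temporal stability and asynchrony partition across species and subplots.
#
# Stability at any scale is the temporal mean of a quantity divided by its
# temporal standard deviation. Writing m_ik and w_ij,kl for the temporal
# mean of species i's cover in subplot k and the covariance between the
# cover series of (i,k) and (j,l), and mu_k, v_kl for the analogous moments
# of subplot biomass, the five statistics are
#
#   species stability    = sum_ik m_ik / sum_ik sqrt(w_ii,kk)
#   species asynchrony   = sum_ik sqrt(w_ii,kk) / sum_k sqrt(sum_ij w_ij,kk)
#   alpha stability      = sum_k mu_k / sum_k sqrt(v_kk)
#   spatial asynchrony   = sum_k sqrt(v_kk) / sqrt(sum_kl v_kl)
#   gamma stability      = sum_k mu_k / sqrt(sum_kl v_kl)
#
# The species-asynchrony denominator sums, within each subplot, the full
# covariance matrix of that subplot's species covers -- i.e. the variance of
# the subplot's summed cover. This reading makes the partition multiplicative:
# species stability x species asynchrony = cover-based alpha stability, and
# alpha stability x spatial asynchrony = gamma stability, exactly. Species-
# level statistics use cover; community-level statistics use biomass.
# Both asynchrony indices are >= 1 (Cauchy-Schwarz), with equality under
# perfect synchrony.

#' Residuals of a linear time trend
#'
#' Detrended stability replaces raw temporal standard deviations with the
#' residual standard deviations of per-series ordinary least squares
#' regressions of value on year index.
#'
#' @param series numeric vector over years (>= 3 time points).
#' @return residual vector (mean zero).
#' @export
detrend_series <- function(series) {
  n <- length(series)
  if (n < 3) stop("insufficient data: detrending needs >= 3 time points")
  t <- seq_len(n)
  as.numeric(stats::lm.fit(cbind(1, t), series)$residuals)
}

#' Temporal means and covariances of a community tensor
#'
#' Computes the species-level moments (mean cover `m` per species-subplot
#' series; covariance matrix `w` across all species-subplot series) and the
#' community-level moments (mean biomass `mu` per subplot; covariance
#' matrix `v` across subplot biomass series). Sample covariances use
#' denominator n-1. With `detrend = TRUE`, `w` and `v` are computed from
#' per-series linear-trend residuals while `m` and `mu` stay raw means.
#'
#' @param tensor a [community_tensor()].
#' @param detrend logical.
#' @return object of class `temporal_moments` with elements `m` (length
#'   S*K, species fastest), `w` (SK x SK), `mu` (length K), `v` (K x K),
#'   `n_years`, `n_species`, `n_subplots`, `detrended`.
#' @export
temporal_moments <- function(tensor, detrend = FALSE) {
  stopifnot(inherits(tensor, "community_tensor"))
  S <- length(tensor$species); K <- tensor$n_subplots
  T_ <- tensor$duration_years
  if (T_ < 2) stop("need at least 2 years for temporal moments")
  # T x (S*K) matrix, species index varying fastest within subplot
  X <- matrix(aperm(tensor$cover, c(3, 1, 2)), nrow = T_)
  Y <- t(tensor$biomass)                       # T x K
  m <- colMeans(X)
  mu <- colMeans(Y)
  if (detrend) {
    if (T_ < 3) stop("insufficient data: detrending needs >= 3 time points")
    X <- apply(X, 2, detrend_series)
    Y <- apply(Y, 2, detrend_series)
  }
  structure(
    list(m = m, w = stats::cov(X), mu = mu, v = stats::cov(Y),
         n_years = T_, n_species = S, n_subplots = K, detrended = detrend),
    class = "temporal_moments"
  )
}

.safe_ratio <- function(num, den) if (den <= 0) Inf else num / den

#' Partition temporal stability across species and spatial scales
#'
#' Assembles the five stability/asynchrony statistics from temporal
#' moments (see the formulas in the package vignette). Zero denominators
#' (constant series) yield flagged `Inf` rather than errors; they are
#' dropped, with a count, at the log-transform step.
#'
#' @param moments a [temporal_moments()] object.
#' @return object of class `stability_set`: `species_stability`,
#'   `species_asynchrony`, `alpha_stability`, `spatial_asynchrony`,
#'   `gamma_stability`, plus `detrended` and `flags` (names of statistics
#'   that came out non-finite).
#' @export
stability_partition <- function(moments) {
  stopifnot(inherits(moments, "temporal_moments"))
  S <- moments$n_species; K <- moments$n_subplots
  w <- moments$w; v <- moments$v

  sd_species <- sqrt(pmax(diag(w), 0))
  # within-subplot community cover variance: sum of the subplot's w block
  comm_var <- vapply(seq_len(K), function(k) {
    idx <- ((k - 1) * S + 1):(k * S)
    sum(w[idx, idx])
  }, 0)
  if (any(comm_var < -1e-12))
    stop("negative within-subplot community variance: covariance matrix ",
         "is inconsistent")
  comm_var <- pmax(comm_var, 0)
  tot_var <- sum(v)
  if (tot_var < -1e-12)
    stop("negative total biomass variance: covariance matrix is inconsistent")
  tot_var <- max(tot_var, 0)
  sd_subplot <- sqrt(pmax(diag(v), 0))

  out <- list(
    species_stability  = .safe_ratio(sum(moments$m), sum(sd_species)),
    species_asynchrony = .safe_ratio(sum(sd_species), sum(sqrt(comm_var))),
    alpha_stability    = .safe_ratio(sum(moments$mu), sum(sd_subplot)),
    spatial_asynchrony = .safe_ratio(sum(sd_subplot), sqrt(tot_var)),
    gamma_stability    = .safe_ratio(sum(moments$mu), sqrt(tot_var))
  )
  out$detrended <- moments$detrended
  out$flags <- names(out)[vapply(out[1:5], function(z) !is.finite(z), TRUE)]
  class(out) <- "stability_set"
  out
}

#' @export
print.stability_set <- function(x, ...) {
  cat("stability_set", if (x$detrended) "(detrended)" else "(raw)", "\n")
  v <- unlist(x[1:5])
  print(round(v, 4))
  if (length(x$flags))
    cat("  flagged non-finite:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Natural-log transform of stability statistics
#'
#' Stability and asynchrony measures are log transformed before analysis
#' to improve normality. Non-positive or non-finite entries (flagged
#' infinities from zero-variance series) become `NA` with a single warning
#' carrying the count; the count is also attached as attribute `"dropped"`.
#'
#' @param values a `stability_set` or numeric vector of positive reals.
#' @param base log base, `"natural"` (default) or `"log10"`.
#' @return numeric vector of transformed values.
#' @export
log_transform_set <- function(values, base = c("natural", "log10")) {
  base <- match.arg(base)
  if (inherits(values, "stability_set")) values <- unlist(values[1:5])
  ok <- is.finite(values) & values > 0
  out <- rep(NA_real_, length(values))
  out[ok] <- if (base == "natural") log(values[ok]) else log10(values[ok])
  names(out) <- names(values)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(n_bad, " non-positive/non-finite value(s) set to NA before log")
  attr(out, "dropped") <- n_bad
  out
}
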