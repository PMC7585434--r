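# Local (alpha) diversity indices and the multiplicative beta/gamma
# partition. Each 1 m2 subplot is a "community"; the replicated subplots
# within a site are the larger scale. Abundance-based gamma is the inverse
# Simpson index of the pooled subplots; multiplicative beta = gamma / mean
# local inverse Simpson (1 = identical compositions, up to K = number of
# subplots for equal-weight disjoint compositions).

.check_relabund <- function(p) {
  if (!is.numeric(p) || !length(p) || anyNA(p) || any(!is.finite(p)))
    stop("relative abundances must be finite numerics")
  if (any(p < 0)) stop("relative abundances must be >= 0")
  if (all(p == 0)) stop("undefined input: all-zero abundance vector")
  if (abs(sum(p) - 1) > 1e-9)
    stop("relative abundances must sum to 1 (tolerance 1e-9); got ", sum(p))
  p
}

#' Shannon-Weaver index (nats)
#'
#' `H = -sum(p * log(p))` over positive entries; 0 for a single species.
#'
#' @param p probability vector (relative abundances summing to 1).
#' @return Shannon entropy in nats.
#' @export
shannon_index <- function(p) {
  p <- .check_relabund(p)
  as.numeric(vegan::diversity(p, index = "shannon"))
}

#' Inverse Simpson index
#'
#' `D = 1 / sum(p^2)`; between 1 and the number of species.
#'
#' @inheritParams shannon_index
#' @return inverse Simpson diversity.
#' @export
inverse_simpson <- function(p) {
  p <- .check_relabund(p)
  as.numeric(vegan::diversity(p, index = "invsimpson"))
}

# index of one abundance vector after normalization; NA for empty communities
.div_of <- function(x, index) {
  s <- sum(x)
  if (s <= 0) return(NA_real_)
  as.numeric(vegan::diversity(x / s, index = index))
}

# species-wise basis abundances per subplot: either the temporal mean cover
# over the window (one composition per subplot) or the per-year covers.
.basis_matrices <- function(tensor, basis) {
  if (basis == "time_mean") {
    list(apply(tensor$cover, c(1, 2), mean))   # one S x K matrix
  } else {
    lapply(seq_len(tensor$duration_years), function(t) tensor$cover[, , t, drop = FALSE][, , 1])
  }
}

#' Local (alpha) diversity of a community tensor
#'
#' Species richness is the average number of species per subplot-year.
#' Shannon and inverse Simpson are computed per subplot on the chosen basis
#' (default: each subplot's species-wise temporal mean cover) and averaged
#' over subplots (and years for `basis = "annual"`). Pielou evenness is
#' mean Shannon divided by the natural log of mean richness.
#'
#' @param tensor a [community_tensor()].
#' @param basis `"time_mean"` (default) or `"annual"`.
#' @return list with `richness`, `shannon`, `inv_simpson`, `evenness`.
#' @export
local_diversity <- function(tensor, basis = c("time_mean", "annual")) {
  basis <- match.arg(basis)
  counts <- apply(tensor$cover > 0, c(2, 3), sum)  # K x T species counts
  richness <- mean(counts)
  mats <- .basis_matrices(tensor, basis)
  H <- unlist(lapply(mats, function(m) apply(m, 2, .div_of, index = "shannon")))
  D <- unlist(lapply(mats, function(m) apply(m, 2, .div_of, index = "invsimpson")))
  shannon <- mean(H, na.rm = TRUE)
  inv_simpson <- mean(D, na.rm = TRUE)
  if (richness <= 1) {
    warning("mean richness <= 1: evenness undefined, returning NA")
    evenness <- NA_real_
  } else {
    evenness <- shannon / log(richness)
  }
  list(richness = richness, shannon = shannon,
       inv_simpson = inv_simpson, evenness = evenness)
}

#' Gamma and multiplicative beta diversity of a community tensor
#'
#' Pools each species' basis cover across subplots, renormalizes, and takes
#' the inverse Simpson index of the pool (gamma). Multiplicative beta is
#' gamma divided by the mean local inverse Simpson on the same basis.
#'
#' @inheritParams local_diversity
#' @return list with `gamma_inv_simpson` and `beta_multiplicative`.
#' @export
gamma_beta_diversity <- function(tensor, basis = c("time_mean", "annual")) {
  basis <- match.arg(basis)
  mats <- .basis_matrices(tensor, basis)
  gam <- vapply(mats, function(m) .div_of(rowSums(m), "invsimpson"), 0)
  loc <- unlist(lapply(mats, function(m) apply(m, 2, .div_of, index = "invsimpson")))
  gamma_inv_simpson <- mean(gam, na.rm = TRUE)
  beta <- gamma_inv_simpson / mean(loc, na.rm = TRUE)
  list(gamma_inv_simpson = gamma_inv_simpson, beta_multiplicative = beta)
}
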