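# Per-duration standardized path models, inverse-variance meta-analytic
# pooling across durations, Cochrane Q treatment contrasts, AR(1) bivariate
# slopes, log response ratios, climate residualization and two-way ANOVA.

#' Default path model linking diversity to stability at two scales
#'
#' Species richness is hypothesized to drive species stability and species
#' asynchrony, which jointly determine alpha stability; beta diversity
#' drives spatial asynchrony; alpha stability and spatial asynchrony
#' determine gamma stability. Richness and beta diversity are exogenous
#' and correlated but not connected by a directed path.
#'
#' @return list of formulas (response ~ predictors), evaluated in order.
#' @export
default_path_model <- function() {
  list(
    species_stability  ~ richness,
    species_asynchrony ~ richness,
    alpha_stability    ~ species_stability + species_asynchrony,
    spatial_asynchrony ~ beta_div,
    gamma_stability    ~ alpha_stability + spatial_asynchrony
  )
}

.check_acyclic <- function(paths) {
  edges <- do.call(rbind, lapply(paths, function(f) {
    resp <- all.vars(f)[1]
    cbind(all.vars(f)[-1], resp)
  }))
  nodes <- unique(as.vector(edges))
  # Kahn's algorithm
  repeat {
    if (!nrow(edges)) return(invisible(TRUE))
    sources <- setdiff(nodes, edges[, 2])
    if (!length(sources)) stop("path model contains a cycle")
    keep <- !(edges[, 1] %in% sources)
    edges <- edges[keep, , drop = FALSE]
    nodes <- setdiff(nodes, sources)
  }
}

#' Standardized path coefficients by piecewise least squares
#'
#' Each response is regressed on its predictors after z-scoring every
#' variable (mean 0, SD 1), giving standardized path coefficients with
#' their least-squares standard errors and per-response R-squared. The
#' Pearson correlation between the exogenous `richness` and `beta_div`
#' variables (when both are present) is attached as attribute
#' `"exogenous_cor"`.
#'
#' @param metrics data frame, one row per site, containing every variable
#'   of the path model (stability/asynchrony variables already on the log
#'   scale).
#' @param paths list of formulas; default [default_path_model()].
#' @return data frame of class `path_fit` with columns `response`,
#'   `predictor`, `coef`, `se`, `n`, `r2`.
#' @export
standardized_path_fit <- function(metrics, paths = default_path_model()) {
  .check_acyclic(paths)
  vars <- unique(unlist(lapply(paths, all.vars)))
  missing <- setdiff(vars, names(metrics))
  if (length(missing))
    stop("variables absent from metrics table: ", paste(missing, collapse = ", "))
  df <- metrics[vars]
  if (anyNA(df)) {
    df <- df[stats::complete.cases(df), , drop = FALSE]
  }
  n <- nrow(df)
  max_p <- max(vapply(paths, function(f) length(all.vars(f)) - 1L, 1L))
  if (n < max_p + 3)
    stop("too few rows (", n, ") for path model with ", max_p, " predictors")
  sds <- vapply(df, stats::sd, 0)
  if (any(sds == 0))
    stop("degenerate input: zero-variance variable(s): ",
         paste(names(sds)[sds == 0], collapse = ", "))
  z <- as.data.frame(scale(df))
  rows <- lapply(paths, function(f) {
    fit <- stats::lm(f, data = z)
    # the gamma = alpha x spatial identity makes one path an exact fit;
    # summary.lm's perfect-fit warning is expected there, not a defect
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    co <- sm$coefficients
    preds <- rownames(co)[rownames(co) != "(Intercept)"]
    data.frame(
      response  = all.vars(f)[1],
      predictor = preds,
      coef      = co[preds, "Estimate"],
      se        = co[preds, "Std. Error"],
      n         = n,
      r2        = sm$r.squared,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all(c("richness", "beta_div") %in% vars))
    attr(out, "exogenous_cor") <- stats::cor(df$richness, df$beta_div)
  class(out) <- c("path_fit", "data.frame")
  out
}

#' Inverse-variance meta-analysis of coefficients across durations
#'
#' Fixed-effect pooling with weights `1/SE^2` (the default used for
#' treatment contrasts), plus DerSimonian-Laird random-effects estimates
#' reported alongside, and the heterogeneity statistic Q.
#'
#' @param coef numeric vector of estimates (>= 2).
#' @param se matching standard errors (> 0).
#' @return list: `pooled`, `se`, `ci` (95%), `Q_het`, `df`, `tau2`,
#'   `pooled_re`, `se_re`, `ci_re`, `k`.
#' @export
meta_combine <- function(coef, se) {
  if (length(coef) != length(se) || length(coef) < 2)
    stop("need >= 2 matching estimates")
  if (any(!is.finite(coef)) || any(!is.finite(se)) || any(se <= 0))
    stop("validation error: SEs must be finite and > 0")
  w <- 1 / se^2
  pooled <- sum(w * coef) / sum(w)
  pse <- sqrt(1 / sum(w))
  k <- length(coef)
  Q <- sum(w * (coef - pooled)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  pooled_re <- sum(wr * coef) / sum(wr)
  pse_re <- sqrt(1 / sum(wr))
  zc <- stats::qnorm(0.975)
  list(pooled = pooled, se = pse, ci = pooled + c(-1, 1) * zc * pse,
       Q_het = Q, df = k - 1, tau2 = tau2,
       pooled_re = pooled_re, se_re = pse_re,
       ci_re = pooled_re + c(-1, 1) * zc * pse_re, k = k)
}

#' Cochrane Q test for a control-vs-fertilized difference in one path
#'
#' Two-group fixed-effect subgroup test:
#' `Q = (coef_c - coef_f)^2 / (se_c^2 + se_f^2)`, df = 1, p from the
#' chi-square(1) upper tail.
#'
#' @param control,fertilized length-2 numeric vectors `(coef, se)`.
#' @return list `Q`, `df`, `p`.
#' @export
treatment_difference_q <- function(control, fertilized) {
  stopifnot(length(control) == 2, length(fertilized) == 2)
  if (control[2] <= 0 || fertilized[2] <= 0)
    stop("validation error: SEs must be > 0")
  Q <- (control[1] - fertilized[1])^2 / (control[2]^2 + fertilized[2]^2)
  list(Q = Q, df = 1L, p = stats::pchisq(Q, df = 1, lower.tail = FALSE))
}

#' Bivariate slope with AR(1) errors (iterated Cochrane-Orcutt)
#'
#' Observations within a series (e.g. the nested duration windows of one
#' site) are expected to be correlated from one step to the next. The
#' slope is estimated by iterated feasible GLS: fit by least squares,
#' estimate rho from the lag-1 autocorrelation of residuals within series,
#' quasi-difference, refit; iterate to `|delta rho| < 1e-8` or 100
#' iterations. The 95% CI comes from the final transformed fit.
#'
#' @param y,x numeric vectors.
#' @param series_id grouping factor over consecutive observations; `NULL`
#'   treats all observations as one series.
#' @param fix_rho optional fixed rho (0 reproduces ordinary least squares).
#' @return list `slope`, `intercept`, `ci` (95%), `rho`, `converged`,
#'   `flag` (NULL or a character note).
#' @export
slope_with_ar1 <- function(y, x, series_id = NULL, fix_rho = NULL) {
  stopifnot(length(y) == length(x))
  if (is.null(series_id)) series_id <- rep(1L, length(y))
  ord <- order(series_id)
  y <- y[ord]; x <- x[ord]; series_id <- series_id[ord]
  if (stats::sd(y) == 0)
    return(list(slope = 0, intercept = y[1], ci = c(0, 0), rho = NA_real_,
                converged = TRUE, flag = "constant response; rho undefined"))

  lag_pairs <- function(e) {
    # within-series lag-1 pairs
    first <- !duplicated(series_id)
    cur <- e[!first]; prev <- e[-length(e)][!first[-1]]
    list(cur = cur, prev = prev)
  }
  ols <- stats::lm(y ~ x)
  if (!is.null(fix_rho) && fix_rho == 0) {
    ci <- stats::confint(ols)["x", ]
    return(list(slope = stats::coef(ols)[["x"]],
                intercept = stats::coef(ols)[["(Intercept)"]],
                ci = unname(ci), rho = 0, converged = TRUE, flag = NULL))
  }
  a <- stats::coef(ols)[[1]]; b <- stats::coef(ols)[[2]]
  rho <- 0; converged <- FALSE
  for (it in seq_len(100)) {
    e <- y - a - b * x
    lp <- lag_pairs(e)
    denom <- sum(lp$prev^2)
    rho_new <- if (!is.null(fix_rho)) fix_rho else if (denom > 0)
      sum(lp$cur * lp$prev) / denom else 0
    rho_new <- max(min(rho_new, 0.99), -0.99)
    first <- !duplicated(series_id)
    ys <- y[!first] - rho_new * y[-length(y)][!first[-1]]
    xs <- x[!first] - rho_new * x[-length(x)][!first[-1]]
    if (length(ys) < 3 || stats::sd(xs) == 0) break
    fit <- stats::lm(ys ~ xs)
    b <- stats::coef(fit)[["xs"]]
    a <- stats::coef(fit)[["(Intercept)"]] / (1 - rho_new)
    if (abs(rho_new - rho) < 1e-8) { rho <- rho_new; converged <- TRUE; break }
    rho <- rho_new
    if (!is.null(fix_rho)) { converged <- TRUE; break }
  }
  ci <- tryCatch(unname(stats::confint(fit)["xs", ]), error = function(e) c(NA, NA))
  if (!converged)
    warning("slope_with_ar1 did not converge; returning last iterate")
  list(slope = b, intercept = a, ci = ci, rho = rho, converged = converged,
       flag = if (converged) NULL else "non-convergence")
}

#' Log response ratio of fertilized to control
#'
#' @param fertilized,control positive reals.
#' @return `log(fertilized / control)`.
#' @export
log_response_ratio <- function(fertilized, control) {
  if (any(!is.finite(fertilized)) || any(!is.finite(control)) ||
      any(fertilized <= 0) || any(control <= 0))
    stop("log response ratio needs positive finite inputs")
  log(fertilized / control)
}

#' Residualize site-level values on climate variability covariates
#'
#' Returns the residuals of a least-squares regression of `y` on the
#' coefficients of variation of precipitation (`MAP_VAR`) and temperature
#' (`MAT_VAR`); near-collinear covariates (|r| > 0.999) trigger a warning
#' and one is dropped.
#'
#' @param y numeric vector, one value per site.
#' @param climate data frame with columns `MAP_VAR` and `MAT_VAR` aligned
#'   with `y`.
#' @return residual vector (mean zero).
#' @export
climate_residualize <- function(y, climate) {
  stopifnot(all(c("MAP_VAR", "MAT_VAR") %in% names(climate)),
            nrow(climate) == length(y))
  if (any(climate$MAP_VAR < 0) || any(climate$MAT_VAR < 0))
    stop("climate CVs must be >= 0")
  if (abs(stats::cor(climate$MAP_VAR, climate$MAT_VAR)) > 0.999) {
    warning("collinear climate covariates; dropping MAT_VAR")
    fit <- stats::lm(y ~ MAP_VAR, data = climate)
  } else {
    fit <- stats::lm(y ~ MAP_VAR + MAT_VAR, data = climate)
  }
  unname(stats::residuals(fit))
}

#' Two-way ANOVA for treatment and experimental-duration effects
#'
#' Fits `value ~ treatment + duration` (optionally with interaction) by
#' `aov` and returns F, degrees of freedom and p per factor. An optional
#' AR(1) pre-whitening quasi-differences the response within site series
#' before fitting.
#'
#' @param metrics data frame with columns `value`, `treatment`, `duration`
#'   (and `site` when `whiten = TRUE`).
#' @param interaction include the treatment x duration interaction?
#' @param whiten logical; AR(1) pre-whitening of `value` within site.
#' @return data frame with columns `term`, `df`, `F`, `p`.
#' @export
anova_effects <- function(metrics, interaction = FALSE, whiten = FALSE) {
  stopifnot(all(c("value", "treatment", "duration") %in% names(metrics)))
  metrics$treatment <- factor(metrics$treatment)
  metrics$duration <- factor(metrics$duration)
  for (f in c("treatment", "duration"))
    if (nlevels(metrics[[f]]) < 2)
      stop("factor ", f, " has a single level")
  if (whiten) {
    stopifnot("site" %in% names(metrics))
    metrics <- metrics[order(metrics$site, metrics$treatment, metrics$duration), ]
    sid <- interaction(metrics$site, metrics$treatment)
    e <- stats::residuals(stats::lm(value ~ treatment + duration, metrics))
    first <- !duplicated(sid)
    cur <- e[!first]; prev <- e[-length(e)][!first[-1]]
    rho <- if (sum(prev^2) > 0) sum(cur * prev) / sum(prev^2) else 0
    v <- metrics$value
    v[!first] <- v[!first] - rho * v[-length(v)][!first[-1]]
    v[first] <- v[first] * sqrt(1 - min(rho^2, 0.99))
    metrics$value <- v
  }
  form <- if (interaction) value ~ treatment * duration else value ~ treatment + duration
  sm <- summary(stats::aov(form, data = metrics))[[1]]
  terms <- trimws(rownames(sm))
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], df = sm$Df[keep], F = sm$`F value`[keep],
             p = sm$`Pr(>F)`[keep], stringsAsFactors = FALSE)
}

#' Overlapping four-year windows
#'
#' Temporal-trend analyses divide a series of `T` post-treatment years into
#' overlapping intervals of four consecutive years: `[t, t+3]` for
#' `t = 1 .. T-3`.
#'
#' @param n_years total number of years T.
#' @return list of integer vectors `c(start, end)`; empty (with a warning)
#'   for T < 4.
#' @export
overlapping_windows <- function(n_years) {
  n_years <- as.integer(n_years)
  if (n_years < 4) {
    warning("fewer than 4 years: no 4-year windows")
    return(list())
  }
  lapply(seq_len(n_years - 3L), function(t) c(t, t + 3L))
}
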