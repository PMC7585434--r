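# Independent oracles and fixture builders. The stability oracle expands
# every covariance term with explicit loops; it shares no code path with
# stability_partition().

random_tensor <- function(S = 3, K = 2, T_ = 5, site = "s1", trt = "Control") {
  cov_arr <- array(stats::runif(S * K * T_, 0, 30),
                   dim = c(S, K, T_),
                   dimnames = list(sprintf("sp%02d", seq_len(S)),
                                   seq_len(K), seq_len(T_)))
  biom <- matrix(stats::runif(K * T_, 50, 400), K, T_)
  community_tensor(cov_arr, biom, site, trt)
}

# perfectly synchronous world: every series proportional to one year signal
synchronous_tensor <- function(S = 4, K = 3, T_ = 6) {
  f <- stats::runif(T_, 0.5, 1.5)
  m <- stats::runif(S, 1, 20)
  u <- stats::runif(K, 0.5, 2)
  cov_arr <- array(0, dim = c(S, K, T_),
                   dimnames = list(sprintf("sp%02d", seq_len(S)),
                                   seq_len(K), seq_len(T_)))
  for (k in seq_len(K)) cov_arr[, k, ] <- outer(m * u[k], f)
  biom <- 4 * apply(cov_arr, c(2, 3), sum)
  community_tensor(cov_arr, biom, "sync", "Control")
}

.detrend_oracle <- function(y) {
  t <- seq_along(y)
  unname(stats::resid(stats::lm(y ~ t)))
}

# brute-force evaluation of the five statistics by explicit term expansion
brute_stability <- function(tensor, detrend = FALSE) {
  S <- length(tensor$species); K <- tensor$n_subplots
  series <- function(i, k) tensor$cover[i, k, ]
  dser <- function(y) if (detrend) .detrend_oracle(y) else y

  m_sum <- 0; sd_sum <- 0
  for (k in seq_len(K)) for (i in seq_len(S)) {
    m_sum <- m_sum + mean(series(i, k))
    sd_sum <- sd_sum + sqrt(stats::cov(dser(series(i, k)), dser(series(i, k))))
  }
  comm_sd_sum <- 0
  for (k in seq_len(K)) {
    vk <- 0
    for (i in seq_len(S)) for (j in seq_len(S))
      vk <- vk + stats::cov(dser(series(i, k)), dser(series(j, k)))
    comm_sd_sum <- comm_sd_sum + sqrt(max(vk, 0))
  }
  mu_sum <- 0; bsd_sum <- 0; vtot <- 0
  for (k in seq_len(K)) {
    mu_sum <- mu_sum + mean(tensor$biomass[k, ])
    bsd_sum <- bsd_sum +
      sqrt(stats::cov(dser(tensor$biomass[k, ]), dser(tensor$biomass[k, ])))
    for (l in seq_len(K))
      vtot <- vtot + stats::cov(dser(tensor$biomass[k, ]),
                                dser(tensor$biomass[l, ]))
  }
  list(
    species_stability  = m_sum / sd_sum,
    species_asynchrony = sd_sum / comm_sd_sum,
    alpha_stability    = mu_sum / bsd_sum,
    spatial_asynchrony = bsd_sum / sqrt(vtot),
    gamma_stability    = mu_sum / sqrt(vtot)
  )
}

# alpha stability computed on the cover currency via the community-biomass
# route (biomass := summed cover), for the multiplicative-chain identity
cover_alpha_stability <- function(tensor, detrend = FALSE) {
  t2 <- community_tensor(tensor$cover, apply(tensor$cover, c(2, 3), sum),
                         tensor$site_id, tensor$treatment)
  stability_partition(temporal_moments(t2, detrend))$alpha_stability
}

# normal-equation oracle for standardized coefficients
zscore_lm_oracle <- function(y, X) {
  zy <- (y - mean(y)) / stats::sd(y)
  zX <- scale(X)
  solve(crossprod(zX), crossprod(zX, zy))[, 1]
}

write_long_fixture <- function(dir = NULL) {
  if (is.null(dir)) { dir <- tempfile("fixture"); dir.create(dir) }
  cover <- data.frame(
    site_code = "a", block = rep(1:2, each = 3), trt = "Control",
    year_trt = rep(1:3, 2), Taxon = "Poa pratensis",
    max_cover = c(10, 12, 9, 20, 18, 25)
  )
  biomass <- data.frame(
    site_code = "a", block = rep(1:2, each = 3), trt = "Control",
    year_trt = rep(1:3, 2), live_mass = c(100, 120, 90, 200, 180, 250)
  )
  cp <- file.path(dir, "cover.csv"); bp <- file.path(dir, "biomass.csv")
  write.csv(cover, cp, row.names = FALSE)
  write.csv(biomass, bp, row.names = FALSE)
  list(cover = cp, biomass = bp, dir = dir)
}
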