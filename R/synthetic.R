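# Synthetic multi-site community time series.
#
# Generative model, per site: a lognormal species pool with species-specific
# responses b_i ~ N(0, tau_b^2) to a shared site-level environmental
# fluctuation E_t, a subplot-level fluctuation e_kt whose cross-subplot
# correlation is rho_space * omega (compositionally dissimilar communities
# respond less coherently), species-specific sensitivities c_i ~ N(1,
# tau_c^2) to e_kt, and idiosyncratic lognormal noise:
#
#   cover_ikt = a_i * exp( s * (b_i * E_t + c_i * e_kt) + sigma * eps_ikt )
#
# with s an environmental-response scale (1 in the control arm). Subplot
# communities are weighted resamples of the pool sharing a core fraction
# omega. Biomass is mass_per_cover times summed cover times a lognormal
# biomass-per-cover fluctuation shared among subplots in proportion to
# omega. The fertilized (NPK) arm drops the rarest species (expected count
# richness_loss per subplot), multiplies species means by
# biomass_multiplier, shrinks the response heterogeneity by
# (1 - homogenization) and pulls the effective overlap toward 1, and -- the
# built-in treatment x richness interaction switch -- scales the whole
# environmental response by exp(fert_destab * z) where z is the site's
# standardized richness, destabilizing species-rich fertilized communities.
#
# RNG draw order (fixed so seeds reproduce across versions): per site --
# duration, richness, overlap, pool abundances, pool responses and
# sensitivities; then per arm -- environments, biomass fluctuations,
# composition, richness-loss uniforms, species noise; finally climate
# covariates. Draw counts never depend on the effect switches, so one seed
# yields common-random-number paired worlds across presets.

#' Configuration for the synthetic community generator
#'
#' Defaults encode the emulated study conditions: 42 sites x 3 subplots x
#' 2 treatment arms, 4-9 post-treatment years per site (more sites with
#' short series), a richness gradient of 4-30 species per subplot,
#' compositional overlap among subplots of 0.1-0.95, and fertilization
#' effects of an expected 1.8 species m-2 lost, biomass x 1.3 and response
#' homogenization 0.8 when switched on via [synthetic_preset()].
#'
#' @param n_sites number of sites.
#' @param n_subplots subplots (blocks) per site per arm.
#' @param year_range inclusive range of post-treatment series lengths.
#' @param year_weights sampling weights over `year_range` (declining site
#'   counts with longer duration).
#' @param pool_size species pool size per site.
#' @param richness_range range of per-subplot species richness across sites.
#' @param abund_meanlog,abund_sdlog lognormal mean-cover distribution
#'   (percent) of pool species.
#' @param env_sd_site sd of the site-level annual fluctuation E_t.
#' @param env_sd_subplot sd of the subplot-level fluctuation e_kt.
#' @param rho_space coherence ceiling of e_kt in `[0, 1]`; the realized
#'   cross-subplot correlation is `rho_space * omega`.
#' @param tau_b sd of species-specific responses b_i to E_t.
#' @param tau_c sd of species-specific sensitivities c_i (mean 1) to the
#'   subplot-level fluctuation e_kt.
#' @param sigma sd of idiosyncratic species noise (log scale).
#' @param omega_range per-site compositional overlap range, in `[0, 1]`.
#' @param richness_loss expected species dropped per fertilized subplot.
#' @param biomass_multiplier multiplier on fertilized species mean covers.
#' @param homogenization h in `[0, 1]`; fertilized b_i shrink by `(1 - h)`.
#' @param fert_destab treatment x richness interaction strength: the
#'   fertilized arm's environmental response is scaled by
#'   `exp(fert_destab * z_richness)` (0 disables the interaction).
#' @param drop_rule `"rarest"` (default) or `"random"` species loss.
#' @param mass_per_cover g m-2 of live biomass per percent summed cover.
#' @param biomass_noise_sd sd (log scale) of the multiplicative
#'   biomass-per-cover fluctuation; compositionally similar subplots share
#'   it (cross-subplot correlation = overlap omega).
#' @param climate_cv_range list with uniform ranges `map` and `mat` for the
#'   site climate-variability covariates.
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical tables.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 42L,
                             n_subplots = 3L,
                             year_range = c(4L, 9L),
                             year_weights = c(5, 5, 6, 6, 5, 15),
                             pool_size = 140L,
                             richness_range = c(4L, 30L),
                             abund_meanlog = 1.0,
                             abund_sdlog = 0.7,
                             env_sd_site = 0.6,
                             env_sd_subplot = 0.1,
                             rho_space = 0.9,
                             tau_b = 0.7,
                             tau_c = 0.5,
                             sigma = 0.25,
                             omega_range = c(0.1, 0.95),
                             richness_loss = 0,
                             biomass_multiplier = 1,
                             homogenization = 0,
                             fert_destab = 0,
                             drop_rule = c("rarest", "random"),
                             mass_per_cover = 4,
                             biomass_noise_sd = 0.4,
                             climate_cv_range = list(map = c(0.1, 0.8),
                                                     mat = c(0.05, 0.6)),
                             seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites), n_subplots = as.integer(n_subplots),
    year_range = as.integer(year_range), year_weights = year_weights,
    pool_size = as.integer(pool_size),
    richness_range = as.integer(richness_range),
    abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
    env_sd_site = env_sd_site, env_sd_subplot = env_sd_subplot,
    rho_space = rho_space, tau_b = tau_b, tau_c = tau_c, sigma = sigma,
    omega_range = omega_range, richness_loss = richness_loss,
    biomass_multiplier = biomass_multiplier,
    homogenization = homogenization, fert_destab = fert_destab,
    drop_rule = match.arg(drop_rule), mass_per_cover = mass_per_cover,
    biomass_noise_sd = biomass_noise_sd, climate_cv_range = climate_cv_range,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_sites < 1 || n_subplots < 2) stop("config error: need >= 1 site and >= 2 subplots")
    if (year_range[1] < 2 || year_range[2] < year_range[1])
      stop("config error: bad year_range")
    if (length(year_weights) != diff(year_range) + 1L)
      stop("config error: year_weights must match year_range length")
    if (richness_range[1] < 2 || richness_range[2] < richness_range[1])
      stop("config error: bad richness_range")
    if (rho_space < 0 || rho_space > 1) stop("config error: rho_space must be in [0,1]")
    if (tau_b < 0 || tau_c < 0 || sigma < 0)
      stop("config error: tau_b, tau_c and sigma must be >= 0")
    if (any(omega_range < 0) || any(omega_range > 1) ||
        omega_range[2] < omega_range[1])
      stop("config error: omega_range must be within [0,1]")
    if (homogenization < 0 || homogenization > 1)
      stop("config error: homogenization must be in [0,1]")
    if (richness_loss < 0) stop("config error: richness_loss must be >= 0")
    if (biomass_multiplier <= 0) stop("config error: biomass_multiplier must be > 0")
    need <- ceiling(richness_range[2] *
                      (1 + (n_subplots - 1) * (1 - omega_range[1]))) + 1
    if (pool_size < need)
      stop("config error: pool_size ", pool_size, " too small; need >= ", need)
  })
  structure(cfg, class = "synthetic_config")
}

#' Named generator presets
#'
#' * `control_like`: heterogeneous species responses (high `tau_b`), no
#'   fertilization effects in either arm -- diversity stabilizes, the two
#'   arms are exchangeable.
#' * `fertilized_like`: the NPK arm loses 1.8 species per subplot, gains
#'   30% biomass, has its species responses homogenized (h = 0.8) and its
#'   environmental response amplified in species-rich sites
#'   (`fert_destab = 0.6`) -- diversity effects attenuate under
#'   fertilization.
#' * `null_world`: no response heterogeneity (`tau_b = 0`), identical
#'   subplot compositions (`omega = 1`), no sensitivity heterogeneity
#'   (`tau_c = 0`) and no idiosyncratic species noise (`sigma = 0`, since
#'   independent species-level noise alone would produce a
#'   portfolio-effect diversity-stability link) -- no diversity-stability
#'   relationship at either scale.
#'
#' @param name preset name.
#' @param ... overrides passed on to [synthetic_config()] (e.g. `seed`,
#'   `n_sites`).
#' @return a [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("control_like", "fertilized_like",
                                      "null_world"), ...) {
  if (!is.character(name) || !name[1] %in%
      c("control_like", "fertilized_like", "null_world"))
    stop("unknown preset '", name[1],
         "'; available: control_like, fertilized_like, null_world")
  name <- name[1]
  base <- switch(name,
    control_like = list(),
    fertilized_like = list(richness_loss = 1.8, biomass_multiplier = 1.3,
                           homogenization = 0.8, fert_destab = 0.6),
    null_world = list(tau_b = 0, tau_c = 0, omega_range = c(1, 1), sigma = 0)
  )
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

#' Generate a synthetic cover/biomass dataset with ground truth
#'
#' Emits long-format cover and biomass tables in the exact CSV schema
#' consumed by [read_long_tables()], a site-level climate covariate table,
#' and a ground-truth record of every drawn parameter (sufficient to
#' recompute expected species mean covers exactly).
#'
#' @param config a [synthetic_config()].
#' @return list with `cover`, `biomass`, `climate` data frames and
#'   `ground_truth`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$n_subplots
  rbar <- mean(config$richness_range)
  rhalf <- max(diff(config$richness_range) / 2, 1)
  years_avail <- config$year_range[1]:config$year_range[2]

  cover_rows <- vector("list", config$n_sites * 2L * K)
  biomass_rows <- vector("list", config$n_sites * 2L * K)
  truth <- vector("list", config$n_sites)
  ri <- 0L

  for (s in seq_len(config$n_sites)) {
    site <- sprintf("site_%02d", s)
    T_s <- sample(years_avail, 1, prob = config$year_weights)
    S_s <- sample(config$richness_range[1]:config$richness_range[2], 1)
    omega_s <- stats::runif(1, config$omega_range[1], config$omega_range[2])
    a_pool <- stats::rlnorm(config$pool_size, config$abund_meanlog,
                            config$abund_sdlog)
    b_pool <- if (config$tau_b > 0)
      stats::rnorm(config$pool_size, 0, config$tau_b) else
      numeric(config$pool_size)
    c_pool <- if (config$tau_c > 0)
      1 + stats::rnorm(config$pool_size, 0, config$tau_c) else
      rep(1, config$pool_size)
    z_s <- (S_s - rbar) / rhalf
    site_truth <- list(site = site, n_years = T_s, richness = S_s,
                       omega = omega_s, a_pool = a_pool, b_pool = b_pool,
                       arms = list())

    for (trt in c("Control", "NPK")) {
      fert <- trt == "NPK"
      b_arm <- if (fert) b_pool * (1 - config$homogenization) else b_pool
      c_arm <- if (fert) 1 + (c_pool - 1) * (1 - config$homogenization) else c_pool
      env_scale <- if (fert) exp(config$fert_destab * z_s) else 1
      mult <- if (fert) config$biomass_multiplier else 1

      # compositionally dissimilar subplots respond less coherently: the
      # effective cross-subplot correlation tracks overlap; homogenization
      # pulls fertilized communities' responses together
      omega_eff <- if (fert) omega_s + (1 - omega_s) * config$homogenization else omega_s
      rho_eff <- config$rho_space * omega_eff

      # the RNG draw counts below do not depend on any effect switch, so the
      # same seed yields paired (common-random-number) worlds across presets
      E <- stats::rnorm(T_s, 0, config$env_sd_site)
      g <- stats::rnorm(T_s)
      h_mat <- matrix(stats::rnorm(K * T_s), K, T_s)
      # biomass-per-cover fluctuations: productivity variation not captured
      # by cover, shared among subplots in proportion to their overlap
      q <- stats::rnorm(T_s)
      r_mat <- matrix(stats::rnorm(K * T_s), K, T_s)
      bdev <- config$biomass_noise_sd *
        (sqrt(omega_eff) * matrix(q, K, T_s, byrow = TRUE) +
           sqrt(1 - omega_eff) * r_mat)
      e_kt <- config$env_sd_subplot *
        (sqrt(rho_eff) * matrix(g, K, T_s, byrow = TRUE) +
           sqrt(1 - rho_eff) * h_mat)

      # composition: shared core + per-subplot uniques, abundance-weighted
      n_core <- round(omega_s * S_s)
      core <- sample.int(config$pool_size, n_core, prob = a_pool)
      rest <- setdiff(seq_len(config$pool_size), core)
      comp <- lapply(seq_len(K), function(k) {
        extra <- if (S_s > n_core)
          sample(rest, S_s - n_core, prob = a_pool[rest]) else integer(0)
        sort(c(core, extra))
      })
      # fertilization drops the rarest species; quantile transform keeps the
      # uniform draw count fixed whether or not losses are switched on
      n_drop <- pmin(stats::qpois(stats::runif(K), config$richness_loss),
                     S_s - 2L)
      keep <- lapply(seq_len(K), function(k) seq_len(S_s))
      if (fert && config$richness_loss > 0) {
        keep <- lapply(seq_len(K), function(k) {
          if (n_drop[k] == 0) return(seq_len(S_s))
          ord <- if (config$drop_rule == "rarest")
            order(a_pool[comp[[k]]]) else sample.int(S_s)
          sort(setdiff(seq_len(S_s), ord[seq_len(n_drop[k])]))
        })
      } else n_drop <- integer(K)

      for (k in seq_len(K)) {
        eps <- if (config$sigma > 0)
          matrix(stats::rnorm(S_s * T_s), S_s, T_s) else
          matrix(0, S_s, T_s)
        sp <- comp[[k]][keep[[k]]]
        Ssp <- length(sp)
        eps <- eps[keep[[k]], , drop = FALSE]
        logdev <- env_scale *
          (outer(b_arm[sp], E) +
             c_arm[sp] * matrix(e_kt[k, ], Ssp, T_s, byrow = TRUE)) +
          config$sigma * eps
        cov_mat <- a_pool[sp] * mult * exp(logdev)   # Ssp x T
        biom <- config$mass_per_cover * colSums(cov_mat) * exp(bdev[k, ])

        ri <- ri + 1L
        cover_rows[[ri]] <- data.frame(
          site_code = site, block = k, trt = trt,
          year_trt = rep(seq_len(T_s), each = Ssp),
          Taxon = rep(sprintf("sp%03d", sp), T_s),
          max_cover = as.vector(cov_mat),
          stringsAsFactors = FALSE
        )
        biomass_rows[[ri]] <- data.frame(
          site_code = site, block = k, trt = trt,
          year_trt = seq_len(T_s), live_mass = biom,
          stringsAsFactors = FALSE
        )
      }
      comp_kept <- lapply(seq_len(K), function(k) comp[[k]][keep[[k]]])
      site_truth$arms[[trt]] <- list(
        composition = comp_kept, n_dropped = n_drop, b = b_arm, c = c_arm,
        env_scale = env_scale, mean_multiplier = mult,
        expected_mean_cover = lapply(comp_kept, function(sp)
          stats::setNames(a_pool[sp] * mult, sprintf("sp%03d", sp))),
        E = E, e_kt = e_kt
      )
    }
    truth[[s]] <- site_truth
  }

  climate <- data.frame(
    site_code = sprintf("site_%02d", seq_len(config$n_sites)),
    MAP_VAR = stats::runif(config$n_sites, config$climate_cv_range$map[1],
                           config$climate_cv_range$map[2]),
    MAT_VAR = stats::runif(config$n_sites, config$climate_cv_range$mat[1],
                           config$climate_cv_range$mat[2]),
    stringsAsFactors = FALSE
  )

  cover <- do.call(rbind, cover_rows[seq_len(ri)])
  biomass <- do.call(rbind, biomass_rows[seq_len(ri)])
  rownames(cover) <- rownames(biomass) <- NULL
  list(cover = cover, biomass = biomass, climate = climate,
       ground_truth = list(config = unclass(config), sites = truth))
}
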