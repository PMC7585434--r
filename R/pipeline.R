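# End-to-end runner: ingest or simulate long tables, compute per
# site x treatment x duration diversity and stability tables, then run the
# path / meta-analysis / slope stage and write CSV outputs plus a JSON run
# report.

#' Per-window diversity and stability metrics
#'
#' For every site x treatment with at least `min(durations)` contiguous
#' post-treatment years, computes the diversity set and the stability
#' partition on each nested window of years `1..d` for each requested
#' duration `d` (clipped, with a note in the attribute `"clipped"`, when a
#' site has fewer years than requested).
#'
#' @param cover,biomass long-format data frames (seasonally collapsed).
#' @param durations integer vector of window lengths (default 4:9).
#' @param detrend logical; detrended stability denominators.
#' @param basis diversity basis, `"time_mean"` or `"annual"`.
#' @return list with data frames `diversity` and `stability`.
#' @export
compute_metrics <- function(cover, biomass, durations = 4:9,
                            detrend = FALSE,
                            basis = c("time_mean", "annual")) {
  basis <- match.arg(basis)
  durations <- sort(unique(as.integer(durations)))
  grp <- interaction(biomass$site_code, biomass$trt, drop = TRUE)
  bio_split <- split(biomass, grp)
  cov_split <- split(cover, interaction(cover$site_code, cover$trt, drop = TRUE))
  div_rows <- list(); stab_rows <- list(); clipped <- character(0)

  for (g in names(bio_split)) {
    bb <- bio_split[[g]]
    cc <- cov_split[[g]]
    if (is.null(cc)) next
    T_avail <- max(bb$year_trt)
    ds <- durations[durations <= T_avail]
    if (length(ds) < length(durations))
      clipped <- c(clipped, paste0(bb$site_code[1], "/", bb$trt[1],
                                   " has ", T_avail, " years"))
    for (d in ds) {
      tensor <- assemble_tensor(cc, bb, bb$site_code[1], bb$trt[1], d)
      loc <- local_diversity(tensor, basis)
      gb <- gamma_beta_diversity(tensor, basis)
      st <- stability_partition(temporal_moments(tensor, detrend))
      div_rows[[length(div_rows) + 1L]] <- data.frame(
        site_code = tensor$site_id, trt = tensor$treatment, duration = d,
        richness = loc$richness, shannon = loc$shannon,
        evenness = loc$evenness, inv_simpson = loc$inv_simpson,
        gamma_D = gb$gamma_inv_simpson, beta_D = gb$beta_multiplicative,
        stringsAsFactors = FALSE
      )
      stab_rows[[length(stab_rows) + 1L]] <- data.frame(
        site_code = tensor$site_id, trt = tensor$treatment, duration = d,
        detrended = as.integer(detrend),
        species_stability = st$species_stability,
        species_asynchrony = st$species_asynchrony,
        alpha_stability = st$alpha_stability,
        spatial_asynchrony = st$spatial_asynchrony,
        gamma_stability = st$gamma_stability,
        stringsAsFactors = FALSE
      )
    }
  }
  div <- do.call(rbind, div_rows)
  stab <- do.call(rbind, stab_rows)
  ord <- order(div$site_code, div$trt, div$duration)
  out <- list(diversity = div[ord, ], stability = stab[ord, ])
  rownames(out$diversity) <- rownames(out$stability) <- NULL
  attr(out, "clipped") <- clipped
  out
}

.stab_vars <- c("species_stability", "species_asynchrony", "alpha_stability",
                "spatial_asynchrony", "gamma_stability")

#' Merge metrics into the analysis table (log scale)
#'
#' Joins the diversity and stability tables and puts the five stability /
#' asynchrony statistics on the log scale. Site-windows with any
#' non-positive or non-finite statistic are excluded with a count
#' (attribute `"n_dropped"`).
#'
#' @param metrics output of [compute_metrics()].
#' @param log_base `"natural"` or `"log10"`.
#' @return data frame with `site_code`, `trt`, `duration`, `richness`,
#'   `beta_div` and the five logged statistics.
#' @export
metrics_analysis_table <- function(metrics, log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  df <- merge(metrics$diversity[c("site_code", "trt", "duration",
                                  "richness", "beta_D")],
              metrics$stability, by = c("site_code", "trt", "duration"))
  names(df)[names(df) == "beta_D"] <- "beta_div"
  ok <- rep(TRUE, nrow(df))
  for (v in .stab_vars) {
    x <- df[[v]]
    ok <- ok & is.finite(x) & x > 0
    df[[v]] <- suppressWarnings(log_transform_set(x, base = log_base))
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Path, meta-analysis, treatment-Q, slope and response-ratio stage
#'
#' Fits the standardized path model separately for each treatment and
#' duration, pools each path's coefficients across durations by
#' fixed-effect meta-analysis (random-effects reported alongside), tests
#' control-vs-NPK differences per path with Cochrane Q, estimates the
#' bivariate diversity-stability slopes with AR(1) errors across the
#' nested duration windows, and computes per-site log response ratios.
#'
#' @param metrics output of [compute_metrics()].
#' @param paths path model; default [default_path_model()].
#' @param log_base log base for stability statistics.
#' @return list: `paths`, `meta`, `treatment_q`, `slopes`, `lrr`,
#'   `n_dropped`.
#' @export
analyze_metrics <- function(metrics, paths = default_path_model(),
                            log_base = "natural") {
  tab <- metrics_analysis_table(metrics, log_base)
  n_dropped <- attr(tab, "n_dropped")

  path_rows <- list()
  for (d in sort(unique(tab$duration))) {
    for (trt in c("Control", "NPK")) {
      sub <- tab[tab$duration == d & tab$trt == trt, , drop = FALSE]
      fit <- tryCatch(standardized_path_fit(sub, paths), error = function(e) NULL)
      if (is.null(fit)) next
      fit$treatment <- trt
      fit$duration <- d
      path_rows[[length(path_rows) + 1L]] <- as.data.frame(fit)
    }
  }
  path_df <- do.call(rbind, path_rows)
  path_df$path <- paste(path_df$predictor, "->", path_df$response)

  meta_rows <- list(); q_rows <- list()
  for (p in unique(path_df$path)) {
    pooled <- list()
    for (trt in c("Control", "NPK")) {
      sub <- path_df[path_df$path == p & path_df$treatment == trt, ]
      if (nrow(sub) < 2) next
      mc <- meta_combine(sub$coef, sub$se)
      pooled[[trt]] <- mc
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        path = p, treatment = trt, pooled = mc$pooled, se = mc$se,
        ci_lo = mc$ci[1], ci_hi = mc$ci[2], Q_het = mc$Q_het,
        pooled_re = mc$pooled_re, se_re = mc$se_re, k = mc$k,
        stringsAsFactors = FALSE
      )
    }
    if (all(c("Control", "NPK") %in% names(pooled))) {
      q <- treatment_difference_q(
        c(pooled$Control$pooled, pooled$Control$se),
        c(pooled$NPK$pooled, pooled$NPK$se))
      q_rows[[length(q_rows) + 1L]] <- data.frame(
        path = p, Q = q$Q, df = q$df, p = q$p, stringsAsFactors = FALSE)
    }
  }

  rels <- list(c("richness", "alpha_stability"),
               c("richness", "gamma_stability"),
               c("beta_div", "spatial_asynchrony"),
               c("beta_div", "gamma_stability"))
  slope_rows <- list()
  for (r in rels) {
    for (trt in c("Control", "NPK")) {
      sub <- tab[tab$trt == trt, ]
      sub <- sub[order(sub$site_code, sub$duration), ]
      if (nrow(sub) < 5) next
      sl <- slope_with_ar1(sub[[r[2]]], sub[[r[1]]], series_id = sub$site_code)
      slope_rows[[length(slope_rows) + 1L]] <- data.frame(
        relationship = paste(r[1], "->", r[2]), treatment = trt,
        slope = sl$slope, ci_lo = sl$ci[1], ci_hi = sl$ci[2], rho = sl$rho,
        stringsAsFactors = FALSE
      )
    }
  }

  lrr_vars <- c("richness", "beta_div", .stab_vars)
  wide_c <- tab[tab$trt == "Control", ]
  wide_f <- tab[tab$trt == "NPK", ]
  m <- merge(wide_c, wide_f, by = c("site_code", "duration"),
             suffixes = c("_c", "_f"))
  lrr_rows <- list()
  for (v in lrr_vars) {
    fc <- m[[paste0(v, "_f")]]; cc <- m[[paste0(v, "_c")]]
    if (v %in% .stab_vars) {
      val <- fc - cc                      # already on the log scale
    } else {
      val <- log_response_ratio(fc, cc)
    }
    lrr_rows[[length(lrr_rows) + 1L]] <- data.frame(
      site_code = m$site_code, duration = m$duration, variable = v,
      lrr = val, stringsAsFactors = FALSE)
  }

  list(
    paths = path_df[c("path", "treatment", "duration", "response",
                      "predictor", "coef", "se", "n", "r2")],
    meta = do.call(rbind, meta_rows),
    treatment_q = do.call(rbind, q_rows),
    slopes = do.call(rbind, slope_rows),
    lrr = do.call(rbind, lrr_rows),
    n_dropped = n_dropped
  )
}

#' Run the full pipeline
#'
#' Either simulates data from a named preset or reads cover/biomass CSVs,
#' computes the metric tables, runs the inference stage, and (when
#' `out_dir` is given) writes `diversity.csv`, `stability.csv`,
#' `slopes.csv`, `path_coefficients.csv`, `meta_paths.csv`,
#' `treatment_q.csv`, `lrr.csv` and `run_report.json`. Deterministic given
#' inputs + seed.
#'
#' @param preset preset name for simulated input (see [synthetic_preset()]);
#'   `NULL` to read files.
#' @param seed integer seed for simulation.
#' @param cover_path,biomass_path input CSVs when `preset` is `NULL`.
#' @param climate_path optional climate covariate CSV.
#' @param durations window lengths (default 4:9).
#' @param detrend logical.
#' @param basis diversity basis.
#' @param log_base `"natural"` or `"log10"`.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param n_sites number of simulated sites (preset mode).
#' @param verbose print stage messages?
#' @return (invisibly) list with all result tables and the run report.
#' @export
run_pipeline <- function(preset = NULL, seed = 1L,
                         cover_path = NULL, biomass_path = NULL,
                         climate_path = NULL,
                         durations = 4:9, detrend = FALSE,
                         basis = "time_mean", log_base = "natural",
                         out_dir = NULL, n_sites = 42L, verbose = FALSE) {
  say <- function(...) if (verbose) message("[multistab] ", ...)
  if (!is.null(preset)) {
    say("simulating preset '", preset, "' (seed ", seed, ")")
    sim <- generate_dataset(synthetic_preset(preset, seed = seed,
                                             n_sites = n_sites))
    cover <- sim$cover; biomass <- sim$biomass; climate <- sim$climate
  } else {
    if (is.null(cover_path) || is.null(biomass_path))
      stop("need either a preset or both cover_path and biomass_path")
    say("reading ", cover_path, " and ", biomass_path)
    tabs <- read_long_tables(cover_path, biomass_path)
    cover <- collapse_seasonal(tabs$cover)
    biomass <- collapse_seasonal(tabs$biomass)
    climate <- if (!is.null(climate_path))
      utils::read.csv(climate_path, stringsAsFactors = FALSE) else NULL
  }
  say("computing metrics")
  metrics <- compute_metrics(cover, biomass, durations = durations,
                             detrend = detrend, basis = basis)
  say("running inference")
  results <- analyze_metrics(metrics, log_base = log_base)

  report <- list(
    seed = seed, preset = preset, durations = durations,
    detrend = detrend, basis = basis, log_base = log_base,
    n_sites_by_duration = as.list(table(
      metrics$diversity$duration[metrics$diversity$trt == "Control"])),
    n_windows_dropped_nonfinite = results$n_dropped,
    clipped = attr(metrics, "clipped"),
    package_version = as.character(utils::packageVersion("multistab"))
  )

  out <- c(metrics, results[c("paths", "meta", "treatment_q", "slopes", "lrr")],
           list(report = report, climate = climate))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(diversity = "diversity.csv", stability = "stability.csv",
                  slopes = "slopes.csv", paths = "path_coefficients.csv",
                  meta = "meta_paths.csv", treatment_q = "treatment_q.csv",
                  lrr = "lrr.csv")
    for (nm in names(files))
      utils::write.csv(out[[nm]], file.path(out_dir, files[[nm]]),
                       row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("wrote outputs to ", out_dir)
  }
  invisible(out)
}
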