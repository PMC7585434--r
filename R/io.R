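# Long-format ingestion and data-preparation conventions:
# seasonal collapse by maximum, genus-level taxon aggregation by summed
# cover, dense zero-filled tensors per site x treatment x duration window.

.cover_cols   <- c("site_code", "block", "trt", "year_trt", "Taxon", "max_cover")
.biomass_cols <- c("site_code", "block", "trt", "year_trt", "live_mass")

.read_checked <- function(path, required, value_col) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  if (!is.numeric(df[[value_col]]))
    stop("schema error in ", basename(path), ": column ", value_col,
         " is not numeric")
  df[[value_col]] <- as.numeric(df[[value_col]])
  bad <- which(df[[value_col]] < 0)
  if (length(bad))
    stop("validation error in ", basename(path), ": negative ", value_col,
         " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  df$block <- as.integer(df$block)
  df$year_trt <- as.integer(df$year_trt)
  if (any(df$year_trt < 1))
    stop("validation error in ", basename(path), ": year_trt must be >= 1")
  df
}

.squish <- function(x) gsub("\\s+", " ", trimws(x))

#' Read long-format cover and biomass tables
#'
#' Cover columns: `site_code, block, trt, year_trt, Taxon, max_cover`
#' (optional `season`). Biomass columns: `site_code, block, trt, year_trt,
#' live_mass` (optional `season`). Treatments must be `Control` or `NPK`.
#' Rows with negative cover or biomass are rejected with the offending row
#' number; taxon labels are whitespace-normalized.
#'
#' @param cover_path,biomass_path paths to CSV files.
#' @return list with data frames `cover` and `biomass`.
#' @export
read_long_tables <- function(cover_path, biomass_path) {
  cover   <- .read_checked(cover_path, .cover_cols, "max_cover")
  biomass <- .read_checked(biomass_path, .biomass_cols, "live_mass")
  cover$Taxon <- .squish(cover$Taxon)
  for (df_name in c("cover", "biomass")) {
    trt <- get(df_name)$trt
    bad <- setdiff(unique(trt), c("Control", "NPK"))
    if (length(bad))
      stop("validation error: unknown treatment label(s) ",
           paste(bad, collapse = ", "), " (expected Control / NPK)")
  }
  list(cover = cover, biomass = biomass)
}

#' Collapse multi-season samplings to one annual record
#'
#' Sites with strongly seasonal communities are sampled more than once per
#' year; the annual value retained is the maximum over seasons (for both
#' species cover and biomass; the biomass rule is configurable to `"sum"`).
#' Tables without a `season` column pass through unchanged, so the operation
#' is idempotent.
#'
#' @param df long-format cover or biomass data frame.
#' @param rule `"max"` (default) or `"sum"`, applied over seasons.
#' @return data frame with one record per key and no `season` column.
#' @export
collapse_seasonal <- function(df, rule = c("max", "sum")) {
  rule <- match.arg(rule)
  if (!"season" %in% names(df)) return(df)
  value_col <- intersect(c("max_cover", "live_mass"), names(df))
  if (length(value_col) != 1)
    stop("expected exactly one of max_cover / live_mass in table")
  keys <- setdiff(names(df), c("season", value_col))
  fun <- if (rule == "max") max else sum
  out <- stats::aggregate(df[value_col], df[keys], fun)
  out <- out[do.call(order, out[keys]), c(keys, value_col)]
  rownames(out) <- NULL
  out
}

#' Aggregate taxa into consistent groups
#'
#' Taxonomy is adjusted for consistent naming over time within sites,
#' typically by aggregating to genus when individuals were not identified
#' to species in all years. Covers of taxa sharing a group label within a
#' subplot-year are summed (cover is areal; summation follows the
#' multilayer convention); taxa absent from `mapping` map to themselves,
#' so total summed cover per subplot-year is conserved.
#'
#' @param cover long-format cover data frame.
#' @param mapping named character vector, `names` = observed taxon,
#'   value = group label.
#' @return aggregated cover data frame.
#' @export
aggregate_taxa <- function(cover, mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  hit <- match(cover$Taxon, names(mapping))
  cover$Taxon <- ifelse(is.na(hit), cover$Taxon, unname(mapping[hit]))
  keys <- setdiff(names(cover), "max_cover")
  out <- stats::aggregate(cover["max_cover"], cover[keys], sum)
  out <- out[do.call(order, out[keys]), c(keys, "max_cover")]
  rownames(out) <- NULL
  out
}

#' Assemble a dense community tensor for one site, treatment and duration
#'
#' Selects post-treatment years `1..duration_years` of one site/treatment,
#' checks completeness (every subplot must have a biomass record for every
#' year of the window), and builds a dense zero-filled cover array over the
#' union of taxa observed in the window, with the aligned biomass matrix.
#'
#' @param cover,biomass long-format data frames (already seasonally
#'   collapsed).
#' @param site_id,treatment site and treatment to select.
#' @param duration_years window length d (years 1..d).
#' @return a [community_tensor()].
#' @export
assemble_tensor <- function(cover, biomass, site_id, treatment, duration_years) {
  d <- as.integer(duration_years)
  cc <- cover[cover$site_code == site_id & cover$trt == treatment &
                cover$year_trt <= d, , drop = FALSE]
  bb <- biomass[biomass$site_code == site_id & biomass$trt == treatment &
                  biomass$year_trt <= d, , drop = FALSE]
  if (!nrow(bb))
    stop("no biomass records for ", site_id, " / ", treatment)
  blocks <- sort(unique(bb$block))
  K <- length(blocks)
  if (K < 2) stop("size error: fewer than 2 subplots for ", site_id)
  if (d < 2) stop("size error: duration must be >= 2 years")

  have <- paste(bb$block, bb$year_trt)
  need <- as.vector(outer(blocks, seq_len(d), paste))
  gaps <- setdiff(need, have)
  if (length(gaps))
    stop("incompleteness error for ", site_id, " / ", treatment,
         ": missing subplot-year(s) [block year]: ",
         paste(gaps, collapse = "; "))
  if (anyDuplicated(have))
    stop("duplicate biomass records for ", site_id, " / ", treatment)

  bm <- matrix(0, K, d, dimnames = list(blocks, seq_len(d)))
  bm[cbind(match(bb$block, blocks), bb$year_trt)] <- bb$live_mass

  species <- sort(unique(cc$Taxon))
  if (!length(species))
    stop("no cover records for ", site_id, " / ", treatment,
         " in years 1..", d)
  key <- paste(cc$Taxon, cc$block, cc$year_trt)
  if (anyDuplicated(key))
    stop("duplicate cover records (collapse seasons first?) for ",
         site_id, " / ", treatment)
  arr <- array(0, dim = c(length(species), K, d),
               dimnames = list(species, blocks, seq_len(d)))
  arr[cbind(match(cc$Taxon, species), match(cc$block, blocks), cc$year_trt)] <-
    cc$max_cover

  community_tensor(arr, bm, site_id, treatment)
}
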