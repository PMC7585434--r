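#' Community tensor: species x subplot x year covers plus subplot x year biomass
#'
#' The unit of all metric computation: one site, one treatment arm, one
#' duration window of contiguous post-treatment years 1..d. Cover is areal
#' percent cover per species (summed cover may exceed 100 for multilayer
#' canopies); biomass is live aboveground mass in g m-2. Species absent from
#' a subplot-year carry cover 0 (true zeros within the observation window).
#'
#' @param cover numeric array `[species, subplot, year]`, percent cover,
#'   with dimnames on the species margin.
#' @param biomass numeric matrix `[subplot, year]`, g m-2.
#' @param site_id site label.
#' @param treatment `"Control"` or `"NPK"`.
#' @return An object of class `community_tensor`.
#' @export
community_tensor <- function(cover, biomass, site_id, treatment) {
  if (!is.array(cover) || length(dim(cover)) != 3L)
    stop("`cover` must be a 3-d array [species, subplot, year]")
  if (!is.matrix(biomass))
    stop("`biomass` must be a matrix [subplot, year]")
  x <- structure(
    list(
      site_id        = as.character(site_id),
      treatment      = match.arg(treatment, c("Control", "NPK")),
      species        = dimnames(cover)[[1]],
      cover          = cover,
      biomass        = biomass,
      n_subplots     = dim(cover)[2],
      duration_years = dim(cover)[3]
    ),
    class = "community_tensor"
  )
  validate_community_tensor(x)
}

#' @rdname community_tensor
#' @param x a `community_tensor`.
#' @export
validate_community_tensor <- function(x) {
  d <- dim(x$cover)
  if (is.null(x$species) || length(x$species) != d[1])
    stop("cover array must carry species dimnames")
  if (!all(dim(x$biomass) == d[2:3]))
    stop("biomass matrix [", paste(dim(x$biomass), collapse = " x "),
         "] does not align with cover subplot/year dims [",
         paste(d[2:3], collapse = " x "), "]")
  if (d[2] < 2) stop("size error: need at least 2 subplots, got ", d[2])
  if (d[3] < 2) stop("size error: need at least 2 years, got ", d[3])
  if (anyNA(x$cover) || anyNA(x$biomass))
    stop("missing values are not allowed inside a community tensor")
  if (any(x$cover < 0)) stop("negative cover in tensor")
  if (any(x$biomass < 0)) stop("negative biomass in tensor")
  x
}

#' @export
print.community_tensor <- function(x, ...) {
  cat("community_tensor:", x$site_id, "/", x$treatment, "\n")
  cat("  ", length(x$species), "species x", x$n_subplots, "subplots x",
      x$duration_years, "years\n")
  cat("  mean summed cover:",
      round(mean(apply(x$cover, c(2, 3), sum)), 1), "% ;",
      "mean biomass:", round(mean(x$biomass), 1), "g m-2\n")
  invisible(x)
}

#' Write a community tensor back to long-format tables
#'
#' Inverse of [assemble_tensor()]: emits cover rows only for non-zero cells
#' (absences are implicit) and one biomass row per subplot-year, using the
#' same CSV schema that [read_long_tables()] consumes, so that a write/read
#' round trip reproduces the tensor exactly.
#'
#' @param tensor a `community_tensor`.
#' @return list with data frames `cover` and `biomass`.
#' @export
tensor_to_long <- function(tensor) {
  stopifnot(inherits(tensor, "community_tensor"))
  dn  <- dimnames(tensor$cover)
  idx <- which(tensor$cover > 0, arr.ind = TRUE)
  cover <- data.frame(
    site_code = tensor$site_id,
    block     = as.integer(idx[, 2]),
    trt       = tensor$treatment,
    year_trt  = as.integer(idx[, 3]),
    Taxon     = dn[[1]][idx[, 1]],
    max_cover = tensor$cover[idx],
    stringsAsFactors = FALSE
  )
  cover <- cover[order(cover$block, cover$year_trt, cover$Taxon), ]
  rownames(cover) <- NULL
  K <- tensor$n_subplots; d <- tensor$duration_years
  biomass <- data.frame(
    site_code = tensor$site_id,
    block     = rep(seq_len(K), each = d),
    trt       = tensor$treatment,
    year_trt  = rep(seq_len(d), K),
    live_mass = as.vector(t(tensor$biomass)),
    stringsAsFactors = FALSE
  )
  list(cover = cover, biomass = biomass)
}
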