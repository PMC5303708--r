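# Pixel counting, percentages, physical-area conversion, per-plant CSV
# records.

#' Count pixels per segmentation class
#'
#' @param mask a [label_mask()].
#' @return An object of class `class_counts` with integer fields
#'   `pixels_green`, `pixels_dead`, `pixels_background`, `total_pixels`;
#'   the three class counts always sum to the total.
#' @export
count_pixels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  lab <- mask$labels
  counts <- tabulate(lab + 1L, nbins = 3L) # codes 0,1,2 -> bins 1,2,3
  structure(list(pixels_green = counts[CLASS_GREEN + 1L],
                 pixels_dead = counts[CLASS_DEAD + 1L],
                 pixels_background = counts[CLASS_BACKGROUND + 1L],
                 total_pixels = length(lab)),
            class = "class_counts")
}

#' Express class counts as percentages
#'
#' Two denominators are reported: the whole image (`of_image`, sums to 100)
#' and the plant silhouette only (`of_plant`, green + dead = 100). When the
#' plant area is zero the of-plant percentages are `NA`, never 0/0.
#'
#' @param counts a `class_counts` from [count_pixels()].
#' @return A list with numeric vectors `of_image` (green, dead, background)
#'   and `of_plant` (green, dead), in percent.
#' @export
to_percentages <- function(counts) {
  stopifnot(inherits(counts, "class_counts"))
  if (counts$total_pixels <= 0L)
    stop("total_pixels must be positive", call. = FALSE)
  tot <- counts$total_pixels
  of_image <- 100 * c(green = counts$pixels_green,
                      dead = counts$pixels_dead,
                      background = counts$pixels_background) / tot
  plant <- counts$pixels_green + counts$pixels_dead
  of_plant <- if (plant > 0L) {
    100 * c(green = counts$pixels_green, dead = counts$pixels_dead) / plant
  } else c(green = NA_real_, dead = NA_real_)
  list(of_image = of_image, of_plant = of_plant)
}

#' Convert a pixel count to a physical area
#'
#' @param count non-negative pixel count.
#' @param cal an [area_calibration()].
#' @param unit `"mm2"` (native) or `"cm2"` (reporting unit; 100 mm2 = 1 cm2).
#' @return Area `count * mm_per_pixel^2`, in the requested unit.
#' @export
pixels_to_area <- function(count, cal, unit = c("mm2", "cm2")) {
  unit <- match.arg(unit)
  stopifnot(inherits(cal, "area_calibration"))
  if (any(!is.finite(count)) || any(count < 0))
    stop("pixel count must be non-negative", call. = FALSE)
  mm2 <- count * cal$mm_per_pixel^2
  if (unit == "cm2") mm2 / 100 else mm2
}

#' Assemble a segmentation result
#'
#' Bundles the mask with its pixel counts, percentages and provenance
#' (configuration fingerprint, seed, warning flags).
#'
#' @param mask a [label_mask()].
#' @param config the [segmentation_config()] that produced it.
#' @param kmeans optional fitted [kmeans_cluster()] result.
#' @param stretch_params optional fitted stretch parameters.
#' @param warnings character vector of warning flags (e.g.
#'   `"zero_foreground"`).
#' @return An object of class `segmentation_result` with fields `mask`,
#'   `counts`, `percentages`, `config_fingerprint`, `seed`, `warnings`,
#'   `kmeans`, `stretch_params`.
#' @export
segmentation_result <- function(mask, config, kmeans = NULL,
                                stretch_params = NULL,
                                warnings = character(0)) {
  stopifnot(inherits(mask, "label_mask"),
            inherits(config, "segmentation_config"))
  counts <- count_pixels(mask)
  structure(list(mask = mask, counts = counts,
                 percentages = to_percentages(counts),
                 config_fingerprint = .config_fingerprint(config),
                 seed = config$seed, warnings = warnings,
                 kmeans = kmeans, stretch_params = stretch_params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  p <- x$percentages$of_image
  cat(sprintf(paste0("<segmentation_result> '%s': %.1f%% green, %.1f%% dead,",
                     " %.1f%% background%s\n"),
              x$mask$image_source_id, p["green"], p["dead"], p["background"],
              if (length(x$warnings)) paste0(" [", paste(x$warnings,
                                                         collapse = ","), "]")
              else ""))
  invisible(x)
}

# Column dictionary for per-plant records. Order is part of the CSV contract.
.record_columns <- c(
  "plant_id", "genotype", "treatment", "replicate", "time_point",
  "pixels_green", "pixels_dead", "pixels_background", "total_pixels",
  "pct_green_image", "pct_dead_image", "pct_green_plant", "pct_dead_plant",
  "green_area_mm2", "dead_area_mm2",
  "ndvi", "height_cm", "shb_g", "glb_g", "dlb_g", "iv_score", "ve_score"
)

#' Per-plant record column dictionary
#'
#' The fixed column order used by [write_records()] and produced by
#' [cmd_segment()]: identifiers (`plant_id`, `genotype`, `treatment`,
#' `replicate`, `time_point`), pixel counts, of-image and of-plant
#' percentages, projected areas in mm2, then manually measured traits
#' (NDVI, plant height in cm, shoot / green leaf / dead leaf biomass in
#' g per plant, initial-vigor and visual-evaluation scores on 1-5 scales).
#'
#' @return Character vector of column names.
#' @export
record_columns <- function() .record_columns

#' Write per-plant observation records to CSV
#'
#' One row per plant and time point, in the fixed column order of
#' [record_columns()] (missing columns are added as empty). Missing values
#' are written as empty cells; zero is never used as a missingness sentinel.
#' The file round-trips through [read_records()]: ids string-exact, counts
#' integer-exact, real values to full precision.
#'
#' @param records a data.frame of per-plant observations.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  for (col in .record_columns)
    if (is.null(records[[col]])) records[[col]] <- rep(NA, nrow(records))
  records <- records[, .record_columns, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write records to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Read per-plant observation records from CSV
#'
#' @param path CSV written by [write_records()] (or hand-assembled with the
#'   same header).
#' @return A data.frame; empty cells become `NA`.
#' @export
read_records <- function(path) {
  if (!file.exists(path))
    stop("records file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
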