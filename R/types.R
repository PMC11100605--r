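#' Calibrated multi-channel image field
#'
#' An `image_stack` bundles the co-registered 2D channels of one imaged
#' tissue field: a nuclear stain ("nucleus"), an insulin protein channel
#' ("insulin"), and one or more mRNA channels named by gene. All channels
#' share the same height x width; intensities are finite and non-negative.
#'
#' Coordinate convention used throughout the package: row-major, 0-based,
#' pixel centers at integer coordinates. `x` runs along columns, `y` along
#' rows; sub-pixel positions are continuous in this frame.
#'
#' @param channels named list of numeric matrices, identical dimensions.
#' @param pixel_edge_um physical edge length of one pixel in micrometres.
#' @param field_id free-text identifier for the field.
#' @return an object of class `image_stack`.
#' @examples
#' st <- image_stack(list(nucleus = matrix(0, 8, 8), insulin = matrix(1, 8, 8)),
#'                   pixel_edge_um = 0.03, field_id = "demo")
#' dim(st$channels$nucleus)
#' @export
image_stack <- function(channels, pixel_edge_um = 0.03, field_id = "field") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("`channels` must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("all channels must be 2D matrices")
  d0 <- dims[[1L]]
  for (d in dims)
    if (!identical(d, d0)) stop("all channels must share identical dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(is.finite(ch))) stop("channel '", nm, "' has non-finite values")
    if (any(ch < 0)) stop("channel '", nm, "' has negative intensities")
  }
  if (!is.numeric(pixel_edge_um) || length(pixel_edge_um) != 1L ||
      !is.finite(pixel_edge_um) || pixel_edge_um <= 0)
    stop("`pixel_edge_um` must be a single positive number")
  structure(list(channels = channels,
                 pixel_edge_um = as.numeric(pixel_edge_um),
                 field_id = as.character(field_id)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat("<image_stack> field '", x$field_id, "': ", d[1L], " x ", d[2L],
      " px (", x$pixel_edge_um, " um/px)\n", sep = "")
  cat("  channels: ", paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Integer-labelled segmentation mask
#'
#' Wraps a 2D integer matrix of labels (0 = background, positive integers =
#' objects) together with the kind of object segmented, `"nucleus"` or
#' `"cell"`.
#'
#' @param labels integer matrix with values >= 0.
#' @param kind `"nucleus"` or `"cell"`.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, kind = c("nucleus", "cell")) {
  kind <- match.arg(kind)
  if (is.null(dim(labels))) stop("`labels` must be a matrix")
  if (any(!is.finite(labels))) stop("labels must be finite")
  if (any(labels < 0)) stop("labels must be >= 0")
  if (any(labels != round(labels))) stop("labels must be integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, kind = kind), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> kind '", x$kind, "': ", nrow(x$labels), " x ",
      ncol(x$labels), " px, ", length(mask_ids(x)), " object(s)\n", sep = "")
  invisible(x)
}

#' Label ids present in a mask
#' @param mask a `label_mask`.
#' @return sorted integer vector of positive label ids.
#' @export
mask_ids <- function(mask) {
  u <- sort(unique(as.integer(mask$labels)))
  u[u > 0L]
}

#' Per-label pixel areas
#' @param mask a `label_mask`.
#' @return named integer vector, names = label ids.
#' @export
mask_areas <- function(mask) {
  v <- mask$labels[mask$labels > 0L]
  if (length(v) == 0L) return(integer(0))
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}

#' Convert a pixel area to square micrometres
#'
#' The field calibration used by the pipeline: a mask of `area_px` pixels
#' with pixel edge `pixel_edge_um` covers `area_px * pixel_edge_um^2` square
#' micrometres. At the default 0.03 um/px, the 3000-pixel minimum-nucleus
#' filter corresponds to 2.7 um^2.
#'
#' @param area_px pixel count, >= 0.
#' @param pixel_edge_um pixel edge length in micrometres, > 0.
#' @return area in square micrometres.
#' @examples
#' mask_area_um2(3000, 0.03)  # 2.7
#' @export
mask_area_um2 <- function(area_px, pixel_edge_um = 0.03) {
  if (any(!is.finite(pixel_edge_um)) || any(pixel_edge_um <= 0))
    stop("`pixel_edge_um` must be positive")
  if (any(area_px < 0)) stop("`area_px` must be >= 0")
  area_px * pixel_edge_um^2
}

#' Pipeline configuration
#'
#' All tunable parameters of the quantification pipeline, with defaults.
#' `min_nucleus_area_px = 3000` and the 0.03 um/px calibration are matched
#' to the source protocol's stated mask filter (3000 px, about 2.7 um^2);
#' everything else is an explicit, documented choice (see the package
#' vignette).
#'
#' @param min_nucleus_area_px nuclei with area strictly below this are removed.
#' @param duplicate_iou_threshold IoU at or above which two masks are
#'   duplicates (only meaningful for overlapping mask proposals).
#' @param cell_expansion_radius_px radial extension of the nuclear boundary
#'   used to predict the cell boundary. No universal value exists; set it per
#'   dataset.
#' @param histogram_bin_count,savgol_window_bins,savgol_polyorder insulin
#'   histogram bin count and Savitzky-Golay smoothing window (odd, in bins)
#'   and polynomial order.
#' @param log_sigma_min_px,log_sigma_max_px,log_n_scales,log_threshold
#'   Laplacian-of-Gaussian scale range (px), number of geometric scale steps,
#'   and detection threshold on the scale-normalized response. The range must
#'   cover the largest structure the outlier fence should see as a single
#'   object (autofluorescent blobs are several times larger than the PSF);
#'   a range that stops at the PSF scale fragments big blobs into several
#'   moderate foci that can slip under the fence.
#' @param aperture_radius_mult focus photometry disk radius as a multiple of
#'   the detected scale.
#' @param unit_intensity_bin_width width of the intensity bins used to find
#'   the single-mRNA modal bin; `NULL` = max intensity / 30.
#' @param tukey_k Tukey fence multiplier for autofluorescence outliers. The
#'   default 1.5 is the textbook value; when genuine multi-mRNA foci are
#'   expected, set `k` large enough that the fence clears `k_max * I1` (see
#'   the vignette's discussion of this trade-off).
#' @param tukey_on `"focus_intensity"` (default): the fence is applied to
#'   per-focus intensities. `"cell_counts"`: applied instead to provisional
#'   per-cell totals, flagging every focus of cells whose count is beyond
#'   the fence.
#' @param count_clamp_min minimum mRNA count assigned to a retained focus.
#' @param unimodal_fallback `"error"` (default) or `"otsu"`: behaviour when
#'   the smoothed insulin histogram has no two modes.
#' @param connectivity pixel connectivity for labelling, 4 or 8.
#' @param random_seed recorded in the run manifest (the pipeline itself is
#'   deterministic; only the simulator consumes randomness).
#' @param pixel_edge_um physical pixel edge length in micrometres.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(min_nucleus_area_px = 3000,
                            duplicate_iou_threshold = 0.5,
                            cell_expansion_radius_px = 10,
                            histogram_bin_count = 64,
                            savgol_window_bins = 11,
                            savgol_polyorder = 3,
                            log_sigma_min_px = 1.0,
                            log_sigma_max_px = 6.0,
                            log_n_scales = 6,
                            log_threshold = 15,
                            aperture_radius_mult = 2,
                            unit_intensity_bin_width = NULL,
                            tukey_k = 1.5,
                            tukey_on = c("focus_intensity", "cell_counts"),
                            count_clamp_min = 1,
                            unimodal_fallback = c("error", "otsu"),
                            connectivity = 8,
                            random_seed = 1L,
                            pixel_edge_um = 0.03) {
  cfg <- list(min_nucleus_area_px = min_nucleus_area_px,
              duplicate_iou_threshold = duplicate_iou_threshold,
              cell_expansion_radius_px = cell_expansion_radius_px,
              histogram_bin_count = histogram_bin_count,
              savgol_window_bins = savgol_window_bins,
              savgol_polyorder = savgol_polyorder,
              log_sigma_min_px = log_sigma_min_px,
              log_sigma_max_px = log_sigma_max_px,
              log_n_scales = log_n_scales,
              log_threshold = log_threshold,
              aperture_radius_mult = aperture_radius_mult,
              unit_intensity_bin_width = unit_intensity_bin_width,
              tukey_k = tukey_k,
              tukey_on = match.arg(tukey_on),
              count_clamp_min = count_clamp_min,
              unimodal_fallback = match.arg(unimodal_fallback),
              connectivity = connectivity,
              random_seed = as.integer(random_seed),
              pixel_edge_um = pixel_edge_um)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$min_nucleus_area_px >= 1,
            cfg$duplicate_iou_threshold > 0, cfg$duplicate_iou_threshold <= 1,
            cfg$cell_expansion_radius_px >= 0,
            cfg$histogram_bin_count >= 4,
            cfg$savgol_window_bins %% 2 == 1,
            cfg$savgol_window_bins > cfg$savgol_polyorder,
            cfg$log_sigma_min_px > 0,
            cfg$log_sigma_min_px < cfg$log_sigma_max_px,
            cfg$log_n_scales >= 2,
            cfg$aperture_radius_mult > 0,
            cfg$tukey_k > 0,
            cfg$count_clamp_min >= 0,
            cfg$connectivity %in% c(4, 8),
            cfg$pixel_edge_um > 0)
  if (!is.null(cfg$unit_intensity_bin_width))
    stopifnot(cfg$unit_intensity_bin_width > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys missing from the file keep their [pipeline_config()] defaults;
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param cfg a `pipeline_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# empty prototypes for the two result tables; single source of column order
empty_cell_table <- function() {
  data.frame(field_id = character(0), cell_id = integer(0),
             nucleus_area_px = integer(0), cell_area_px = integer(0),
             insulin_mean_intensity = numeric(0),
             cell_class = character(0), stringsAsFactors = FALSE)
}

empty_focus_table <- function() {
  data.frame(field_id = character(0), focus_id = integer(0),
             gene = character(0), x = numeric(0), y = numeric(0),
             sigma = numeric(0), intensity = numeric(0),
             mrna_count = integer(0), cell_id = integer(0),
             compartment = character(0), outlier = logical(0),
             stringsAsFactors = FALSE)
}

#' Validate a cell table
#'
#' Checks the per-cell record invariants: positive unique ids, nucleus area
#' not exceeding cell area, non-negative insulin intensity, and a known
#' cell class.
#'
#' @param cells data.frame with the columns of [empty cell table][quantify_field].
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_cells <- function(cells) {
  req <- names(empty_cell_table())
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("cell table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(cells)) {
    stopifnot(all(cells$cell_id > 0),
              !anyDuplicated(cells[c("field_id", "cell_id")]),
              all(cells$nucleus_area_px <= cells$cell_area_px),
              all(cells$insulin_mean_intensity >= 0),
              all(cells$cell_class %in% c("beta", "non_beta", "unclassified")))
  }
  cells
}

#' Validate a focus table
#'
#' Checks per-focus invariants: retained (non-outlier, cell-assigned) foci
#' carry a positive mRNA count and a nuclear/cytoplasmic compartment;
#' intensities are finite.
#'
#' @param foci focus data.frame.
#' @param count_clamp_min minimum count required of retained foci.
#' @return the validated data.frame.
#' @export
validate_foci <- function(foci, count_clamp_min = 1) {
  req <- names(empty_focus_table())
  miss <- setdiff(req, names(foci))
  if (length(miss)) stop("focus table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(foci)) {
    stopifnot(all(is.finite(foci$intensity)),
              all(foci$compartment %in% c("nuclear", "cytoplasmic", "unassigned")))
    ret <- !foci$outlier & !is.na(foci$cell_id) & foci$cell_id > 0
    if (any(ret)) stopifnot(all(foci$mrna_count[ret] >= count_clamp_min))
  }
  foci
}
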