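#' Quantify one imaged field end-to-end
#'
#' Runs the full per-cell smFISH quantification on an [image_stack()]:
#' nucleus segmentation (or an externally supplied mask), mask filtering,
#' radial cell-boundary prediction, insulin-histogram beta/non-beta
#' classification, per-gene LoG spot detection, Tukey-fence outlier
#' flagging, single-mRNA unit-intensity estimation, intensity deconvolution
#' into transcript counts, cell/compartment assignment, and aggregation.
#'
#' The stage order for counting follows the method's intent: outliers are
#' flagged *before* the unit intensity is estimated and counts are assigned,
#' so autofluorescent blobs can neither shift the modal intensity bin nor be
#' counted as many mRNAs.
#'
#' @param stack an [image_stack()] with channels `nucleus`, `insulin`, and
#'   one channel per gene.
#' @param config a [pipeline_config()].
#' @param nucleus_mask optional externally supplied nucleus [label_mask()]
#'   (bypasses the built-in segmenter).
#' @param genes gene channel names; default: every channel except `nucleus`
#'   and `insulin`.
#' @param verbose log per-stage messages.
#' @return an object of class `smfish_run`: list with `cells`, `foci`,
#'   `counts` (per-cell per-gene table), `localization`, `threshold`,
#'   `units` (per-gene `unit_intensity`), `nuclei`, `cell_mask`, `config`.
#' @export
quantify_field <- function(stack, config = pipeline_config(),
                           nucleus_mask = NULL, genes = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(genes))
    genes <- setdiff(names(stack$channels), c("nucleus", "insulin"))
  if (!all(c("nucleus", "insulin") %in% names(stack$channels)))
    stop("stack must have 'nucleus' and 'insulin' channels")
  if (!length(genes)) stop("no gene channels to quantify")

  nuclei <- if (is.null(nucleus_mask)) {
    log_stage("segment", "segmenting nuclei (Otsu + watershed fallback)",
              verbose = verbose)
    segment_nuclei(stack$channels$nucleus, config)
  } else nucleus_mask
  n_before <- length(mask_ids(nuclei))
  nuclei <- filter_masks(nuclei, config$min_nucleus_area_px,
                         config$duplicate_iou_threshold)
  log_stage("segment", n_before, " nuclei in, ", length(mask_ids(nuclei)),
            " after area/duplicate filter (min area ",
            config$min_nucleus_area_px, " px)", verbose = verbose)
  cell_mask <- expand_to_cells(nuclei, config$cell_expansion_radius_px)

  intens <- measure_cell_intensity(cell_mask, stack$channels$insulin)
  cl <- classify_from_config(intens, config, verbose = verbose)
  log_stage("celltype", "insulin threshold ", format(cl$threshold), "; ",
            sum(cl$classes == "beta"), " beta / ",
            sum(cl$classes == "non_beta"), " non-beta", verbose = verbose)

  areas_n <- mask_areas(nuclei)
  areas_c <- mask_areas(cell_mask)
  ids <- mask_ids(cell_mask)
  cells <- data.frame(field_id = stack$field_id, cell_id = ids,
                      nucleus_area_px = as.integer(areas_n[as.character(ids)]),
                      cell_area_px = as.integer(areas_c[as.character(ids)]),
                      insulin_mean_intensity = as.numeric(intens[as.character(ids)]),
                      cell_class = as.character(cl$classes[as.character(ids)]),
                      stringsAsFactors = FALSE)
  validate_cells(cells)

  units <- list()
  foci_all <- list()
  for (g in genes) {
    f <- detect_spots(stack$channels[[g]],
                      sigma_min_px = config$log_sigma_min_px,
                      sigma_max_px = config$log_sigma_max_px,
                      threshold = config$log_threshold,
                      n_scales = config$log_n_scales,
                      aperture_radius_mult = config$aperture_radius_mult)
    log_stage("spots", g, ": ", nrow(f), " foci detected", verbose = verbose)
    if (!nrow(f)) {
      units[[g]] <- NULL
      next
    }
    f$gene <- g
    if (config$tukey_on == "focus_intensity") {
      f <- tukey_filter(f, config$tukey_k)
    } else f$outlier <- rep(FALSE, nrow(f))
    units[[g]] <- estimate_unit_intensity(f, config$unit_intensity_bin_width)
    f <- deconvolve_counts(f, units[[g]], config$count_clamp_min)
    f <- assign_spots(f, cell_mask, nuclei)
    if (config$tukey_on == "cell_counts")
      f <- tukey_filter_counts(f, config$tukey_k)
    log_stage("spots", g, ": ", sum(f$outlier), " outliers flagged; I1 = ",
              format(units[[g]]$I1), verbose = verbose)
    foci_all[[g]] <- f
  }
  foci <- if (length(foci_all)) do.call(rbind, c(unname(foci_all),
                                                 list(make.row.names = FALSE)))
  else empty_focus_table()
  if (nrow(foci)) {
    foci$field_id <- stack$field_id
    foci$focus_id <- seq_len(nrow(foci))  # unique across genes
    foci <- foci[c("field_id", "focus_id", "gene", "x", "y", "sigma",
                   "intensity", "mrna_count", "cell_id", "compartment",
                   "outlier")]
  } else foci <- empty_focus_table()
  validate_foci(foci, config$count_clamp_min)

  counts <- per_cell_counts(foci, cells, genes = genes)
  loc <- localization_fractions(counts)
  structure(list(cells = cells, foci = foci, counts = counts,
                 localization = loc, threshold = cl$threshold,
                 units = units, nuclei = nuclei, cell_mask = cell_mask,
                 config = config, field_id = stack$field_id),
            class = "smfish_run")
}

#' @export
print.smfish_run <- function(x, ...) {
  cat("<smfish_run> field '", x$field_id, "': ", nrow(x$cells), " cells (",
      sum(x$cells$cell_class == "beta"), " beta), ", nrow(x$foci),
      " foci across ", length(unique(x$foci$gene)), " gene(s)\n", sep = "")
  invisible(x)
}

#' Write all outputs of a quantification run
#'
#' Writes the result tables ([write_tables()]), the label masks, per-group
#' statistics and localization summaries, and the run manifest into a
#' directory. Deterministic: identical runs produce byte-identical files.
#'
#' @param run an `smfish_run`.
#' @param out_dir output directory.
#' @param seed seed to record in the manifest.
#' @return character vector of written files, invisibly.
#' @export
write_run <- function(run, out_dir, seed = run$config$random_seed) {
  stopifnot(inherits(run, "smfish_run"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  genes <- sort(unique(run$counts$gene))
  files <- write_tables(run$cells, run$foci, out_dir, genes = genes)
  p_loc <- file.path(out_dir, "localization.csv")
  write.csv(run$localization$groups, p_loc, row.names = FALSE, quote = FALSE)
  p_stats <- file.path(out_dir, "group_stats.csv")
  write.csv(group_stats(run$counts), p_stats, row.names = FALSE, quote = FALSE)
  p_nuc <- file.path(out_dir, "nuclei_labels.tif")
  write_label_mask(run$nuclei, p_nuc)
  p_cell <- file.path(out_dir, "cell_labels.tif")
  write_label_mask(run$cell_mask, p_cell)
  p_man <- file.path(out_dir, "manifest.yaml")
  write_manifest(p_man, run$config, seed = seed,
                 inputs = list(field_id = run$field_id))
  invisible(c(files, p_loc, p_stats, p_nuc, p_cell, p_man))
}

# per-gene beta vs non-beta Mann-Whitney on per-cell totals
group_stats <- function(counts) {
  out <- lapply(sort(unique(counts$gene)), function(g) {
    d <- counts[counts$gene == g, , drop = FALSE]
    a <- d$total[d$cell_class == "beta"]
    b <- d$total[d$cell_class == "non_beta"]
    if (!length(a) || !length(b)) return(NULL)
    r <- mann_whitney(a, b, group_a = "beta", group_b = "non_beta", gene = g,
                      statistic_name = "per_cell_total_count")
    data.frame(gene = g, statistic_name = r$statistic_name,
               group_a = r$group_a, group_b = r$group_b,
               n_a = r$n_a, n_b = r$n_b, U_statistic = r$U_statistic,
               p_value = r$p_value, median_a = r$median_a,
               median_b = r$median_b, method = r$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(0), statistic_name = character(0),
                      group_a = character(0), group_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      U_statistic = numeric(0), p_value = numeric(0),
                      median_a = numeric(0), median_b = numeric(0),
                      method = character(0), stringsAsFactors = FALSE)
  out
}

#' Rebuild the summary report from a run directory
#'
#' Re-reads `cells.csv` and `foci.csv` from a completed run directory,
#' recomputes the per-cell count table, localization summaries and group
#' statistics from scratch, and rewrites `counts.csv`, `localization.csv`
#' and `group_stats.csv`. Every number in the report is therefore
#' re-derivable from the two primary tables.
#'
#' @param run_dir directory written by [write_run()].
#' @return invisible list with the recomputed `counts`, `localization`,
#'   `group_stats` tables.
#' @export
report <- function(run_dir) {
  cells <- read.csv(file.path(run_dir, "cells.csv"),
                    stringsAsFactors = FALSE)
  foci <- read.csv(file.path(run_dir, "foci.csv"), stringsAsFactors = FALSE)
  if (!nrow(foci)) foci <- empty_focus_table()
  if (!nrow(cells)) cells <- empty_cell_table()
  cells$field_id <- as.character(cells$field_id)
  foci$field_id <- as.character(foci$field_id)
  counts <- per_cell_counts(foci, cells)
  loc <- localization_fractions(counts)
  gs <- group_stats(counts)
  write.csv(counts, file.path(run_dir, "counts.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(loc$groups, file.path(run_dir, "localization.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(gs, file.path(run_dir, "group_stats.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(list(counts = counts, localization = loc, group_stats = gs))
}
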