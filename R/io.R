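#' Load a multi-channel image stack from a TIFF file
#'
#' Pages are matched to channel names in order. Extra pages beyond the
#' channel map are ignored with a warning; too few pages is an error.
#'
#' @param path TIFF file (multi-page, grayscale, uncompressed).
#' @param channel_map character vector of channel names in page order, e.g.
#'   `c("nucleus", "insulin", "Cd274", "Mx1")`.
#' @param pixel_edge_um pixel edge length in micrometres.
#' @param field_id identifier; defaults to the file name without extension.
#' @return an [image_stack()].
#' @export
load_image_stack <- function(path, channel_map, pixel_edge_um = 0.03,
                             field_id = NULL) {
  if (!length(channel_map)) stop("`channel_map` must name at least one channel")
  pages <- read_tiff(path)
  if (length(pages) < length(channel_map))
    stop("plane count < channel count: file has ", length(pages),
         " plane(s), channel map names ", length(channel_map))
  if (length(pages) > length(channel_map))
    warning("ignoring ", length(pages) - length(channel_map),
            " plane(s) beyond the channel map")
  if (is.null(field_id))
    field_id <- sub("\\.[^.]*$", "", basename(path))
  channels <- stats::setNames(pages[seq_along(channel_map)], channel_map)
  image_stack(channels, pixel_edge_um = pixel_edge_um, field_id = field_id)
}

#' Write an image stack to a multi-page TIFF
#'
#' Channels are written in their list order as 64-bit float pages, so a
#' write/read round trip reproduces the in-memory arrays bit-for-bit.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  write_tiff(stack$channels, path, type = "float64")
}

#' Load an integer label mask from a TIFF or PNG file
#'
#' @param path `.tif`/`.tiff` (any supported grayscale layout) or `.png`
#'   (gray; values are rescaled back to integers by bit depth).
#' @param kind `"nucleus"` or `"cell"`.
#' @return a [label_mask()].
#' @export
load_label_mask <- function(path, kind = c("nucleus", "cell")) {
  kind <- match.arg(kind)
  ext <- tolower(sub(".*\\.", "", path))
  m <- if (ext %in% c("tif", "tiff")) {
    pages <- read_tiff(path)
    if (length(pages) != 1L) stop("label mask TIFF must have exactly one page")
    pages[[1L]]
  } else if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1L]  # gray stored with alpha/extra
    round(v * 65535)
  } else stop("unsupported label mask format: .", ext)
  label_mask(round(m), kind = kind)
}

#' Write a label mask to a 16-bit TIFF
#' @param mask a [label_mask()] with labels below 65536.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  write_tiff(mask$labels, path, type = "uint16")
}

order_stable <- function(...) order(..., method = "radix")

#' Write the result tables of a run
#'
#' Writes `cells.csv`, `foci.csv` and `counts.csv` (per-cell per-gene totals
#' with the nuclear/cytoplasmic split) with deterministic column and row
#' order, so identical inputs give byte-identical files.
#'
#' @param cells cell table (see [quantify_field()]).
#' @param foci focus table.
#' @param out_dir output directory, created if needed.
#' @param genes gene names for the count table; default: those in `foci`.
#' @return character vector of the files written, invisibly.
#' @export
write_tables <- function(cells, foci, out_dir, genes = NULL) {
  validate_cells(cells)
  validate_foci(foci, count_clamp_min = 0)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  cells <- cells[order_stable(cells$field_id, cells$cell_id), , drop = FALSE]
  foci <- foci[order_stable(foci$field_id, foci$gene, foci$focus_id), , drop = FALSE]
  counts <- per_cell_counts(foci, cells, genes = genes)
  paths <- file.path(out_dir, c("cells.csv", "foci.csv", "counts.csv"))
  for (p in seq_along(paths)) {
    df <- list(cells, foci, counts)[[p]]
    rownames(df) <- NULL
    write.csv(df, paths[p], row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(paths)
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and input identifiers of
#' a run as YAML next to its outputs, for reproducibility.
#'
#' @param path output YAML path.
#' @param config a `pipeline_config`.
#' @param seed integer seed recorded for the run.
#' @param inputs named list of input descriptions (paths, field ids...).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed = config$random_seed,
                           inputs = list()) {
  man <- list(package = "smfishq",
              version = as.character(utils::packageVersion("smfishq")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = as.integer(seed),
              inputs = inputs,
              config = unclass(config))
  yaml::write_yaml(man, path)
  invisible(path)
}

log_stage <- function(stage, ..., verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}
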