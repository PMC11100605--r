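#' Otsu's threshold
#'
#' Maximizes between-class variance on a 256-bin histogram of the input.
#' Returns the threshold on the original intensity scale; values strictly
#' above it are foreground.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram resolution.
#' @return threshold value, or `NA` if the input has no spread.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(NA_real_)
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b[-n_bins])  # threshold between bins
  br[k + 1L]
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Classical fallback segmenter for when no externally produced nucleus mask
#' is supplied: global Otsu threshold, then marker-based watershed on the
#' Euclidean distance transform to split touching nuclei. Deterministic for
#' a fixed input. Externally supplied masks (e.g. from a foundation-model
#' segmenter) bypass this entirely via [load_label_mask()].
#'
#' @param nucleus_channel 2D intensity matrix.
#' @param params a [pipeline_config()] (uses `connectivity`).
#' @param marker_height_frac markers are the pixels whose distance to the
#'   background exceeds this fraction of their component's maximum distance.
#' @return a nucleus [label_mask()].
#' @export
segment_nuclei <- function(nucleus_channel, params = pipeline_config(),
                           marker_height_frac = 0.5) {
  stopifnot(all(is.finite(nucleus_channel)), all(nucleus_channel >= 0))
  empty <- label_mask(matrix(0L, nrow(nucleus_channel), ncol(nucleus_channel)),
                      "nucleus")
  thr <- otsu_threshold(nucleus_channel)
  if (is.na(thr)) return(empty)
  fg <- matrix(as.integer(nucleus_channel > thr), nrow(nucleus_channel))
  if (!any(fg > 0L)) return(empty)
  comp <- .cpp_label_components(fg, as.integer(params$connectivity))
  d <- sqrt(.cpp_edt_sq(1L - fg))  # distance of foreground to background
  # markers: per-component ridge of the distance transform
  cmax <- rep(0, max(comp))
  sel <- comp > 0L
  agg <- tapply(d[sel], comp[sel], max)
  cmax[as.integer(names(agg))] <- agg
  markers_bin <- matrix(0L, nrow(fg), ncol(fg))
  markers_bin[sel] <- as.integer(d[sel] >= pmax(1, marker_height_frac *
                                                  cmax[comp[sel]]))
  markers <- .cpp_label_components(markers_bin, as.integer(params$connectivity))
  lab <- .cpp_watershed(-d, markers, fg)
  label_mask(lab, "nucleus")
}

mask_from_list <- function(masks) {
  # flatten a list of (possibly overlapping) binary masks to a label matrix;
  # earlier masks win contested pixels
  lab <- matrix(0L, nrow(masks[[1L]]), ncol(masks[[1L]]))
  for (i in rev(seq_along(masks))) lab[masks[[i]] != 0] <- i
  lab
}

#' Remove small and duplicate nucleus masks
#'
#' Post-processing of segmentation output: objects with area strictly below
#' `min_area_px` are removed, and of any pair of masks whose intersection
#' over union reaches `duplicate_iou_threshold`, the smaller one is removed
#' (ties: the one with the smaller label id is kept). Surviving labels are
#' renumbered consecutively from 1 in their original order.
#'
#' Duplicates can only overlap when the input is a *list* of binary masks
#' (the native output shape of proposal-based segmenters); in a flat label
#' matrix distinct labels are disjoint by construction and only the area
#' filter applies.
#'
#' @param nuclei a nucleus [label_mask()], or a list of logical/0-1 matrices
#'   (one per mask proposal, may overlap).
#' @param min_area_px objects smaller than this many pixels are dropped.
#' @param duplicate_iou_threshold IoU at or above which two masks are
#'   duplicates.
#' @return a nucleus [label_mask()].
#' @export
filter_masks <- function(nuclei, min_area_px = 3000,
                         duplicate_iou_threshold = 0.5) {
  stopifnot(min_area_px >= 1, duplicate_iou_threshold > 0)
  if (inherits(nuclei, "label_mask")) {
    # labels in a flat mask are disjoint, so IoU-duplicates cannot occur:
    # only the area filter applies, and it can be done by table lookup
    ids <- mask_ids(nuclei)
    if (!length(ids)) return(nuclei)
    areas <- mask_areas(nuclei)
    surv <- ids[areas[as.character(ids)] >= min_area_px]
    relab <- integer(max(ids) + 1L)          # old label + 1 -> new label
    relab[surv + 1L] <- seq_along(surv)
    return(label_mask(matrix(relab[nuclei$labels + 1L], nrow(nuclei$labels)),
                      "nucleus"))
  }
  if (!is.list(nuclei))
    stop("`nuclei` must be a label_mask or a list of binary masks")
  masks <- lapply(nuclei, function(m) m != 0)
  areas <- vapply(masks, sum, numeric(1))
  keep <- areas >= min_area_px & areas > 0
  # duplicate removal among survivors: drop the smaller of any IoU-duplicate
  # pair; on equal area keep the smaller label id
  idx <- which(keep)
  if (length(idx) > 1L) {
    for (ii in seq_along(idx)[-length(idx)]) {
      a <- idx[ii]
      if (!keep[a]) next
      for (b in idx[idx > a]) {
        if (!keep[b]) next
        inter <- sum(masks[[a]] & masks[[b]])
        if (inter == 0) next
        iou <- inter / (areas[a] + areas[b] - inter)
        if (iou >= duplicate_iou_threshold) {
          if (areas[b] <= areas[a]) keep[b] <- FALSE else { keep[a] <- FALSE; break }
        }
      }
    }
  }
  if (!length(masks)) stop("`nuclei` list is empty")
  surv <- which(keep)
  lab <- matrix(0L, nrow(masks[[1L]]), ncol(masks[[1L]]))
  for (k in seq_along(surv)) lab[masks[[surv[k]]] & lab == 0L] <- k
  label_mask(lab, "nucleus")
}

#' Predict cell boundaries by radial expansion of nuclei
#'
#' Every background pixel within Euclidean distance `radius_px` of some
#' nucleus is assigned the label of the nearest nucleus pixel (ties go to
#' the lower label id); nucleus pixels keep their own label. This is the
#' Voronoi-constrained dilation model of the cell: each nucleus is a subset
#' of its cell and cells never overlap.
#'
#' @param nuclei a filtered nucleus [label_mask()].
#' @param radius_px expansion radius in pixels, >= 0.
#' @return a cell [label_mask()].
#' @export
expand_to_cells <- function(nuclei, radius_px) {
  stopifnot(inherits(nuclei, "label_mask"))
  if (radius_px < 0) stop("`radius_px` must be >= 0")
  label_mask(.cpp_expand_labels(nuclei$labels, radius_px), "cell")
}
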