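#' Detect diffraction-limited mRNA foci with a multi-scale LoG filter
#'
#' Computes the scale-normalized Laplacian-of-Gaussian response over a
#' geometric ladder of scales, finds local maxima in (x, y, scale) above
#' `threshold`, refines position and scale by quadratic interpolation, and
#' measures each focus's background-subtracted intensity in a disk of radius
#' `aperture_radius_mult` x the detected scale (background = median of the
#' surrounding annulus). The disk sum is divided by the analytic fraction of
#' a Gaussian's mass inside that disk, `1 - exp(-m^2/2)`, so `intensity`
#' estimates the focus's full integrated intensity above background.
#'
#' @param channel 2D intensity matrix.
#' @param sigma_min_px,sigma_max_px scale search range in pixels.
#' @param threshold detection threshold on the scale-normalized response (a
#'   matched Gaussian spot of peak amplitude A responds at about A/2).
#' @param n_scales number of geometric scale steps.
#' @param aperture_radius_mult photometry disk radius in units of the
#'   detected scale.
#' @return data.frame with columns `focus_id`, `x`, `y` (0-based, sub-pixel),
#'   `sigma`, `response`, `intensity`; zero rows if nothing detected.
#' @export
detect_spots <- function(channel, sigma_min_px = 1.0, sigma_max_px = 3.0,
                         threshold = 15, n_scales = 6L,
                         aperture_radius_mult = 2) {
  stopifnot(all(is.finite(channel)), sigma_min_px > 0,
            sigma_min_px < sigma_max_px, n_scales >= 2L)
  empty <- data.frame(focus_id = integer(0), x = numeric(0), y = numeric(0),
                      sigma = numeric(0), response = numeric(0),
                      intensity = numeric(0))
  nr <- nrow(channel); nc <- ncol(channel)
  sigmas <- exp(seq(log(sigma_min_px), log(sigma_max_px),
                    length.out = n_scales))
  resp <- lapply(sigmas, function(s)
    -s^2 * laplacian(gaussian_blur(channel, s)))

  # local maxima within each scale plane (8-neighborhood, >= with a raster
  # tie-break so symmetric plateaus yield a single candidate)
  cand <- list()
  for (si in seq_along(sigmas)) {
    m <- resp[[si]]
    ge <- m >= threshold
    if (!any(ge)) next
    shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
    ismax <- ge
    for (sh in shifts) {
      nb <- shift_mat(m, sh[1L], sh[2L], fill = -Inf)
      # strict on "later" neighbours, >= on "earlier": deterministic plateaus
      if (sh[1L] > 0 || (sh[1L] == 0 && sh[2L] > 0))
        ismax <- ismax & (m >= nb)
      else
        ismax <- ismax & (m > nb)
    }
    lo <- if (si > 1L) resp[[si - 1L]] else NULL
    hi <- if (si < length(sigmas)) resp[[si + 1L]] else NULL
    if (!is.null(lo)) ismax <- ismax & (m >= lo)
    if (!is.null(hi)) ismax <- ismax & (m >= hi)
    idx <- which(ismax)
    if (!length(idx)) next
    cand[[length(cand) + 1L]] <- data.frame(
      r = (idx - 1L) %% nr + 1L, c = (idx - 1L) %/% nr + 1L,
      si = si, response = m[idx])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)

  # greedy non-maximum suppression across scales: strongest first, suppress
  # any weaker candidate whose center falls within the stronger one's core
  cand <- cand[order(-cand$response, cand$r, cand$c, cand$si), , drop = FALSE]
  keep <- logical(nrow(cand))
  ky <- numeric(0); kx <- numeric(0); ks <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    s_i <- sigmas[cand$si[i]]
    if (length(ky)) {
      d2 <- (ky - cand$r[i])^2 + (kx - cand$c[i])^2
      lim <- (sqrt(2) * pmax(ks, s_i))^2
      if (any(d2 <= lim)) next
    }
    keep[i] <- TRUE
    ky <- c(ky, cand$r[i]); kx <- c(kx, cand$c[i]); ks <- c(ks, s_i)
  }
  cand <- cand[keep, , drop = FALSE]

  # sub-pixel and sub-scale quadratic refinement
  refine1d <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (den >= 0) return(0)           # not locally concave; keep the grid point
    max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
  }
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand$r[i]; cc <- cand$c[i]; si <- cand$si[i]
    m <- resp[[si]]
    dy <- if (r > 1L && r < nr) refine1d(m[r - 1L, cc], m[r, cc], m[r + 1L, cc]) else 0
    dx <- if (cc > 1L && cc < nc) refine1d(m[r, cc - 1L], m[r, cc], m[r, cc + 1L]) else 0
    lsig <- log(sigmas[si])
    if (si > 1L && si < length(sigmas)) {
      ds <- refine1d(resp[[si - 1L]][r, cc], m[r, cc], resp[[si + 1L]][r, cc])
      lsig <- lsig + ds * (log(sigmas[2L]) - log(sigmas[1L]))
    }
    c(y = r - 1 + dy, x = cc - 1 + dx, sigma = exp(lsig),
      response = m[r, cc])
  })
  out <- as.data.frame(do.call(rbind, out))

  out$intensity <- vapply(seq_len(nrow(out)), function(i)
    focus_intensity(channel, out$y[i], out$x[i], out$sigma[i],
                    aperture_radius_mult), numeric(1))
  out <- out[order_stable(out$y, out$x), , drop = FALSE]
  data.frame(focus_id = seq_len(nrow(out)), x = out$x, y = out$y,
             sigma = out$sigma, response = out$response,
             intensity = out$intensity)
}

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# background-subtracted, aperture-corrected disk photometry at 0-based (y, x)
focus_intensity <- function(channel, y, x, sigma, mult = 2,
                            annulus_width = 3) {
  nr <- nrow(channel); nc <- ncol(channel)
  r_in <- mult * sigma
  r_out <- r_in + annulus_width
  h <- ceiling(r_out)
  rr <- max(1L, floor(y + 1 - h)):min(nr, ceiling(y + 1 + h))
  cc <- max(1L, floor(x + 1 - h)):min(nc, ceiling(x + 1 + h))
  d2 <- outer(((rr - 1) - y)^2, ((cc - 1) - x)^2, `+`)
  block <- channel[rr, cc, drop = FALSE]
  disk <- d2 <= r_in^2
  annulus <- d2 > r_in^2 & d2 <= r_out^2
  bg <- if (any(annulus)) median(block[annulus]) else 0
  raw <- sum(block[disk] - bg)
  frac <- 1 - exp(-mult^2 / 2)  # Gaussian mass inside the disk
  raw / frac
}

#' Estimate the intensity of a single mRNA
#'
#' Bins the (non-outlier) focus intensities of one gene into equal-width
#' intervals `[0, w), [w, 2w), ...` and takes the bin holding the most foci
#' (ties: the lower-intensity bin); the unit intensity `I1` is the median
#' focus intensity within that modal bin. Works because most detected foci
#' are single mRNAs.
#'
#' @param foci focus data.frame for one gene (uses `intensity`; rows with
#'   `outlier = TRUE`, if present, are ignored).
#' @param bin_width intensity bin width; `NULL` = max intensity / 30.
#' @return an object of class `unit_intensity`: list with `gene`, `I1`,
#'   `modal_bin` = c(low, high), `n_support`.
#' @export
estimate_unit_intensity <- function(foci, bin_width = NULL) {
  if (!is.null(foci$outlier)) foci <- foci[!foci$outlier, , drop = FALSE]
  if (!nrow(foci)) stop("no (non-outlier) foci to estimate unit intensity from")
  v <- foci$intensity
  stopifnot(all(is.finite(v)), all(v >= 0))
  if (is.null(bin_width)) bin_width <- max(v) / 30
  stopifnot(bin_width > 0)
  bin <- floor(v / bin_width)             # half-open [low, high) bins
  tab <- table(bin)
  modal <- as.numeric(names(tab))[order(-as.integer(tab),
                                        as.numeric(names(tab)))][1L]
  in_modal <- bin == modal
  structure(list(gene = if (!is.null(foci$gene) && nrow(foci)) foci$gene[1L]
                 else NA_character_,
                 I1 = median(v[in_modal]),
                 modal_bin = c(low = modal * bin_width,
                               high = (modal + 1) * bin_width),
                 n_support = sum(in_modal)),
            class = "unit_intensity")
}

#' Flag autofluorescent outlier foci with Tukey's fence
#'
#' Computes Q1 and Q3 of the focus intensities by the linear-interpolation
#' quantile rule and flags foci with intensity above `Q3 + k * IQR` as
#' outliers. Only the upper fence is applied: dim foci are already handled
#' by the detection threshold, while the purpose of the fence is to prevent
#' large autofluorescent blobs from being counted as many mRNAs.
#'
#' @param foci focus data.frame (uses `intensity`).
#' @param k fence multiplier (1.5 = conventional).
#' @return `foci` with a logical `outlier` column set.
#' @export
tukey_filter <- function(foci, k = 1.5) {
  stopifnot(k > 0)
  if (!nrow(foci)) stop("no foci to filter")
  q <- quantile(foci$intensity, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2L] + k * (q[2L] - q[1L])
  foci$outlier <- foci$intensity > fence
  foci
}

# per-cell-count variant of the fence (config flag tukey_on = "cell_counts"):
# the fence is computed over provisional per-cell totals of one gene's
# assigned foci; every focus of a cell beyond the upper fence is flagged
tukey_filter_counts <- function(foci, k = 1.5) {
  stopifnot(k > 0)
  assigned <- !is.na(foci$cell_id)
  if (!any(assigned)) return(foci)
  totals <- tapply(foci$mrna_count[assigned], foci$cell_id[assigned], sum)
  q <- quantile(as.numeric(totals), c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2L] + k * (q[2L] - q[1L])
  bad_cells <- as.integer(names(totals))[totals > fence]
  hit <- assigned & foci$cell_id %in% bad_cells
  foci$outlier <- foci$outlier | hit
  foci$mrna_count[hit] <- 0L
  foci
}

#' Deconvolve focus intensities into mRNA counts
#'
#' Each retained focus's count is its intensity divided by the single-mRNA
#' intensity `I1`, rounded half-to-even, and clamped below at `clamp_min`
#' (a detected non-outlier focus represents at least one mRNA). Outlier foci
#' get count 0 and are excluded downstream.
#'
#' @param foci focus data.frame with `intensity` (and optionally `outlier`).
#' @param unit a `unit_intensity` from [estimate_unit_intensity()].
#' @param clamp_min minimum count for retained foci.
#' @return `foci` with an integer `mrna_count` column.
#' @export
deconvolve_counts <- function(foci, unit, clamp_min = 1L) {
  stopifnot(inherits(unit, "unit_intensity"), unit$I1 > 0)
  if (is.null(foci$outlier)) foci$outlier <- rep(FALSE, nrow(foci))
  cnt <- pmax(clamp_min, round(foci$intensity / unit$I1))  # round half-to-even
  cnt[foci$outlier] <- 0
  foci$mrna_count <- as.integer(cnt)
  foci
}

#' Assign foci to cells and subcellular compartments
#'
#' The focus pixel is `(round(y), round(x))`; its cell is the cell label at
#' that pixel (0 = unassigned, excluded from per-cell statistics) and its
#' compartment is `nuclear` when the nucleus label there equals the cell id,
#' `cytoplasmic` otherwise.
#'
#' @param foci focus data.frame with 0-based `x`, `y`.
#' @param cells cell [label_mask()].
#' @param nuclei nucleus [label_mask()] of the same shape.
#' @return `foci` with `cell_id` and `compartment` columns.
#' @export
assign_spots <- function(foci, cells, nuclei) {
  stopifnot(inherits(cells, "label_mask"), inherits(nuclei, "label_mask"),
            identical(dim(cells$labels), dim(nuclei$labels)))
  nr <- nrow(cells$labels); nc <- ncol(cells$labels)
  if (!nrow(foci)) {
    foci$cell_id <- integer(0); foci$compartment <- character(0)
    return(foci)
  }
  r <- round(foci$y) + 1L
  cc <- round(foci$x) + 1L
  if (any(r < 1L | r > nr | cc < 1L | cc > nc))
    stop("focus coordinates out of image bounds")
  idx <- cbind(r, cc)
  cid <- cells$labels[idx]
  nid <- nuclei$labels[idx]
  foci$cell_id <- ifelse(cid > 0L, cid, NA_integer_)
  foci$compartment <- ifelse(cid == 0L, "unassigned",
                             ifelse(nid == cid, "nuclear", "cytoplasmic"))
  foci
}

#' @export
print.unit_intensity <- function(x, ...) {
  cat("<unit_intensity> gene ", x$gene, ": I1 = ", format(x$I1),
      " (modal bin [", format(x$modal_bin[1L]), ", ",
      format(x$modal_bin[2L]), "), n = ", x$n_support, ")\n", sep = "")
  invisible(x)
}
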