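#' Mean insulin intensity per segmented cell
#'
#' @param cells a cell [label_mask()].
#' @param insulin_channel intensity matrix of the same shape.
#' @return named numeric vector: names = cell ids, values = arithmetic mean
#'   intensity over the cell's pixels. Empty mask gives an empty vector.
#' @export
measure_cell_intensity <- function(cells, insulin_channel) {
  stopifnot(inherits(cells, "label_mask"))
  if (!identical(dim(cells$labels), dim(insulin_channel)))
    stop("mask and insulin channel shapes differ")
  sel <- cells$labels > 0L
  if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
  sums <- tapply(insulin_channel[sel], cells$labels[sel], mean)
  stats::setNames(as.numeric(sums), names(sums))
}

# Savitzky-Golay smoothing with polynomial-interpolated edges: each interior
# value is the window-center value of the degree-`polyorder` least-squares
# fit; the first/last half-windows are the edge-window fits evaluated
# off-center (no artificial boundary minima).
savgol_smooth <- function(y, window, polyorder) {
  stopifnot(window %% 2 == 1, window > polyorder, length(y) >= window)
  half <- (window - 1L) %/% 2L
  A <- outer(-half:half, 0:polyorder, `^`)
  # projection row for the window center: e1' (A'A)^-1 A'
  AtA_inv_At <- solve(crossprod(A), t(A))
  center_w <- AtA_inv_At[1L, ]
  n <- length(y)
  out <- numeric(n)
  for (i in (half + 1L):(n - half)) {
    out[i] <- sum(center_w * y[(i - half):(i + half)])
  }
  coef_l <- AtA_inv_At %*% y[1:window]
  coef_r <- AtA_inv_At %*% y[(n - window + 1L):n]
  powers <- function(t) t^(0:polyorder)
  for (i in seq_len(half)) {
    out[i] <- sum(coef_l * powers(i - 1L - half))
    out[n - half + i] <- sum(coef_r * powers(i))
  }
  out
}

#' Histogram of per-cell intensities with Savitzky-Golay smoothing
#'
#' Bins `values` into `bin_count` equal-width bins spanning their range and
#' smooths the counts with a Savitzky-Golay filter (the least-squares
#' polynomial fit over a sliding window, evaluated at the window center;
#' edges use the edge-window polynomial evaluated off-center).
#'
#' @param values numeric sample (at least two distinct values).
#' @param bin_count number of histogram bins.
#' @param window_bins odd smoothing window length in bins; must not exceed
#'   `bin_count` and must exceed `polyorder`.
#' @param polyorder polynomial degree of the fit.
#' @return list with `bin_centers`, `smoothed` (smoothed counts) and
#'   `counts` (raw counts).
#' @export
smooth_histogram <- function(values, bin_count = 64L, window_bins = 11L,
                             polyorder = 3L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("need at least 2 distinct values to build a histogram")
  if (window_bins %% 2 != 1 || window_bins <= polyorder)
    stop("`window_bins` must be odd and greater than `polyorder`")
  if (window_bins > bin_count)
    stop("smoothing window (", window_bins, ") larger than bin count (",
         bin_count, ")")
  rng <- range(values)
  breaks <- seq(rng[1L], rng[2L], length.out = bin_count + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     bin_count)
  centers <- (breaks[-1L] + breaks[-(bin_count + 1L)]) / 2
  smoothed <- savgol_smooth(as.numeric(counts), window_bins, polyorder)
  list(bin_centers = centers, smoothed = smoothed, counts = counts)
}

# local maxima of a vector, plateaus collapsed to their first bin;
# endpoints count as maxima when the interior neighbour is lower
local_maxima <- function(s) {
  r <- rle(s)
  k <- length(r$values)
  if (k == 1L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1L], -Inf)
  starts[r$values > left & r$values > right]
}

# topological persistence of the local maxima of a 1D profile: sweep the
# level set downwards, merging components; when two components meet, the
# younger (lower-birth) peak dies. The dominant modes of a histogram are
# its most persistent peaks; for a clean bimodal histogram these are
# exactly the two highest local maxima.
peak_persistence <- function(s) {
  n <- length(s)
  comp <- integer(n)                 # 0 = not yet seen, else peak index
  birth <- numeric(0); peak_at <- integer(0); persist <- numeric(0)
  find_peak <- function(i) {
    while (peak_at[i] != i) i <- peak_at[i]
    i
  }
  ord <- order(-s, seq_len(n))
  for (i in ord) {
    lc <- if (i > 1L && comp[i - 1L] > 0L) comp[i - 1L] else 0L
    rc <- if (i < n && comp[i + 1L] > 0L) comp[i + 1L] else 0L
    if (lc == 0L && rc == 0L) {
      peak_at <- c(peak_at, length(peak_at) + 1L)
      birth <- c(birth, s[i])
      persist <- c(persist, NA_real_)
      comp[i] <- length(peak_at)
      names(birth)[length(birth)] <- i   # bin index of the peak
    } else if (lc > 0L && rc > 0L) {
      a <- find_peak(lc); b <- find_peak(rc)
      if (a != b) {
        # the lower-birth peak dies at this saddle
        die <- if (birth[a] < birth[b] ||
                   (birth[a] == birth[b] && a > b)) a else b
        live <- if (die == a) b else a
        persist[die] <- birth[die] - s[i]
        peak_at[die] <- live
      }
      comp[i] <- find_peak(lc)
    } else {
      comp[i] <- find_peak(max(lc, rc))
    }
  }
  root <- find_peak(1L)
  persist[root] <- birth[root] - min(s)
  data.frame(bin = as.integer(names(birth)), height = as.numeric(birth),
             persistence = persist)
}

#' Insulin-intensity threshold from a smoothed histogram
#'
#' Identifies the two highest local maxima (the beta and non-beta modes) of
#' the smoothed histogram and returns the bin center of the lowest smoothed
#' count strictly between them (ties resolved toward the lower intensity).
#' Negative smoothed counts are clipped to zero before mode finding.
#'
#' @param bin_centers,smoothed output of [smooth_histogram()].
#' @return threshold intensity (a bin center).
#' @section Errors: a unimodal smoothed histogram raises a condition of class
#'   `smfishq_unimodal_error` carrying the mode diagnostics; callers may
#'   catch it and fall back (see `unimodal_fallback` in [pipeline_config()]).
#' @export
find_threshold <- function(bin_centers, smoothed) {
  stopifnot(length(bin_centers) == length(smoothed))
  s <- pmax(0, smoothed)
  peaks <- local_maxima(s)
  if (length(peaks) < 2L)
    stop(structure(class = c("smfishq_unimodal_error", "error", "condition"),
                   list(message = paste0("smoothed histogram is unimodal (",
                                         length(peaks), " mode(s) found); ",
                                         "no separating threshold"),
                        call = sys.call(-1L), modes = peaks)))
  # rank modes by topological persistence so that noise wiggles riding on a
  # dominant mode are never mistaken for the second population; on a clean
  # bimodal histogram this is identical to taking the two highest maxima
  pp <- peak_persistence(s)
  pp <- pp[order(-pp$persistence, -pp$height, pp$bin), , drop = FALSE]
  top2 <- pp$bin[1:2]
  lo <- min(top2); hi <- max(top2)
  if (hi - lo < 2L)
    stop(structure(class = c("smfishq_unimodal_error", "error", "condition"),
                   list(message = "the two modes are adjacent; no bin strictly between them",
                        call = sys.call(-1L), modes = peaks)))
  between <- (lo + 1L):(hi - 1L)
  j <- between[which.min(s[between])]  # which.min takes the first = lower intensity
  # dip criterion: declaring bimodality from sampling noise is unsafe, so
  # the valley must drop below half the lower of the two mode heights
  if (s[j] > 0.5 * min(s[top2]))
    stop(structure(class = c("smfishq_unimodal_error", "error", "condition"),
                   list(message = paste0(
                     "no sufficient dip between candidate modes (valley ",
                     signif(s[j], 4), " vs mode heights ",
                     paste(signif(s[top2], 4), collapse = "/"),
                     "); treating histogram as unimodal"),
                        call = sys.call(-1L), modes = top2)))
  bin_centers[j]
}

#' Classify cells as beta or non-beta by insulin intensity
#'
#' Cells with mean insulin intensity strictly above the threshold are
#' `beta`; at or below, `non_beta` (deterministic tie rule).
#'
#' @param intensities named vector from [measure_cell_intensity()].
#' @param threshold intensity threshold from [find_threshold()].
#' @return named character vector of classes.
#' @export
classify_cells <- function(intensities, threshold) {
  stopifnot(is.finite(threshold))
  stats::setNames(ifelse(intensities > threshold, "beta", "non_beta"),
                  names(intensities))
}

# full classification step with the configured unimodal fallback
classify_from_config <- function(intensities, config, verbose = TRUE) {
  hist <- smooth_histogram(intensities,
                           bin_count = config$histogram_bin_count,
                           window_bins = config$savgol_window_bins,
                           polyorder = config$savgol_polyorder)
  thr <- tryCatch(find_threshold(hist$bin_centers, hist$smoothed),
                  smfishq_unimodal_error = function(e) {
                    if (config$unimodal_fallback == "otsu") {
                      log_stage("celltype", "unimodal histogram; falling ",
                                "back to Otsu threshold", verbose = verbose)
                      otsu_threshold(intensities)
                    } else stop(e)
                  })
  list(threshold = thr, classes = classify_cells(intensities, thr),
       histogram = hist)
}
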