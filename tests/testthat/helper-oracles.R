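# Independent oracles used by the unit and acceptance tests. Each one is a
# deliberately naive implementation (brute force, closed form, or direct
# enumeration) kept separate from the package's production code paths.

# linear-interpolation (type 7) quantile computed by hand from order stats
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Tukey upper-fence flags by the stated rule
oracle_tukey_flags <- function(x, k) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  x > q3 + k * (q3 - q1)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments:
# U recomputed by pairwise counting, p = fraction of assignments with a
# tail statistic at least as extreme (both tails, via min(U, mn - U))
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  count_U <- function(idx_a) {
    av <- pooled[idx_a]; bv <- pooled[-idx_a]
    sum(outer(av, bv, `>`)) + 0.5 * sum(outer(av, bv, `==`))
  }
  u_obs <- count_U(seq_len(na))
  m_obs <- min(u_obs, na * nb - u_obs)
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, count_U)
  mean(pmin(us, na * nb - us) <= m_obs)
}

# per-window least-squares polynomial fit evaluated at the window center,
# via lm() on each window (independent of the convolution-style production
# implementation)
oracle_savgol_interior <- function(y, window, polyorder) {
  half <- (window - 1) %/% 2
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    t <- -half:half
    fit <- stats::lm(y[(i - half):(i + half)] ~ poly(t, polyorder, raw = TRUE))
    out[i] <- unname(stats::predict(fit, newdata = data.frame(t = 0)))
  }
  out
}

# brute-force multi-scale LoG blob detection by direct kernel convolution
# and strict 3D local-maximum search, with 3-px deduplication
oracle_log_detect <- function(channel, sigmas, threshold) {
  nr <- nrow(channel); nc <- ncol(channel)
  resp <- lapply(sigmas, function(s) {
    h <- ceiling(4 * s)
    xs <- -h:h
    g2 <- outer(xs^2, xs^2, `+`)
    # scale-normalized negative LoG kernel (positive response for bright blobs)
    k <- -s^2 * (g2 - 2 * s^2) / (2 * pi * s^6) * exp(-g2 / (2 * s^2))
    r <- matrix(0, nr, nc)
    for (i in 1:nr) for (j in 1:nc) {
      ri <- max(1, i - h):min(nr, i + h)
      cj <- max(1, j - h):min(nc, j + h)
      r[i, j] <- sum(channel[ri, cj] * k[ri - i + h + 1, cj - j + h + 1])
    }
    r
  })
  hits <- NULL
  for (si in seq_along(sigmas)) {
    m <- resp[[si]]
    for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
      v <- m[i, j]
      if (v < threshold) next
      if (v < max(m[(i - 1):(i + 1), (j - 1):(j + 1)])) next
      if (si > 1 && v < resp[[si - 1]][i, j]) next
      if (si < length(sigmas) && v < resp[[si + 1]][i, j]) next
      hits <- rbind(hits, c(y = i - 1, x = j - 1, v = v))
    }
  }
  if (is.null(hits)) return(data.frame(y = numeric(0), x = numeric(0)))
  hits <- hits[order(-hits[, "v"]), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) for (j in (i + 1):nrow(hits)) {
      if (keep[j] && (hits[i, "y"] - hits[j, "y"])^2 +
          (hits[i, "x"] - hits[j, "x"])^2 <= 9) keep[j] <- FALSE
    }
  }
  as.data.frame(hits[keep, c("y", "x"), drop = FALSE])
}

# random label field of disjoint disks for geometry tests
random_disk_field <- function(nr, nc, n_disks, r_range, seed) {
  set.seed(seed)
  lab <- matrix(0L, nr, nc)
  placed <- 0L; tries <- 0L
  cys <- c(); cxs <- c(); rs <- c()
  while (placed < n_disks && tries < 500L) {
    tries <- tries + 1L
    r <- runif(1, r_range[1], r_range[2])
    cy <- runif(1, r + 1, nr - r - 2)
    cx <- runif(1, r + 1, nc - r - 2)
    if (placed > 0 && any(sqrt((cys - cy)^2 + (cxs - cx)^2) < rs + r + 2)) next
    placed <- placed + 1L
    cys <- c(cys, cy); cxs <- c(cxs, cx); rs <- c(rs, r)
    d2 <- outer(((seq_len(nr) - 1) - cy)^2, ((seq_len(nc) - 1) - cx)^2, `+`)
    lab[d2 <= r^2 & lab == 0L] <- placed
  }
  lab
}

# match each detected focus to its nearest truth spot within `max_dist` px;
# returns the truth row index per focus (NA if unmatched)
match_to_truth <- function(det, truth, max_dist = 2) {
  vapply(seq_len(nrow(det)), function(i) {
    d2 <- (truth$x - det$x[i])^2 + (truth$y - det$y[i])^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= max_dist^2) j else NA_integer_
  }, integer(1))
}

# small simulated world used by several module tests: modest field so the
# whole suite stays fast
small_sim <- function(seed = 1, n_cells = 30,
                      field_shape_px = c(1024, 1024),
                      genes_beta = c(GeneA = 12),
                      genes_nonbeta = c(GeneA = 2), ...) {
  sim_params(field_shape_px = field_shape_px, n_cells = n_cells,
             gene_means_beta = genes_beta, gene_means_nonbeta = genes_nonbeta,
             seed = seed, ...)
}

small_config <- function(...) {
  pipeline_config(cell_expansion_radius_px = 22, tukey_k = 400, ...)
}
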