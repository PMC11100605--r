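#' Per-cell per-gene transcript counts with compartment split
#'
#' Aggregates the retained (non-outlier, cell-assigned) foci into one row
#' per (cell, gene): total mRNA count and its nuclear/cytoplasmic split,
#' with the cell's class carried along. Cells with no foci get explicit
#' zero rows so that every segmented cell appears for every gene.
#'
#' @param foci assigned, counted focus table.
#' @param cells classified cell table.
#' @param genes genes to tabulate; default: those present in `foci`.
#' @return data.frame: `field_id`, `cell_id`, `gene`, `total`, `nuclear`,
#'   `cytoplasmic`, `cell_class`, sorted by (field, gene, cell).
#' @export
per_cell_counts <- function(foci, cells, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(foci$gene))
  base <- if (nrow(cells) && length(genes))
    merge(cells[c("field_id", "cell_id", "cell_class")],
          data.frame(gene = genes, stringsAsFactors = FALSE))
  else
    data.frame(field_id = character(0), cell_id = integer(0),
               cell_class = character(0), gene = character(0),
               stringsAsFactors = FALSE)
  ret <- foci[!foci$outlier & !is.na(foci$cell_id) & foci$cell_id > 0, ,
              drop = FALSE]
  if (nrow(ret)) {
    key <- paste(ret$field_id, ret$cell_id, ret$gene)
    tot <- tapply(ret$mrna_count, key, sum)
    nuc <- tapply(ret$mrna_count * (ret$compartment == "nuclear"), key, sum)
    bkey <- paste(base$field_id, base$cell_id, base$gene)
    base$total <- as.integer(ifelse(is.na(tot[bkey]), 0L, tot[bkey]))
    base$nuclear <- as.integer(ifelse(is.na(nuc[bkey]), 0L, nuc[bkey]))
  } else {
    base$total <- integer(nrow(base))
    base$nuclear <- integer(nrow(base))
  }
  base$cytoplasmic <- base$total - base$nuclear
  out <- base[c("field_id", "cell_id", "gene", "total", "nuclear",
                "cytoplasmic", "cell_class")]
  out <- out[order_stable(out$field_id, out$gene, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nuclear/cytoplasmic localization fractions
#'
#' Per-cell nuclear fraction = nuclear / total (cells with zero transcripts
#' for a gene are excluded), plus per (gene, class) group summaries as
#' mean +/- standard error of the mean.
#'
#' @param count_table output of [per_cell_counts()].
#' @return list with `per_cell` (adds `nuclear_fraction`) and `groups`
#'   (`gene`, `cell_class`, `n_cells`, `mean_nuclear_fraction`, `sem`).
#' @export
localization_fractions <- function(count_table) {
  pc <- count_table[count_table$total > 0, , drop = FALSE]
  pc$nuclear_fraction <- pc$nuclear / pc$total
  groups <- if (nrow(pc)) {
    do.call(rbind, lapply(split(pc, list(pc$gene, pc$cell_class), drop = TRUE),
                          function(d) data.frame(
      gene = d$gene[1L], cell_class = d$cell_class[1L], n_cells = nrow(d),
      mean_nuclear_fraction = mean(d$nuclear_fraction),
      sem = if (nrow(d) > 1L) sd(d$nuclear_fraction) / sqrt(nrow(d)) else NA_real_,
      stringsAsFactors = FALSE)))
  } else {
    data.frame(gene = character(0), cell_class = character(0),
               n_cells = integer(0), mean_nuclear_fraction = numeric(0),
               sem = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(groups) <- NULL
  groups <- groups[order_stable(groups$gene, groups$cell_class), , drop = FALSE]
  list(per_cell = pc, groups = groups)
}

# exact null distribution of the Mann-Whitney U statistic via the classic
# counting recursion c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1):
# counts[u + 1] = number of rank subsets of size m (out of m + n) with U = u
mw_exact_counts <- function(m, n) {
  f <- array(0, dim = c(m + 1L, n + 1L, m * n + 1L))
  f[1L, , 1L] <- 1  # empty first sample: U = 0
  f[, 1L, 1L] <- 1  # empty second sample: U = 0
  for (i in seq_len(m)) for (j in seq_len(n)) for (u in 0:(i * j)) {
    v <- f[i + 1L, j, u + 1L]
    if (u >= j) v <- v + f[i, j + 1L, u - j + 1L]
    f[i + 1L, j + 1L, u + 1L] <- v
  }
  f[m + 1L, n + 1L, ]
}

# normal approximation with mid-ranks, tie-corrected variance and a 0.5
# continuity correction; also used directly by tests to cross-check the
# exact branch
mann_whitney_normal_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  N <- na + nb
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(U - na * nb / 2) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(0, z)))
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent samples. U is
#' computed from the rank sum of the first sample with mid-ranks for ties.
#' For `n_a + n_b <= 12` with no ties the two-sided p-value is exact (tail
#' sums of the enumerated null distribution of U); otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used.
#'
#' @param sample_a,sample_b numeric samples (each non-empty).
#' @param group_a,group_b,gene,statistic_name labels carried into the result.
#' @return an object of class `group_result`: list with `gene`,
#'   `statistic_name`, group labels and sizes, `U_statistic`, `p_value`,
#'   `median_a`, `median_b`, and `method` ("exact" or "normal").
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p_value  # exact: 1/3
#' @export
mann_whitney <- function(sample_a, sample_b, group_a = "a", group_b = "b",
                         gene = NA_character_,
                         statistic_name = "mann_whitney_U") {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  na <- length(sample_a); nb <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled)  # mid-ranks for ties
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (na + nb <= 12 && !has_ties) {
    counts <- mw_exact_counts(na, nb)
    total <- sum(counts)
    u_lo <- min(U, na * nb - U)
    u_hi <- na * nb - u_lo
    p <- (sum(counts[seq_len(u_lo + 1)]) +
          sum(counts[(u_hi + 1):(na * nb + 1)])) / total
    p <- min(1, p)
    method <- "exact"
  } else {
    p <- mann_whitney_normal_p(sample_a, sample_b)
    method <- "normal"
  }
  structure(list(gene = gene, statistic_name = statistic_name,
                 group_a = group_a, group_b = group_b,
                 n_a = na, n_b = nb, U_statistic = U, p_value = p,
                 median_a = median(sample_a), median_b = median(sample_b),
                 method = method),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("<group_result> ", x$statistic_name,
      if (!is.na(x$gene)) paste0(" [", x$gene, "]"), ": ",
      x$group_a, " (n=", x$n_a, ", median ", format(x$median_a), ") vs ",
      x$group_b, " (n=", x$n_b, ", median ", format(x$median_b), "); U = ",
      format(x$U_statistic), ", p = ", format.pval(x$p_value),
      " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Corrected total fluorescence
#'
#' The standard background correction for immunofluorescence quantification:
#' integrated density minus region area times mean background intensity.
#' A negative result (region dimmer than background) is returned as-is with
#' a warning.
#'
#' @param integrated_density sum of pixel intensities over the region.
#' @param region_area_px region area in pixels.
#' @param background_mean mean intensity of the background reference.
#' @return corrected fluorescence (same units as `integrated_density`).
#' @examples
#' ctcf(1000, 50, 4)  # 800
#' @export
ctcf <- function(integrated_density, region_area_px, background_mean) {
  stopifnot(all(is.finite(integrated_density)), all(is.finite(background_mean)),
            all(region_area_px >= 0))
  out <- integrated_density - region_area_px * background_mean
  if (any(out < 0))
    warning("negative corrected fluorescence for ", sum(out < 0), " region(s)")
  out
}

#' Log2 signal-to-noise normalization against IgG negative controls
#'
#' Divides each marker's count by the geometric mean of the IgG
#' negative-control counts and reports log2 of the ratio, the convention
#' used for spatial-proteomics panels.
#'
#' @param target_counts positive named/unnamed counts per marker.
#' @param igg_counts positive counts of the IgG negative controls.
#' @return numeric vector of log2 SNR values, same length as `target_counts`.
#' @examples
#' snr_normalize(8, c(2, 2))  # 2
#' @export
snr_normalize <- function(target_counts, igg_counts) {
  if (any(target_counts <= 0) || any(igg_counts <= 0))
    stop("all counts must be positive")
  geo <- exp(mean(log(igg_counts)))
  log2(target_counts / geo)
}
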