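#' Simulation parameters for synthetic islet-tissue fields
#'
#' The defaults describe the package's reference synthetic world (see the
#' vignette for the rationale behind each number): a 2048 x 2048 px field of
#' 200 non-overlapping elliptical nuclei (semi-axes 33-40 px) whose cells are
#' the 22-px Voronoi-constrained dilation of the nuclei; 70% of cells are
#' insulin-high beta cells (intensity N(150, 15) vs N(40, 8)); each gene
#' places Poisson-distributed transcripts per cell (mean 20 in beta, 2 in
#' non-beta), 15% of foci are multiplets of 2 or 3 co-located mRNAs, 30% of
#' foci are nuclear; spots render as Gaussians of sd 1.5 px and unit peak
#' amplitude 100 on background 10 with additive Gaussian noise sd 5
#' (0.05 x unit amplitude); 5 large autofluorescent blobs per mRNA channel.
#'
#' @param field_shape_px c(height, width) in pixels.
#' @param n_cells number of cells to place.
#' @param nucleus_radius_px_range range of ellipse semi-axes in pixels.
#' @param cell_expansion_truth_px true radial cell expansion in pixels.
#' @param beta_fraction probability a cell is a beta cell.
#' @param insulin_intensity_beta,insulin_intensity_nonbeta c(mean, sd) of the
#'   class-conditional per-cell insulin intensity.
#' @param gene_means_beta,gene_means_nonbeta named numeric vectors (names =
#'   genes) of Poisson mean transcripts per cell by class.
#' @param multiplet_fraction probability a focus is a multiplet.
#' @param multiplet_size_distribution named probability vector over multiplet
#'   sizes k >= 2, e.g. `c("2" = 0.7, "3" = 0.3)`.
#' @param nuclear_fraction_true probability a focus is placed in the nucleus;
#'   scalar or named per-gene vector.
#' @param psf_sigma_px point-spread sd of a diffraction-limited spot, px.
#' @param unit_amplitude peak intensity of a single-mRNA spot.
#' @param nucleus_amplitude rendered intensity of nuclei in the DAPI channel.
#' @param background_level constant background added to every channel.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param n_autofluor_outliers large bright blobs per mRNA channel.
#' @param outlier_amplitude_multiplier,outlier_sigma_mult amplitude and size
#'   of outlier blobs relative to a unit spot.
#' @param seed RNG seed; identical params + seed give bit-identical output.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(field_shape_px = c(2048, 2048),
                       n_cells = 200,
                       nucleus_radius_px_range = c(33, 40),
                       cell_expansion_truth_px = 22,
                       beta_fraction = 0.7,
                       insulin_intensity_beta = c(150, 15),
                       insulin_intensity_nonbeta = c(40, 8),
                       gene_means_beta = c(Cd274 = 20, Mx1 = 20),
                       gene_means_nonbeta = c(Cd274 = 2, Mx1 = 2),
                       multiplet_fraction = 0.15,
                       multiplet_size_distribution = c("2" = 0.7, "3" = 0.3),
                       nuclear_fraction_true = 0.3,
                       psf_sigma_px = 1.5,
                       unit_amplitude = 100,
                       nucleus_amplitude = 200,
                       background_level = 10,
                       noise_sd = 5,
                       n_autofluor_outliers = 5,
                       outlier_amplitude_multiplier = 10,
                       outlier_sigma_mult = 3,
                       seed = 1L) {
  genes <- names(gene_means_beta)
  if (is.null(genes) || !identical(sort(genes), sort(names(gene_means_nonbeta))))
    stop("gene_means_beta and gene_means_nonbeta must share gene names")
  if (length(nuclear_fraction_true) == 1L && is.null(names(nuclear_fraction_true)))
    nuclear_fraction_true <- stats::setNames(rep(nuclear_fraction_true,
                                                 length(genes)), genes)
  stopifnot(beta_fraction >= 0, beta_fraction <= 1,
            multiplet_fraction >= 0, multiplet_fraction <= 1,
            all(nuclear_fraction_true >= 0), all(nuclear_fraction_true <= 1),
            all(gene_means_beta >= 0), all(gene_means_nonbeta >= 0),
            psf_sigma_px > 0, n_cells >= 0,
            length(field_shape_px) == 2L, all(field_shape_px >= 8),
            nucleus_radius_px_range[1L] > 0,
            nucleus_radius_px_range[1L] <= nucleus_radius_px_range[2L],
            abs(sum(multiplet_size_distribution) - 1) < 1e-8,
            all(as.integer(names(multiplet_size_distribution)) >= 2),
            noise_sd >= 0, background_level >= 0, unit_amplitude > 0)
  structure(list(field_shape_px = as.integer(field_shape_px),
                 n_cells = as.integer(n_cells),
                 nucleus_radius_px_range = nucleus_radius_px_range,
                 cell_expansion_truth_px = cell_expansion_truth_px,
                 beta_fraction = beta_fraction,
                 insulin_intensity_beta = insulin_intensity_beta,
                 insulin_intensity_nonbeta = insulin_intensity_nonbeta,
                 gene_means_beta = gene_means_beta,
                 gene_means_nonbeta = gene_means_nonbeta,
                 multiplet_fraction = multiplet_fraction,
                 multiplet_size_distribution = multiplet_size_distribution,
                 nuclear_fraction_true = nuclear_fraction_true,
                 psf_sigma_px = psf_sigma_px,
                 unit_amplitude = unit_amplitude,
                 nucleus_amplitude = nucleus_amplitude,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 n_autofluor_outliers = as.integer(n_autofluor_outliers),
                 outlier_amplitude_multiplier = outlier_amplitude_multiplier,
                 outlier_sigma_mult = outlier_sigma_mult,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# add one isotropic Gaussian of peak `amp`, sd `sigma`, centered at 0-based
# (y, x), to image `img`, rendered in a +/- 4 sigma window
render_spot <- function(img, y, x, amp, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  h <- ceiling(4 * sigma)
  r0 <- max(1L, floor(y + 1 - h)); r1 <- min(nr, ceiling(y + 1 + h))
  c0 <- max(1L, floor(x + 1 - h)); c1 <- min(nc, ceiling(x + 1 + h))
  if (r0 > r1 || c0 > c1) return(img)
  dy <- (r0:r1) - 1 - y
  dx <- (c0:c1) - 1 - x
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
    amp * outer(exp(-dy^2 / (2 * sigma^2)), exp(-dx^2 / (2 * sigma^2)))
  img
}

place_nuclei <- function(params) {
  nr <- params$field_shape_px[1L]; nc <- params$field_shape_px[2L]
  rng <- params$nucleus_radius_px_range
  margin <- rng[2L] + params$cell_expansion_truth_px + 2
  if (params$n_cells > 0 && (nr <= 2 * margin || nc <= 2 * margin))
    stop("field too small for nucleus radius and expansion")
  n <- params$n_cells
  cy <- numeric(n); cx <- numeric(n); a <- numeric(n); b <- numeric(n)
  th <- numeric(n)
  attempts <- 0L; max_attempts <- max(1000L, 500L * n)
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("field too small to place ", n, " nuclei without overlap")
    y <- runif(1, margin, nr - 1 - margin)
    x <- runif(1, margin, nc - 1 - margin)
    ai <- runif(1, rng[1L], rng[2L])
    bi <- runif(1, rng[1L], rng[2L])
    if (placed > 0L) {
      ok <- all(sqrt((cy[seq_len(placed)] - y)^2 +
                     (cx[seq_len(placed)] - x)^2) >
                pmax(a[seq_len(placed)], b[seq_len(placed)]) + max(ai, bi) + 2)
      if (!ok) next
    }
    placed <- placed + 1L
    cy[placed] <- y; cx[placed] <- x; a[placed] <- ai; b[placed] <- bi
    th[placed] <- runif(1, 0, pi)
  }
  data.frame(cell_id = seq_len(n), center_y = cy, center_x = cx,
             a = a, b = b, theta = th)
}

rasterize_nuclei <- function(nuclei, shape) {
  lab <- matrix(0L, shape[1L], shape[2L])
  for (i in seq_len(nrow(nuclei))) {
    a <- nuclei$a[i]; b <- nuclei$b[i]; th <- nuclei$theta[i]
    cy <- nuclei$center_y[i]; cx <- nuclei$center_x[i]
    h <- ceiling(max(a, b)) + 1
    rr <- max(1L, floor(cy + 1 - h)):min(shape[1L], ceiling(cy + 1 + h))
    cc <- max(1L, floor(cx + 1 - h)):min(shape[2L], ceiling(cx + 1 + h))
    dy <- outer((rr - 1) - cy, rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), (cc - 1) - cx)
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    inside <- (u^2 + v^2) <= 1
    block <- lab[rr, cc]
    block[inside] <- i
    lab[rr, cc] <- block
  }
  lab
}

# split transcripts of one cell into focus multiplicities
draw_multiplicities <- function(n_transcripts, params) {
  sizes <- as.integer(names(params$multiplet_size_distribution))
  probs <- as.numeric(params$multiplet_size_distribution)
  ks <- integer(0)
  remaining <- n_transcripts
  while (remaining > 0L) {
    k <- 1L
    if (params$multiplet_fraction > 0 &&
        runif(1) < params$multiplet_fraction)
      k <- sample(sizes, 1L, prob = probs)
    k <- min(k, remaining)
    ks <- c(ks, k)
    remaining <- remaining - k
  }
  ks
}

#' Generate one synthetic islet-tissue field with ground truth
#'
#' Renders a multi-channel field (nucleus stain, insulin, one mRNA channel
#' per gene) together with the true nucleus and cell label masks and
#' complete truth tables for every cell and every placed focus.
#'
#' @param params a [sim_params()] object.
#' @return a list with elements `stack` ([image_stack()]), `nuclei` and
#'   `cells` ([label_mask()]s), and `truth` (class `ground_truth`: data
#'   frames `cells`, `counts`, `spots`).
#' @export
generate_field <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  shape <- params$field_shape_px
  genes <- names(params$gene_means_beta)

  nuclei_geom <- place_nuclei(params)
  nuc_lab <- rasterize_nuclei(nuclei_geom, shape)
  cell_lab <- if (params$n_cells > 0)
    .cpp_expand_labels(nuc_lab, params$cell_expansion_truth_px)
  else nuc_lab

  n <- params$n_cells
  cls <- if (n > 0)
    ifelse(runif(n) < params$beta_fraction, "beta", "non_beta")
  else character(0)

  # insulin channel: constant per-cell class-conditional draw
  ins_mu <- ifelse(cls == "beta", params$insulin_intensity_beta[1L],
                   params$insulin_intensity_nonbeta[1L])
  ins_sd <- ifelse(cls == "beta", params$insulin_intensity_beta[2L],
                   params$insulin_intensity_nonbeta[2L])
  cell_ins <- if (n > 0) pmax(0, rnorm(n, ins_mu, ins_sd)) else numeric(0)
  ins_img <- matrix(params$background_level, shape[1L], shape[2L])
  if (n > 0) {
    inside <- cell_lab > 0L
    ins_img[inside] <- ins_img[inside] + cell_ins[cell_lab[inside]]
  }

  # nucleus channel: blurred solid ellipses
  nuc_img <- gaussian_blur((nuc_lab > 0L) * params$nucleus_amplitude, 2) +
    params$background_level

  # per-cell pixel lists by compartment (0-based x/y derived from indices)
  if (n > 0) {
    idx_all <- seq_along(nuc_lab)
    nuc_px <- split(idx_all[nuc_lab > 0L], nuc_lab[nuc_lab > 0L])
    cyto_sel <- cell_lab > 0L & nuc_lab == 0L
    cyto_px <- split(idx_all[cyto_sel], cell_lab[cyto_sel])
  }

  spots <- list()
  mrna_imgs <- list()
  for (g in genes) {
    # decide every focus first, then render all Gaussians in one pass
    gx <- numeric(0); gy <- numeric(0); gk <- integer(0)
    gcell <- integer(0); gcomp <- character(0)
    for (ci in seq_len(n)) {
      mu <- if (cls[ci] == "beta") params$gene_means_beta[[g]]
            else params$gene_means_nonbeta[[g]]
      n_tx <- rpois(1L, mu)
      if (n_tx == 0L) next
      ks <- draw_multiplicities(n_tx, params)
      for (k in ks) {
        nuclear <- runif(1) < params$nuclear_fraction_true[[g]]
        pool <- if (nuclear) nuc_px[[as.character(ci)]]
                else cyto_px[[as.character(ci)]]
        if (is.null(pool) || !length(pool)) {
          pool <- nuc_px[[as.character(ci)]]
          nuclear <- TRUE
        }
        px <- pool[sample.int(length(pool), 1L)]
        # linear index -> 0-based (y, x), plus sub-pixel jitter
        gy <- c(gy, (px - 1L) %% shape[1L] + runif(1, -0.49, 0.49))
        gx <- c(gx, (px - 1L) %/% shape[1L] + runif(1, -0.49, 0.49))
        gk <- c(gk, k)
        gcell <- c(gcell, ci)
        gcomp <- c(gcomp, if (nuclear) "nuclear" else "cytoplasmic")
      }
    }
    n_out <- params$n_autofluor_outliers
    oy <- if (n_out > 0L) runif(n_out, 0, shape[1L] - 1) else numeric(0)
    ox <- if (n_out > 0L) runif(n_out, 0, shape[2L] - 1) else numeric(0)
    img <- .cpp_render_spots(
      matrix(params$background_level, shape[1L], shape[2L]),
      c(gy, oy), c(gx, ox),
      c(gk * params$unit_amplitude,
        rep(params$outlier_amplitude_multiplier * params$unit_amplitude, n_out)),
      c(rep(params$psf_sigma_px, length(gy)),
        rep(params$outlier_sigma_mult * params$psf_sigma_px, n_out)))
    if (params$noise_sd > 0)
      img <- pmax(img + rnorm(length(img), 0, params$noise_sd), 0)
    mrna_imgs[[g]] <- img
    spots[[g]] <- data.frame(
      gene = rep(g, length(gy) + n_out),
      cell_id = c(gcell, rep(NA_integer_, n_out)),
      x = c(gx, ox), y = c(gy, oy),
      k = c(gk, rep(0L, n_out)),
      compartment = c(gcomp, rep("unassigned", n_out)),
      is_outlier = c(rep(FALSE, length(gy)), rep(TRUE, n_out)),
      stringsAsFactors = FALSE)
  }
  if (params$noise_sd > 0) {
    nuc_img <- pmax(nuc_img + rnorm(length(nuc_img), 0, params$noise_sd), 0)
    ins_img <- pmax(ins_img + rnorm(length(ins_img), 0, params$noise_sd), 0)
  }

  spots_df <- do.call(rbind, c(unname(spots), list(make.row.names = FALSE)))

  # truth counts derived from the placed spots themselves (conservation by
  # construction)
  counts <- expand.grid(cell_id = seq_len(n), gene = genes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(counts)) {
    sp <- spots_df[!spots_df$is_outlier, , drop = FALSE]
    key <- paste(sp$cell_id, sp$gene)
    tot <- tapply(sp$k, key, sum)
    nuc <- tapply(sp$k * (sp$compartment == "nuclear"), key, sum)
    ckey <- paste(counts$cell_id, counts$gene)
    counts$total <- as.integer(ifelse(is.na(tot[ckey]), 0L, tot[ckey]))
    counts$nuclear <- as.integer(ifelse(is.na(nuc[ckey]), 0L, nuc[ckey]))
    counts$cytoplasmic <- counts$total - counts$nuclear
  } else {
    counts$total <- integer(0); counts$nuclear <- integer(0)
    counts$cytoplasmic <- integer(0)
  }

  nuc_mask <- label_mask(nuc_lab, "nucleus")
  cell_mask <- label_mask(cell_lab, "cell")
  areas_n <- mask_areas(nuc_mask); areas_c <- mask_areas(cell_mask)
  truth_cells <- cbind(nuclei_geom,
                       data.frame(true_class = cls,
                                  insulin_true = cell_ins,
                                  nucleus_area_px = as.integer(
                                    areas_n[as.character(seq_len(n))]),
                                  cell_area_px = as.integer(
                                    areas_c[as.character(seq_len(n))]),
                                  stringsAsFactors = FALSE))

  channels <- c(list(nucleus = nuc_img, insulin = ins_img), mrna_imgs)
  stack <- image_stack(channels, pixel_edge_um = 0.03,
                       field_id = sprintf("sim%06d", params$seed))
  truth <- structure(list(cells = truth_cells, counts = counts,
                          spots = spots_df, params = params),
                     class = "ground_truth")
  list(stack = stack, nuclei = nuc_mask, cells = cell_mask, truth = truth)
}

#' Summarize ground truth into per-class expected statistics
#'
#' @param gt a `ground_truth` object from [generate_field()].
#' @return data.frame with one row per (gene, class): number of cells, mean
#'   true copy number, and mean per-cell nuclear fraction (cells with zero
#'   transcripts excluded from the fraction).
#' @export
truth_summary <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!nrow(gt$cells)) stop("empty ground truth")
  df <- merge(gt$counts,
              gt$cells[c("cell_id", "true_class")], by = "cell_id")
  out <- do.call(rbind, lapply(split(df, list(df$gene, df$true_class),
                                     drop = TRUE), function(d) {
    frac <- d$nuclear[d$total > 0] / d$total[d$total > 0]
    data.frame(gene = d$gene[1L], class = d$true_class[1L],
               n_cells = nrow(d), mean_count = mean(d$total),
               mean_nuclear_fraction = if (length(frac)) mean(frac) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order_stable(out$gene, out$class), , drop = FALSE]
}

#' Write a simulated field to disk
#'
#' Writes the image stack (multi-page float TIFF), the truth label masks
#' (16-bit TIFF), and the truth tables (CSV) into a directory.
#'
#' @param field result of [generate_field()].
#' @param out_dir output directory.
#' @return character vector of files written, invisibly.
#' @export
write_field <- function(field, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  p1 <- file.path(out_dir, "stack.tif")
  write_image_stack(field$stack, p1)
  p2 <- file.path(out_dir, "nuclei.tif"); write_label_mask(field$nuclei, p2)
  p3 <- file.path(out_dir, "cells.tif"); write_label_mask(field$cells, p3)
  p4 <- file.path(out_dir, "truth_cells.csv")
  p5 <- file.path(out_dir, "truth_counts.csv")
  p6 <- file.path(out_dir, "truth_spots.csv")
  write.csv(field$truth$cells, p4, row.names = FALSE, quote = FALSE)
  write.csv(field$truth$counts, p5, row.names = FALSE, quote = FALSE)
  write.csv(field$truth$spots, p6, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2, p3, p4, p5, p6))
}
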