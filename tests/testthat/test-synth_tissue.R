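test_that("sim_params validates its inputs", {
  expect_error(sim_params(beta_fraction = 1.5))
  expect_error(sim_params(psf_sigma_px = 0))
  expect_error(sim_params(multiplet_size_distribution = c("1" = 1)))
  expect_error(sim_params(gene_means_beta = c(A = 1),
                          gene_means_nonbeta = c(B = 1)), "share gene names")
})

test_that("generate_field is deterministic and honours n_cells = 0", {
  p <- small_sim(seed = 11, n_cells = 0, field_shape_px = c(128, 128))
  f <- generate_field(p)
  expect_identical(mask_ids(f$nuclei), integer(0))
  expect_identical(nrow(f$truth$cells), 0L)
  expect_true(all(f$truth$spots$is_outlier))  # only autofluorescent blobs

  p2 <- small_sim(seed = 3, n_cells = 5, field_shape_px = c(512, 512))
  f1 <- generate_field(p2)
  f2 <- generate_field(p2)
  expect_identical(f1$stack$channels, f2$stack$channels)
  expect_identical(f1$truth$spots, f2$truth$spots)
  expect_identical(f1$truth$counts, f2$truth$counts)
})

test_that("noise-free rendering matches the analytic Gaussian integral", {
  p <- small_sim(seed = 4, n_cells = 3, field_shape_px = c(512, 512),
                 noise_sd = 0, background_level = 0,
                 n_autofluor_outliers = 0)
  f <- generate_field(p)
  sp <- f$truth$spots
  expected <- sum(sp$k) * p$unit_amplitude * 2 * pi * p$psf_sigma_px^2
  got <- sum(f$stack$channels$GeneA)
  # +/- 4 sigma truncation loses < 0.1% of each spot's mass
  expect_lt(abs(got - expected) / expected, 1e-3)
})

test_that("transcript conservation: truth counts equal focus multiplicities", {
  f <- generate_field(small_sim(seed = 9, n_cells = 12,
                                field_shape_px = c(768, 768),
                                genes_beta = c(GeneA = 15, GeneB = 6),
                                genes_nonbeta = c(GeneA = 2, GeneB = 1)))
  sp <- f$truth$spots[!f$truth$spots$is_outlier, ]
  expect_identical(sum(f$truth$counts$total), as.integer(sum(sp$k)))
  for (g in c("GeneA", "GeneB")) {
    cg <- f$truth$counts[f$truth$counts$gene == g, ]
    sg <- sp[sp$gene == g, ]
    per_cell <- tapply(sg$k, sg$cell_id, sum)
    for (cid in names(per_cell))
      expect_identical(cg$total[cg$cell_id == as.integer(cid)],
                       as.integer(per_cell[[cid]]))
    expect_true(all(cg$nuclear <= cg$total))
  }
})

test_that("nuclear-labelled truth spots lie inside their cell's nucleus", {
  f <- generate_field(small_sim(seed = 6, n_cells = 10,
                                field_shape_px = c(768, 768)))
  sp <- f$truth$spots[f$truth$spots$compartment == "nuclear", ]
  idx <- cbind(round(sp$y) + 1L, round(sp$x) + 1L)
  expect_true(all(f$nuclei$labels[idx] == sp$cell_id))
})

test_that("increasing unit_amplitude strictly increases peak intensities", {
  base <- list(seed = 8, n_cells = 6, field_shape_px = c(512, 512),
               noise_sd = 0, background_level = 0, n_autofluor_outliers = 0)
  f1 <- generate_field(do.call(small_sim, c(base, unit_amplitude = 100)))
  f2 <- generate_field(do.call(small_sim, c(base, unit_amplitude = 150)))
  expect_identical(f1$truth$spots[c("x", "y", "k")],
                   f2$truth$spots[c("x", "y", "k")])
  idx <- cbind(round(f1$truth$spots$y) + 1L, round(f1$truth$spots$x) + 1L)
  expect_true(all(f2$stack$channels$GeneA[idx] >
                  f1$stack$channels$GeneA[idx]))
})

test_that("truth_summary reports per-class means and nuclear fractions", {
  f <- generate_field(small_sim(seed = 2, n_cells = 4,
                                field_shape_px = c(512, 512),
                                beta_fraction = 0,
                                genes_beta = c(GeneA = 10),
                                genes_nonbeta = c(GeneA = 0)))
  ts <- truth_summary(f$truth)
  expect_identical(ts$class, "non_beta")
  expect_identical(ts$mean_count, 0)   # all cells non-beta, gene mean 0

  # hand-built truth: one cell, 5 transcripts of which 2 nuclear
  gt <- structure(list(
    cells = data.frame(cell_id = 1L, true_class = "beta"),
    counts = data.frame(cell_id = 1L, gene = "G", total = 5L, nuclear = 2L,
                        cytoplasmic = 3L),
    spots = data.frame()), class = "ground_truth")
  ts2 <- truth_summary(gt)
  expect_equal(ts2$mean_nuclear_fraction, 0.4)
  expect_equal(ts2$mean_count, 5)
  expect_error(truth_summary(structure(list(cells = data.frame()),
                                       class = "ground_truth")), "empty")
})

test_that("empirical per-cell means respect the Poisson sampling bound", {
  # mean 30 across 200 beta cells: |mean - 30| <= 3 * sqrt(30 / 200)
  f <- generate_field(sim_params(field_shape_px = c(2048, 2048),
                                 n_cells = 200, beta_fraction = 1,
                                 gene_means_beta = c(G = 30),
                                 gene_means_nonbeta = c(G = 0),
                                 noise_sd = 0, n_autofluor_outliers = 0,
                                 seed = 12))
  expect_lt(abs(mean(f$truth$counts$total) - 30), 3 * sqrt(30 / 200))
})

test_that("overfull fields fail with a clear error", {
  expect_error(generate_field(small_sim(seed = 1, n_cells = 50,
                                        field_shape_px = c(256, 256))),
               "field too small")
})
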