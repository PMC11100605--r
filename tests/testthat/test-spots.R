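render_test_spots <- function(shape, ys, xs, amps, sigma) {
  smfishq:::.cpp_render_spots(matrix(0, shape[1], shape[2]), ys, xs, amps,
                              rep(sigma, length(ys)))
}

test_that("detect_spots finds nothing on empty input and exact spots on clean input", {
  expect_identical(nrow(detect_spots(matrix(0, 64, 64))), 0L)

  # one Gaussian spot, sd 1.5 px, amplitude 100, no noise
  img <- render_test_spots(c(64, 64), 31.3, 24.7, 100, 1.5)
  det <- detect_spots(img, 1, 3, threshold = 15, n_scales = 6)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$y - 31.3), 1)
  expect_lt(abs(det$x - 24.7), 1)
  expect_lt(abs(det$sigma - 1.5) / 1.5, 0.25)

  # two spots 15 px apart
  img2 <- render_test_spots(c(64, 64), c(30, 30), c(20, 35), c(100, 100), 1.5)
  det2 <- detect_spots(img2, 1, 3, threshold = 15)
  expect_identical(nrow(det2), 2L)
})

test_that("detect_spots agrees with the brute-force LoG oracle", {
  sigmas <- exp(seq(log(1), log(3), length.out = 6))
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(3:8, 1)
    ys <- runif(n, 10, 85); xs <- runif(n, 10, 85)
    # enforce >= 12 px separation so both routes must resolve every spot
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1))
      if (keep[i] && keep[j] &&
          (ys[i] - ys[j])^2 + (xs[i] - xs[j])^2 < 144) keep[i] <- FALSE
    ys <- ys[keep]; xs <- xs[keep]
    img <- render_test_spots(c(96, 96), ys, xs, rep(100, length(ys)), 1.5)
    det <- detect_spots(img, 1, 3, threshold = 15)
    orc <- oracle_log_detect(img, sigmas, threshold = 15)
    expect_identical(nrow(det), length(ys))
    expect_identical(nrow(det), nrow(orc))
    for (i in seq_len(nrow(det))) {
      d <- sqrt((orc$y - det$y[i])^2 + (orc$x - det$x[i])^2)
      expect_lt(min(d), 1)
    }
  }
})

test_that("focus intensity estimates the full integrated intensity", {
  img <- render_test_spots(c(64, 64), 30, 30, 100, 1.5) + 10  # background 10
  det <- detect_spots(img, 1, 3, threshold = 15)
  truth <- 100 * 2 * pi * 1.5^2
  expect_lt(abs(det$intensity - truth) / truth, 0.1)
})

test_that("estimate_unit_intensity follows the worked binning example", {
  foci <- data.frame(gene = "G", intensity = c(98, 99, 100, 101, 102, 305))
  u <- estimate_unit_intensity(foci, bin_width = 10)
  expect_equal(unname(u$modal_bin), c(100, 110))
  expect_equal(u$I1, 101)
  expect_identical(u$n_support, 3L)

  all_same <- data.frame(intensity = rep(7.5, 12))
  expect_equal(estimate_unit_intensity(all_same, 1)$I1, 7.5)
  expect_error(estimate_unit_intensity(data.frame(intensity = numeric(0))),
               "no \\(non-outlier\\) foci")
  # modal-bin tie resolves to the lower-intensity bin
  tie <- data.frame(intensity = c(11, 12, 31, 32))
  expect_equal(unname(estimate_unit_intensity(tie, 10)$modal_bin), c(10, 20))
})

test_that("tukey_filter reproduces the fence worked example and edge cases", {
  foci <- data.frame(intensity = c(1, 2, 3, 4, 100))
  out <- tukey_filter(foci, k = 1.5)
  expect_identical(out$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  same <- tukey_filter(data.frame(intensity = rep(3, 8)), 1.5)
  expect_false(any(same$outlier))                 # IQR 0, fence = value

  low <- tukey_filter(data.frame(intensity = c(1, 2, 3, 4, 5)), 1.5)
  expect_false(any(low$outlier))                  # max below the fence
  expect_error(tukey_filter(data.frame(intensity = numeric(0))), "no foci")
})

test_that("tukey_filter equals the brute-force quantile oracle", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(4:60, 1)
    x <- round(rlnorm(n, 5, 1), 3)
    got <- tukey_filter(data.frame(intensity = x), k = 1.5)$outlier
    expect_identical(got, oracle_tukey_flags(x, 1.5))
  }
})

test_that("deconvolve_counts rounds, clamps and zeroes outliers", {
  unit <- structure(list(gene = "G", I1 = 100, modal_bin = c(90, 110),
                         n_support = 5L), class = "unit_intensity")
  foci <- data.frame(intensity = c(310, 40, 250, 5000),
                     outlier = c(FALSE, FALSE, FALSE, TRUE))
  out <- deconvolve_counts(foci, unit, clamp_min = 1L)
  expect_identical(out$mrna_count, c(3L, 1L, 2L, 0L))
  # round-half-to-even: 250/100 = 2.5 -> 2; 350/100 = 3.5 -> 4
  out2 <- deconvolve_counts(data.frame(intensity = c(250, 350),
                                       outlier = c(FALSE, FALSE)), unit, 1L)
  expect_identical(out2$mrna_count, c(2L, 4L))
  # monotone in intensity for fixed I1
  set.seed(4)
  xs <- sort(runif(100, 0, 1000))
  cnt <- deconvolve_counts(data.frame(intensity = xs,
                                      outlier = rep(FALSE, 100)), unit, 1L)
  expect_true(all(diff(cnt$mrna_count) >= 0))
})

test_that("assign_spots resolves cell and compartment from the masks", {
  nuc <- matrix(0L, 20, 20); nuc[5:8, 5:8] <- 1L
  nucm <- label_mask(nuc, "nucleus")
  cells <- expand_to_cells(nucm, 5)
  foci <- data.frame(x = c(6, 11, 19), y = c(6, 6, 19),
                     intensity = 1, outlier = FALSE, mrna_count = 1L)
  out <- assign_spots(foci, cells, nucm)
  expect_identical(out$cell_id, c(1L, 1L, NA_integer_))
  expect_identical(out$compartment, c("nuclear", "cytoplasmic", "unassigned"))
  bad <- data.frame(x = 25, y = 2)
  expect_error(assign_spots(bad, cells, nucm), "out of image bounds")
})

test_that("per-gene conservation: nuclear + cytoplasmic = total", {
  f <- generate_field(small_sim(seed = 13, n_cells = 10,
                                field_shape_px = c(768, 768)))
  run <- quantify_field(f$stack, small_config())
  expect_true(all(run$counts$nuclear + run$counts$cytoplasmic ==
                  run$counts$total))
  ret <- run$foci[!run$foci$outlier & !is.na(run$foci$cell_id), ]
  expect_identical(sum(run$counts$total), as.integer(sum(ret$mrna_count)))
})
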