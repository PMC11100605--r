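mk_cells <- function(n, classes = rep("beta", n)) {
  data.frame(field_id = "f", cell_id = seq_len(n), nucleus_area_px = 10L,
             cell_area_px = 20L, insulin_mean_intensity = 1,
             cell_class = classes, stringsAsFactors = FALSE)
}

test_that("per_cell_counts aggregates foci with explicit zero rows", {
  cells <- mk_cells(2)
  foci <- data.frame(field_id = "f", focus_id = 1:5, gene = "G",
                     x = 0, y = 0, sigma = 1.5, intensity = 100,
                     mrna_count = c(2L, 1L, 1L, 1L, 2L),
                     cell_id = c(1L, 1L, 1L, 1L, NA),
                     compartment = c("nuclear", "nuclear", "cytoplasmic",
                                     "cytoplasmic", "unassigned"),
                     outlier = c(FALSE, FALSE, FALSE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  # cell 1: nuclear 2+1 = 3, cytoplasmic 1+1 = 2, total 5; cell 2: zeros
  ct <- per_cell_counts(foci, cells)
  expect_identical(ct$total, c(5L, 0L))
  expect_identical(ct$nuclear, c(3L, 0L))
  expect_identical(ct$cytoplasmic, c(2L, 0L))
  # conservation: totals equal the retained focus counts
  ret <- foci[!foci$outlier & !is.na(foci$cell_id), ]
  expect_identical(sum(ct$total), as.integer(sum(ret$mrna_count)))
})

test_that("localization_fractions excludes zero-total cells", {
  ct <- data.frame(field_id = "f", cell_id = 1:3, gene = "G",
                   total = c(5L, 0L, 4L), nuclear = c(2L, 0L, 4L),
                   cytoplasmic = c(3L, 0L, 0L), cell_class = "beta",
                   stringsAsFactors = FALSE)
  loc <- localization_fractions(ct)
  expect_identical(nrow(loc$per_cell), 2L)       # zero-total cell excluded
  expect_equal(loc$per_cell$nuclear_fraction, c(0.4, 1))
  expect_equal(loc$groups$mean_nuclear_fraction, 0.7)
  expect_equal(loc$groups$n_cells, 2L)
  expect_equal(loc$groups$sem, stats::sd(c(0.4, 1)) / sqrt(2))
})

test_that("mann_whitney matches the small-sample exact examples", {
  r1 <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r1$U_statistic, 0)
  expect_equal(r1$p_value, 2 / 6)
  expect_identical(r1$method, "exact")

  r2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U_statistic, 0)
  expect_equal(r2$p_value, 0.1)

  r3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$p_value, 1)                     # identical samples

  expect_error(mann_whitney(numeric(0), 1), "empty sample")
  r4 <- mann_whitney(rnorm(30), rnorm(30))
  expect_identical(r4$method, "normal")
  expect_true(r4$p_value > 0 && r4$p_value <= 1)
  expect_true(r4$U_statistic >= 0 && r4$U_statistic <= 900)
})

test_that("exact branch equals full enumeration on tie-free inputs", {
  set.seed(31)
  for (na in 1:4) for (nb in na:4) {
    if (na + nb > 8) next
    for (rep in 1:3) {
      a <- sample(100, na); b <- setdiff(sample(200, na + nb + 5), a)[1:nb]
      r <- mann_whitney(a, b)
      expect_equal(r$p_value, oracle_mw_exact(a, b),
                   info = sprintf("na=%d nb=%d rep=%d", na, nb, rep))
    }
  }
})

test_that("normal branch agrees with the exact branch where both apply", {
  set.seed(8)
  a <- sample(1000, 6); b <- setdiff(sample(1000, 12), a)[1:6]
  exact <- mann_whitney(a, b)$p_value
  approx <- smfishq:::mann_whitney_normal_p(a, b)
  expect_lt(abs(exact - approx), 0.06)
})

test_that("ctcf implements the background correction", {
  expect_equal(ctcf(1000, 50, 4), 800)
  expect_equal(ctcf(123.5, 10, 0), 123.5)
  expect_equal(ctcf(50 * 4, 50, 4), 0)            # uniform region = background
  expect_warning(ctcf(10, 50, 4), "negative")
})

test_that("snr_normalize uses the geometric mean of IgG controls", {
  expect_equal(snr_normalize(8, c(2, 2)), 2)
  expect_equal(snr_normalize(4, c(1, 4, 16)), 0)  # geometric mean 4
  expect_equal(snr_normalize(6, c(6, 6)), 0)
  expect_error(snr_normalize(0, c(1, 2)), "positive")
  expect_error(snr_normalize(5, c(0, 2)), "positive")
})

test_that("report regenerates identical tables from the primary tables", {
  f <- generate_field(small_sim(seed = 17, n_cells = 10,
                                field_shape_px = c(768, 768)))
  run <- quantify_field(f$stack, small_config())
  d <- withr::local_tempdir()
  write_run(run, d)
  before <- lapply(c("counts.csv", "localization.csv", "group_stats.csv"),
                   function(fn) readLines(file.path(d, fn)))
  rep1 <- report(d)
  after <- lapply(c("counts.csv", "localization.csv", "group_stats.csv"),
                  function(fn) readLines(file.path(d, fn)))
  expect_identical(before, after)
  expect_identical(rep1$counts$total, run$counts$total)
})
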