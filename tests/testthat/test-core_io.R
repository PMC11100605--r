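test_that("image_stack enforces its invariants", {
  m <- matrix(1, 8, 8)
  st <- image_stack(list(nucleus = m, insulin = m), 0.03, "f1")
  expect_s3_class(st, "image_stack")
  expect_error(image_stack(list(m)), "named")
  expect_error(image_stack(list(nucleus = m, insulin = matrix(1, 4, 4))),
               "identical dimensions")
  expect_error(image_stack(list(nucleus = m - 2)), "negative")
  expect_error(image_stack(list(nucleus = m * NA)), "non-finite")
  expect_error(image_stack(list(nucleus = m), pixel_edge_um = 0), "positive")
})

test_that("label_mask enforces its invariants", {
  expect_error(label_mask(matrix(-1L, 2, 2)), ">= 0")
  expect_error(label_mask(matrix(0.5, 2, 2)), "integers")
  lm <- label_mask(matrix(c(0L, 2L, 2L, 0L), 2, 2), "nucleus")
  expect_identical(mask_ids(lm), 2L)
  expect_identical(unname(mask_areas(lm)), 2L)
})

test_that("mask_area_um2 reproduces the stated calibration", {
  expect_equal(mask_area_um2(3000, 0.03), 2.7, tolerance = 1e-12)
  expect_identical(mask_area_um2(0, 5), 0)
  expect_identical(mask_area_um2(1, 1), 1)
  expect_error(mask_area_um2(10, 0), "positive")
  expect_error(mask_area_um2(-1, 1), ">= 0")
})

test_that("TIFF writer/reader round-trips exactly, both sample types", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  set.seed(42)
  pages <- list(matrix(runif(12 * 7) * 1000, 12, 7),
                matrix(rnorm(12 * 7)^2, 12, 7))
  write_tiff(pages, tmp, type = "float64")
  back <- read_tiff(tmp)
  expect_identical(back, pages)   # bit-identical, not just equal

  lab <- matrix(sample(0:65535, 50), 10, 5)
  write_tiff(lab, tmp, type = "uint16")
  expect_identical(read_tiff(tmp)[[1L]], lab + 0)
  expect_error(write_tiff(matrix(-1, 2, 2), tmp, type = "uint16"), "0..65535")
})

test_that("read_tiff handles big-endian and multi-strip files", {
  # hand-built 2x3 big-endian uint8 TIFF, one strip per row
  tmp <- withr::local_tempfile(fileext = ".tif")
  con <- file(tmp, "wb")
  wb <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "big")
  writeChar("MM", con, eos = NULL); wb(42, 2); wb(8, 4)       # header
  n <- 10L                                                     # entries
  # IFD at offset 8; strip data after IFD: 8 + 2 + 12*10 + 4 = 134
  wb(n, 2)
  entry <- function(tag, type, value) {
    wb(tag, 2); wb(type, 2); wb(1, 4)
    if (type == 3) { wb(value, 2); wb(0, 2) } else wb(value, 4)
  }
  entry(256, 4, 3); entry(257, 4, 2); entry(258, 3, 8); entry(259, 3, 1)
  entry(262, 3, 1)
  # strip offsets/counts arrays (count 2) stored after pixel data at 140
  wb(273, 2); wb(4, 2); wb(2, 4); wb(140, 4)
  entry(277, 3, 1); entry(278, 4, 1)
  wb(279, 2); wb(4, 2); wb(2, 4); wb(148, 4)
  entry(339, 3, 1)
  wb(0, 4)                                                     # next IFD
  writeBin(as.raw(c(1, 2, 3, 9, 8, 7)), con)                   # pixels @134
  wb(c(134, 137), 4)                                           # offsets @140
  wb(c(3, 3), 4)                                               # counts @148
  close(con)
  m <- read_tiff(tmp)
  expect_length(m, 1L)
  expect_equal(m[[1L]], matrix(c(1, 2, 3, 9, 8, 7), 2, 3, byrow = TRUE))
})

test_that("load_image_stack maps planes to channels and validates counts", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(1, 6, 6), matrix(2, 6, 6), matrix(3, 6, 6),
                matrix(4, 6, 6))
  write_tiff(pages, tmp)
  st <- load_image_stack(tmp, c("nucleus", "insulin", "Cd274", "Mx1"))
  expect_named(st$channels, c("nucleus", "insulin", "Cd274", "Mx1"))
  expect_equal(st$channels$Mx1, matrix(4, 6, 6))
  expect_error(load_image_stack(tmp, letters[1:5]), "plane count < channel")
  expect_warning(load_image_stack(tmp, c("nucleus", "insulin")), "ignoring")
  expect_error(load_image_stack("no/such/file.tif", "a"), "not found")
})

test_that("a simulated field written to TIFF reloads bit-identically", {
  f <- generate_field(small_sim(seed = 5, n_cells = 4,
                                field_shape_px = c(448, 448)))
  dir <- withr::local_tempdir()
  write_field(f, dir)
  st <- load_image_stack(file.path(dir, "stack.tif"),
                         names(f$stack$channels))
  for (ch in names(f$stack$channels))
    expect_identical(st$channels[[ch]], f$stack$channels[[ch]])
  nm <- load_label_mask(file.path(dir, "nuclei.tif"), "nucleus")
  expect_identical(nm$labels, f$nuclei$labels)
})

test_that("write_tables is deterministic with a conserved count table", {
  f <- generate_field(small_sim(seed = 2, n_cells = 8,
                                field_shape_px = c(512, 512)))
  run <- quantify_field(f$stack, small_config(min_nucleus_area_px = 1000))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_tables(run$cells, run$foci, d1)
  write_tables(run$cells, run$foci, d2)
  for (fn in c("cells.csv", "foci.csv", "counts.csv"))
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  # recount oracle: per-cell totals equal the sum of retained foci counts
  counts <- read.csv(file.path(d1, "counts.csv"))
  foci <- read.csv(file.path(d1, "foci.csv"))
  ret <- foci[!foci$outlier & !is.na(foci$cell_id), ]
  for (i in seq_len(nrow(counts))) {
    sel <- ret$cell_id == counts$cell_id[i] & ret$gene == counts$gene[i]
    expect_identical(counts$total[i], as.integer(sum(ret$mrna_count[sel])))
  }
  # empty collections -> headers-only files
  d3 <- withr::local_tempdir()
  write_tables(run$cells[0, ], run$foci[0, ], d3)
  expect_length(readLines(file.path(d3, "cells.csv")), 1L)
  expect_length(readLines(file.path(d3, "foci.csv")), 1L)
})

test_that("config YAML round-trips and rejects unknown keys", {
  cfg <- pipeline_config(tukey_k = 2.5, cell_expansion_radius_px = 17)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, tmp)
  back <- read_config(tmp)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("not_a_real_key: 5", tmp)
  expect_error(read_config(tmp), "unknown config keys")
  expect_error(pipeline_config(savgol_window_bins = 4), "savgol")
  expect_error(pipeline_config(log_sigma_min_px = 3, log_sigma_max_px = 2))
})

test_that("run manifest records config and seed as YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_manifest(tmp, pipeline_config(), seed = 99,
                 inputs = list(field_id = "demo"))
  man <- yaml::read_yaml(tmp)
  expect_identical(man$seed, 99L)
  expect_identical(man$package, "smfishq")
  expect_identical(man$inputs$field_id, "demo")
  expect_equal(man$config$min_nucleus_area_px, 3000)
})
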