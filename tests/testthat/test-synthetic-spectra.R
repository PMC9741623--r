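test_that("the wavenumber grid is equally spaced with inclusive endpoints", {
  g <- make_grid(4000, 11000, 1814)
  expect_length(g, 1814)
  expect_equal(g[1], 4000)
  expect_equal(g[1814], 11000)
  expect_equal(make_grid(0, 1, 2), c(0, 1))
  expect_equal(unique(round(diff(make_grid(0, 10, 11)), 12)), 1.0)
  expect_error(make_grid(0, 10, 1), "n_points")
  expect_error(make_grid(10, 0, 5), "min_wn")
})

test_that("default class profiles encode the origin-discriminating structure", {
  profs <- default_class_profiles()
  centers <- vapply(profs, `[[`, numeric(1), "center")
  expect_setequal(centers, c(4258, 4404, 4666, 5191, 5781, 6884, 8778))
  amp <- function(wn) profs[[which(centers == wn)]]$amplitude_by_class
  # marker band present only for Changsha and Zunyi, with equal amplitude
  m <- amp(8778)
  expect_gt(m[["Changsha"]], 0)
  expect_equal(m[["Changsha"]], m[["Zunyi"]])
  expect_identical(unname(m[c("Chengdu", "Xinyang")]), c(0, 0))
  # polyphenol/sugar bands ordered Changsha > Chengdu > Xinyang > Zunyi
  for (wn in c(4258, 4666, 5781, 6884)) {
    a <- amp(wn)[maojian_classes()]
    expect_true(all(diff(a) < 0), info = paste("band", wn))
  }
  # caffeine band nearly equal across classes
  caffeine <- amp(5191)
  expect_lte(max(caffeine) / min(caffeine), 1.05)
})

test_that("synthesized scans follow the additive peak + drift + noise model", {
  grid <- make_grid(0, 100, 101)
  cfg <- generator_config(
    grid = grid,
    peaks = list(peak_spec(50, 5, c(Changsha = 1))),
    baseline = list(offset_sd = 0, slope_sd = 0, curvature_sd = 0),
    noise_sd = 0, n_per_class = 1, n_replicates = 1
  )
  y <- synthesize_scan(cfg$peaks, "Changsha", grid, cfg)
  expect_equal(which.max(y), which.min(abs(grid - 50)))
  expect_equal(max(y), 1)
  # empty peak list, no drift, no noise: the zero spectrum
  y0 <- synthesize_scan(list(), "Changsha", grid, cfg)
  expect_identical(y0, rep(0, 101))
  # determinism under a fixed RNG state
  cfg2 <- generator_config(grid = grid,
                           peaks = list(peak_spec(50, 5, c(Changsha = 1))),
                           n_per_class = 1, n_replicates = 1)
  set.seed(99); a <- synthesize_scan(cfg2$peaks, "Changsha", grid, cfg2)
  set.seed(99); b <- synthesize_scan(cfg2$peaks, "Changsha", grid, cfg2)
  expect_identical(a, b)
  # peak outside the grid span is rejected
  expect_error(
    synthesize_scan(list(peak_spec(500, 5, c(Changsha = 1))),
                    "Changsha", grid, cfg),
    "grid span")
})

test_that("generated datasets are balanced, complete and reproducible", {
  cfg <- tiny_config(n_per_class = 4, n_replicates = 3, seed = 5)
  scans <- generate_dataset(cfg)
  expect_equal(nrow(scans$absorbance), 4 * 4 * 3)
  expect_equal(length(unique(scans$sample_id)), 16)
  expect_true(all(table(scans$label) == 12))
  expect_true(all(table(scans$sample_id) == 3))
  expect_true(all(scans$replicate %in% 1:3))
  expect_identical(generate_dataset(cfg)$absorbance, scans$absorbance)
  # one sample, one replicate: 4 scans
  scans1 <- generate_dataset(tiny_config(n_per_class = 1, n_replicates = 1))
  expect_equal(nrow(scans1$absorbance), 4)
  expect_error(generator_config(n_per_class = 0), "n_per_class")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
})

test_that("replicates of one sample share amplitudes but differ in noise", {
  cfg <- tiny_config(n_per_class = 2, n_replicates = 3, seed = 3,
                     noise_sd = 0.005)
  scans <- generate_dataset(cfg)
  reps <- scans$absorbance[scans$sample_id == scans$sample_id[1], ]
  # same underlying signal: replicate means agree far more closely than
  # spectra of different samples
  expect_false(identical(reps[1, ], reps[2, ]))
  within <- max(abs(colMeans(reps[1:2, ]) - reps[3, ]))
  expect_lt(within, 0.5)
})

test_that("wide CSV round trip is the identity within tolerance", {
  scans <- generate_dataset(tiny_config(n_per_class = 2, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(scans, path)
  rt <- read_dataset(path)
  expect_equal(rt$absorbance, scans$absorbance, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(rt$sample_id, scans$sample_id)
  expect_identical(as.character(rt$label), as.character(scans$label))
  expect_identical(rt$replicate, scans$replicate)
})

test_that("malformed dataset files are rejected with informative errors", {
  scans <- generate_dataset(tiny_config(n_per_class = 1, n_replicates = 1,
                                        n_points = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(scans, path)
  lines <- readLines(path)
  # row of the wrong length
  bad <- c(lines, sub("^([^,]*,[^,]*,[^,]*,[^,]*),.*$", "\\1", lines[2]))
  badpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, badpath)
  expect_error(read_dataset(badpath), "row")
  # empty file errors rather than returning an empty dataset
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_dataset(empty), "empty")
  # unknown class label
  badlab <- gsub(",Changsha,", ",Atlantis,", lines, fixed = TRUE)
  labpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(badlab, labpath)
  expect_error(read_dataset(labpath), "Atlantis")
})

test_that("descending-grid files are reversed to ascending on read", {
  scans <- generate_dataset(tiny_config(n_per_class = 1, n_replicates = 1,
                                        n_points = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  rev_scans <- scans
  rev_scans$absorbance <- scans$absorbance[, 12:1, drop = FALSE]
  dt <- data.table::data.table(sample_id = scans$sample_id,
                               class = as.character(scans$label),
                               replicate = scans$replicate)
  spec <- data.table::as.data.table(rev_scans$absorbance)
  data.table::setnames(spec, as.character(rev(scans$wavenumber)))
  data.table::fwrite(cbind(dt, spec), path)
  expect_message(rt <- read_dataset(path), "descending")
  expect_equal(rt$absorbance, scans$absorbance, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("JCAMP-DX export writes a well-formed single-spectrum file", {
  grid <- make_grid(4000, 5000, 50)
  y <- exp(-0.5 * ((grid - 4500) / 100)^2)
  path <- withr::local_tempfile(fileext = ".jdx")
  write_jdx(y, grid, path, title = "test spectrum")
  lines <- readLines(path)
  expect_true(any(grepl("^##TITLE=test spectrum", lines)))
  expect_true(any(grepl("^##NPOINTS=50$", lines)))
  expect_true(any(grepl("^##XYDATA=", lines)))
  expect_identical(lines[length(lines)], "##END=")
})
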