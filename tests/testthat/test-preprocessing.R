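test_that("replicate averaging is the pointwise mean per sample", {
  wn <- c(1, 2)
  x <- rbind(c(0, 0), c(3, 3), c(6, 6))
  scans <- nir_spectra(x, wn, rep("s1", 3), rep("Changsha", 3),
                       replicate = 1:3)
  avg <- average_replicates(scans)
  expect_equal(unname(avg$absorbance[1, ]), c(3, 3))
  expect_equal(nrow(avg$absorbance), 1)
  expect_null(avg$replicate)
  # three identical scans average to themselves
  same <- nir_spectra(rbind(c(1, 2), c(1, 2), c(1, 2)), wn,
                      rep("s1", 3), rep("Zunyi", 3), replicate = 1:3)
  expect_equal(unname(average_replicates(same)$absorbance[1, ]), c(1, 2))
  # labels preserved, one spectrum per sample
  scans2 <- generate_dataset(tiny_config(n_per_class = 3, n_replicates = 2))
  avg2 <- average_replicates(scans2)
  expect_equal(nrow(avg2$absorbance), 12)
  expect_true(all(table(avg2$label) == 3))
  # a sample with inconsistent labels is rejected
  mixed <- nir_spectra(rbind(c(1, 2), c(1, 2)), wn, c("s1", "s1"),
                       c("Changsha", "Zunyi"), replicate = 1:2)
  expect_error(average_replicates(mixed), "inconsistent")
})

test_that("spectra on different grids cannot be combined", {
  expect_error(nir_spectra(matrix(1:4, 2), c(1, 2, 3), c("a", "b"),
                           c("Changsha", "Zunyi")),
               "wavenumber")
})

test_that("rubber-band correction matches the worked example and hull maths", {
  expect_equal(rubber_band_baseline(c(1, 3, 0.5, 2, 1), 0:4),
               c(0, 2.25, 0, 1.25, 0))
  # a straight-line spectrum is its own hull
  x <- seq_len(20)
  expect_equal(rubber_band_baseline(2 + 0.5 * x, x), rep(0, 20))
  expect_error(rubber_band_baseline(c(1, 2), 1:2), "3 points")
  expect_error(rubber_band_baseline(c(1, NA, 2), 1:3), "finite")
  expect_error(rubber_band_baseline(1:5, 1:5, n_anchor = 1), "n_anchor")
})

test_that("rubber-band correction satisfies its invariants on random spectra", {
  set.seed(101)
  for (rep in 1:25) {
    y <- random_spectrum(60)
    x <- seq(4000, 9000, length.out = 60)
    res <- rubber_band_baseline(y, x, details = TRUE)
    expect_true(all(res$corrected >= 0))
    expect_true(all(abs(res$corrected[res$vertices]) < 1e-12))
    # affine invariance
    a <- rnorm(1); b <- rnorm(1, 0, 1e-3)
    shifted <- rubber_band_baseline(y + a + b * x, x)
    expect_lt(max(abs(shifted - res$corrected)), 1e-9)
    # idempotence
    again <- rubber_band_baseline(res$corrected, x)
    expect_lt(max(abs(again - res$corrected)), 1e-9)
  }
})

test_that("the hull baseline equals the brute-force lower envelope", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    x <- sort(runif(n)); x <- x + seq_len(n) * 1e-3
    y <- rnorm(n)
    res <- rubber_band_baseline(y, x, details = TRUE)
    expect_equal(res$baseline, brute_force_lower_envelope(x, y),
                 tolerance = 1e-10)
  }
})

test_that("min-max normalization maps onto [0, 1] and keeps rankings", {
  expect_equal(min_max_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  v <- c(0, 0.25, 1, 0.5)
  expect_identical(min_max_normalize(v), v)
  expect_warning(z <- min_max_normalize(c(7, 7, 7)), "constant")
  expect_identical(z, c(0, 0, 0))
  expect_error(min_max_normalize(c(1, Inf)), "finite")
  set.seed(2)
  for (rep in 1:10) {
    y <- rnorm(40)
    z <- min_max_normalize(y)
    expect_identical(order(y), order(z))
    expect_equal(range(z), c(0, 1))
  }
})

test_that("the stratified split honours counts, disjointness and the seed", {
  scans <- generate_dataset(tiny_config(n_per_class = 10, n_replicates = 1))
  ds <- average_replicates(scans)
  sp <- split_dataset(ds, test_fraction = 0.3, val_per_class = 2, seed = 4)
  expect_equal(length(sp$test), 4 * 3)
  expect_equal(length(sp$validation), 4 * 2)
  expect_equal(length(sp$train), 4 * 5)
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all_idx), seq_len(40))
  expect_equal(anyDuplicated(all_idx), 0)
  # per-class balance in each partition
  for (part in sp) expect_true(all(table(ds$label[part]) ==
                                     length(part) / 4))
  expect_identical(split_dataset(ds, 0.3, 2, seed = 4), sp)
  expect_false(identical(split_dataset(ds, 0.3, 2, seed = 5), sp))
  # 10-sample class at 0.3 with no validation: 7 train / 3 test
  sp2 <- split_dataset(ds, 0.3, 0, seed = 1)
  expect_equal(length(sp2$train), 28)
  expect_equal(length(sp2$test), 12)
  expect_error(split_dataset(ds, 0.3, 7, seed = 1), "too small")
  expect_error(split_dataset(ds, 1.2, 0, seed = 1), "test_fraction")
})

test_that("the preprocessing chain composes the stages in order", {
  cfg <- tiny_config(n_per_class = 10, n_replicates = 2, seed = 6)
  prep <- preprocess(generate_dataset(cfg), test_fraction = 0.3,
                     val_per_class = 2, seed = 9)
  expect_equal(nrow(prep$dataset$absorbance), 40)
  expect_true(all(prep$dataset$absorbance >= 0 &
                    prep$dataset$absorbance <= 1))
  expect_equal(unname(apply(prep$dataset$absorbance, 1, min)), rep(0, 40))
  expect_equal(unname(apply(prep$dataset$absorbance, 1, max)), rep(1, 40))
  expect_equal(length(prep$split$train), 20)
  expect_equal(length(prep$split$validation), 8)
  expect_equal(length(prep$split$test), 12)
  expect_identical(prep$manifest$stages[1], "average_replicates")
  # same seed, same split
  prep2 <- preprocess(generate_dataset(cfg), 0.3, 2, seed = 9)
  expect_identical(prep2$split, prep$split)
})

test_that("processed class means keep the generator's peak ordering", {
  prep <- preprocess(generate_dataset(clean_config(n_per_class = 4)),
                     val_per_class = 0, seed = 2)
  ds <- prep$dataset
  grid <- ds$wavenumber
  band <- which(abs(grid - 4666) < 40)
  marker <- which(abs(grid - 8778) < 40)
  mean_at <- function(cl, idx) {
    mean(ds$absorbance[ds$label == cl, idx])
  }
  # polyphenol band ordering survives the pipeline
  at4666 <- vapply(maojian_classes(), mean_at, numeric(1), idx = band)
  expect_gt(at4666[["Changsha"]], at4666[["Zunyi"]])
  # marker band separates {Changsha, Zunyi} from {Chengdu, Xinyang}
  at8778 <- vapply(maojian_classes(), mean_at, numeric(1), idx = marker)
  expect_gt(min(at8778[c("Changsha", "Zunyi")]),
            max(at8778[c("Chengdu", "Xinyang")]) + 0.05)
})
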