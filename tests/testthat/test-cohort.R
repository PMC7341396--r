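test_that("stage covariance realizes the block structure exactly", {
  ## zero correlations -> identity
  w0 <- matrix(0, 2, 4, dimnames = list(c("A", "B"), ad_stages()))
  cfg0 <- cohort_config(n_rois = 6L, n_timepoints = 40L,
                        partition = tiny_partition(3L), within_r = w0,
                        between_r = 0,
                        network_pattern = c(A = "none", B = "none"))
  expect_equal(unname(build_stage_covariance(cfg0, "NC")[1:6, 1:6]),
               diag(6), ignore_attr = TRUE)

  ## 2 networks of 2 ROIs: direct construction
  w <- matrix(0.5, 2, 4, dimnames = list(c("A", "B"), ad_stages()))
  cfg <- cohort_config(n_rois = 4L, n_timepoints = 40L,
                       partition = rsn_partition(c("A", "A", "B", "B")),
                       within_r = w, between_r = 0.1,
                       network_pattern = c(A = "none", B = "none"))
  sg <- build_stage_covariance(cfg, "EMCI")
  expected <- rbind(c(1, .5, .1, .1), c(.5, 1, .1, .1),
                    c(.1, .1, 1, .5), c(.1, .1, .5, 1))
  expect_equal(unname(sg[1:4, 1:4]), expected, ignore_attr = TRUE)

  ## the DMN default U-shape is read back from the four stage matrices
  cc <- cohort_config()
  idx <- network_indices(cc$partition, "DMN")[1:2]
  vals <- vapply(ad_stages(), function(st)
    build_stage_covariance(cc, st)[idx[1], idx[2]], 0)
  expect_equal(unname(vals), c(0.30, 0.45, 0.35, 0.20))

  ## all four stage covariances are PD
  for (st in ad_stages()) {
    ev <- eigen(build_stage_covariance(cc, st), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("config validation enforces trajectory shapes and MMSE sanity", {
  w <- default_within_r()
  w["DMN", "EMCI"] <- 0.10  # breaks the rise-then-fall shape
  expect_error(cohort_config(within_r = w), "inversion network DMN")
  w <- default_within_r()
  w["SEN", "AD"] <- 0.50    # breaks strict decline
  expect_error(cohort_config(within_r = w), "decline network SEN")
  mm <- default_mmse_params()
  mm["AD", "sd"] <- -1
  expect_error(cohort_config(mmse_params = mm), "sd must be nonnegative")
})

test_that("generated cohort has the configured group sizes and is seeded", {
  cc <- cohort_config(seed = 7L)
  coh <- generate_cohort(cc)
  expect_length(coh, 130L)
  st <- vapply(coh, function(s) s$stage, "")
  expect_equal(as.integer(table(factor(st, ad_stages()))),
               c(35L, 37L, 33L, 25L))
  coh2 <- generate_cohort(cc)
  expect_identical(coh[[1]]$data, coh2[[1]]$data)
  expect_identical(vapply(coh, `[[`, 0L, "mmse"),
                   vapply(coh2, `[[`, 0L, "mmse"))
  coh3 <- generate_cohort(cohort_config(seed = 8L))
  expect_false(identical(coh[[1]]$data, coh3[[1]]$data))

  empty <- generate_cohort(tiny_cohort_config(
    sizes = c(NC = 0L, EMCI = 0L, LMCI = 0L, AD = 0L)))
  expect_length(empty, 0L)
})

test_that("MMSE draws match the configured stage distribution", {
  cc <- tiny_cohort_config(T = 30L,
                           sizes = c(NC = 0L, EMCI = 0L, LMCI = 0L, AD = 10000L),
                           seed = 42L)
  coh <- generate_cohort(cc)
  mmse <- vapply(coh, `[[`, 0L, "mmse")
  expect_true(all(mmse >= 0 & mmse <= 30))
  expect_lt(abs(mean(mmse) - 22.72), 0.1)
  expect_lt(abs(sd(mmse) - 2.41), 0.15)
})

test_that("within-network correlations converge to their targets", {
  cc <- tiny_cohort_config(T = 5000L,
                           sizes = c(NC = 1L, EMCI = 0L, LMCI = 0L, AD = 1L),
                           seed = 3L)
  coh <- generate_cohort(cc)
  for (s in coh) {
    C <- cor(s$data)
    target <- cc$within_r["A", s$stage]
    within <- C[1:3, 1:3][upper.tri(diag(3))]
    expect_lt(abs(mean(within) - target), 0.03)
    between <- C[1:3, 4:6]
    expect_lt(abs(mean(between) - cc$between_r), 0.03)
  }
})

test_that("cohorts round-trip losslessly through the TSV writer", {
  cc <- tiny_cohort_config(seed = 5L)
  coh <- generate_cohort(cc)
  dir <- tempfile()
  manifest <- write_cohort(coh, dir)
  back <- read_cohort(manifest)
  expect_length(back, length(coh))
  for (i in seq_along(coh)) {
    expect_identical(back[[i]]$stage, coh[[i]]$stage)
    expect_identical(back[[i]]$mmse, coh[[i]]$mmse)
    expect_equal(back[[i]]$data, coh[[i]]$data, tolerance = 0)
  }
  expect_equal(length(list.files(dir, pattern = "\\.tsv$")),
               length(coh) + 1L)  # one file per subject + manifest

  ## empty cohort -> manifest with header only
  dir2 <- tempfile()
  m2 <- write_cohort(structure(list(), class = c("stage_cohort", "list")), dir2)
  expect_length(readLines(m2), 1L)

  ## duplicate subject ids rejected
  dup <- c(coh[1], coh[1])
  expect_error(write_cohort(dup, tempfile()), "duplicate")
})

test_that("time-series validation catches degenerate inputs", {
  x <- matrix(rnorm(35 * 4), 35, 4)
  x[, 2] <- 1
  expect_error(roi_timeseries("s1", "NC", 30, x), "zero variance: 2")
  expect_error(roi_timeseries("s1", "NC", 30, matrix(rnorm(20), 10, 2)),
               "at least 30 time points")
  expect_error(roi_timeseries("s1", "NC", 31, matrix(rnorm(120), 40, 3)),
               "MMSE")
})
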