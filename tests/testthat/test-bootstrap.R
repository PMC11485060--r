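test_that("stratified resampling preserves stratum sizes exactly", {
  d <- as_exposure_data(oral_tab())
  for (s in 1:5) {
    r <- stratified_resample(d, seed = s)
    expect_equal(sum(r$outcome), sum(d$outcome))
    expect_equal(r$n, d$n)
  }
  r1 <- stratified_resample(d, seed = 42)
  r2 <- stratified_resample(d, seed = 42)
  expect_identical(r1$level, r2$level)
  tiny <- exposure_data(outcome = c(1, 0), level = c("A1B1", "A0B0"))
  expect_equal(unclass(as_count_table(stratified_resample(tiny, 1))),
               unclass(as_count_table(tiny)))
  expect_error(stratified_resample(
    exposure_data(outcome = c(1, 1), level = c("A0B0", "A1B1"))),
    "strata")
})

test_that("bootstrap intervals are seed-reproducible", {
  spec <- bootstrap_spec(replicates = 200, seed = 11)
  a <- bootstrap_ci(oral_tab(), "RERI", spec)
  b <- bootstrap_ci(oral_tab(), "RERI", spec)
  expect_identical(c(a$lower, a$upper), c(b$lower, b$upper))
  c2 <- bootstrap_ci(oral_tab(), "RERI",
                     bootstrap_spec(replicates = 200, seed = 12))
  expect_false(identical(a$lower, c2$lower))
})

test_that("the three bootstrap measures give concordant verdicts on one stream", {
  concordant <- 0; total <- 0
  for (s in 1:40) {
    d <- generate_dataset(standard_scenarios("S3")[[1]], n = 300,
                          seed = 500 + s)
    spec <- bootstrap_spec(replicates = 150, seed = s)
    ests <- lapply(c("RERI", "AP", "S"), function(m)
      bootstrap_ci(d, m, spec))
    v <- vapply(ests, function(e) e$verdict, "")
    if (all(v != "undefined")) {
      total <- total + 1
      if (length(unique(v)) == 1L) concordant <- concordant + 1
    }
  }
  expect_gte(concordant / total, 0.95)
})

test_that("the percentile interval usually contains the point estimate", {
  hits <- 0
  for (s in 1:30) {
    d <- generate_dataset(standard_scenarios("S2")[[1]], n = 400,
                          seed = 900 + s)
    est <- bootstrap_ci(d, "RERI", bootstrap_spec(replicates = 200, seed = s))
    if (est$lower <= est$point && est$point <= est$upper) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.95)
})

test_that("degenerate resamples are counted and handled per policy", {
  # a sparse cell makes empty-cell resamples likely
  tab <- count_table(c(2, 30, 30, 30), c(30, 30, 30, 2))
  est <- bootstrap_ci(tab, "RERI",
                      bootstrap_spec(replicates = 300, seed = 5,
                                     zero_cell_policy = "correct"))
  expect_equal(est$diagnostics$degenerate, 0)  # correction repairs them all
  est2 <- bootstrap_ci(tab, "RERI",
                       bootstrap_spec(replicates = 300, seed = 5,
                                      zero_cell_policy = "drop"))
  expect_gt(est2$diagnostics$degenerate, 0)
  expect_equal(est2$diagnostics$valid + est2$diagnostics$degenerate, 300)
})

test_that("row-level resampling path handles confounder-adjusted data", {
  set.seed(8)
  n <- 500
  z <- rnorm(n)
  cell <- sample.int(4, n, replace = TRUE)
  eta <- c(0, 1, 1, 2)[cell] - 0.5 + 0.5 * z
  d <- exposure_data(outcome = rbinom(n, 1, plogis(eta)),
                     level = c("A0B0", "A1B0", "A0B1", "A1B1")[cell],
                     confounders = cbind(z = z))
  est <- bootstrap_ci(d, "RERI", bootstrap_spec(replicates = 60, seed = 2))
  expect_true(is.finite(est$lower) && is.finite(est$upper))
  expect_lte(est$lower, est$upper)
})
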