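test_that("oral-cancer unconstrained fit reproduces the published values", {
  fit <- fit_unconstrained(oral_tab())
  # coefficients in input column order (a_only, b_only, both); the source
  # table's single-factor labels are interchangeable
  expect_lt(max(abs(unname(fit$theta) - c(1.086, 1.204, 2.201))), 1e-3)
  expect_lt(abs(gdev(fit) - 605.93), 0.02)
  expect_false(fit$constrained)
  expect_equal(fit$df, 4L)
})

test_that("saturated closed form agrees with the iterative MLE", {
  for (s in 1:10) {
    tab <- random_table(s)
    a <- saturated_from_counts(tab)
    b <- fit_unconstrained(as_exposure_data(tab))  # IRLS route
    expect_equal(a$theta, b$theta, tolerance = 1e-6)
    expect_equal(a$theta0, b$theta0, tolerance = 1e-6)
    expect_equal(a$loglik, b$loglik, tolerance = 1e-8)
    expect_equal(unname(a$vcov), unname(b$vcov), tolerance = 1e-4)
  }
})

test_that("saturated closed-form pieces match their definitions", {
  s <- saturated_from_counts(oral_tab())
  expect_equal(unname(s$theta[3]), log((225 * 20) / (166 * 3)),
               tolerance = 1e-12)
  u <- saturated_from_counts(count_table(rep(10, 4), rep(10, 4)))
  expect_equal(unname(u$theta), c(0, 0, 0))
  expect_equal(unname(diag(u$vcov)[2:4]), rep(0.4, 3))
  expect_error(saturated_from_counts(count_table(c(0, 1, 1, 1), rep(5, 4))),
               "zero cell")
})

test_that("product-term and combined-level parameterizations are equivalent", {
  for (s in 1:12) {
    tab <- random_table(100 + s)
    fit <- fit_unconstrained(tab)
    or <- product_term_fit(tab)
    expect_equal(unname(fit$theta),
                 c(or$beta[2], or$beta[3], or$beta[2] + or$beta[3] + or$beta[4]),
                 tolerance = 1e-5)
    expect_equal(fit$loglik, or$loglik, tolerance = 1e-6)
  }
})

test_that("constrained fit lies on the manifold and never beats the MLE", {
  fit <- fit_constrained(oral_tab())
  th <- fit$theta
  expect_lt(abs(exp(th[3]) - exp(th[1]) - exp(th[2]) + 1), 1e-8)
  expect_lt(max(abs(sort(unname(th[1:2])) - c(1.497, 1.882))), 5e-3)
  expect_lt(abs(unname(th[3]) - 2.306), 5e-3)
  expect_lt(abs(gdev(fit) - 607.73), 0.02)
  expect_equal(fit$df, 3L)
  for (s in 1:15) {
    tab <- random_table(200 + s)
    mc <- fit_constrained(tab)
    mu <- fit_unconstrained(tab)
    expect_lt(abs(interaction_contrast(mc$theta)), 1e-8)
    expect_gte(gdev(mc) - gdev(mu), -1e-6)
  }
})

test_that("constrained fit is exact when the data are additive by construction", {
  d <- generate_dataset(scenario_spec("null", 4, 5, 8), n = 20000, seed = 17)
  mu <- fit_unconstrained(d); mc <- fit_constrained(d)
  expect_lt(gdev(mc) - gdev(mu), 3)  # chi2(1) scale fluctuation
  expect_true(mc$converged)
})

test_that("fitting errors are informative", {
  expect_error(fit_unconstrained(count_table(c(3, 0, 6, 225),
                                             c(20, 18, 12, 166))),
               "separation|a_only")
  expect_error(
    fit_unconstrained(exposure_data(outcome = c(1, 1), level = c("A0B0", "A1B1"))),
    "degenerate")
})

test_that("deviance scores held-out data at the fitted coefficients", {
  tab <- oral_tab()
  fit <- fit_unconstrained(tab)
  expect_equal(gdev(fit, tab), gdev(fit), tolerance = 1e-8)
  # scoring at probability one-half costs 2 log 2 per subject
  even <- saturated_from_counts(count_table(rep(10, 4), rep(10, 4)))
  d <- as_exposure_data(count_table(rep(3, 4), rep(3, 4)))
  expect_equal(gdev(even, d), 2 * d$n * log(2), tolerance = 1e-8)
  dz <- exposure_data(outcome = c(1, 0), level = c("A0B0", "A0B0"),
                      confounders = cbind(z = c(1, 2)))
  expect_error(gdev(fit, dz), "confounder")
})

test_that("confounders are adjusted and leave the constraint untouched", {
  set.seed(42)
  n <- 2000
  z <- rnorm(n)
  cell <- sample.int(4, n, replace = TRUE)
  eta <- c(0, log(4), log(5), log(8))[cell] - 1 + 0.7 * z
  d <- exposure_data(outcome = rbinom(n, 1, plogis(eta)),
                     level = c("A0B0", "A1B0", "A0B1", "A1B1")[cell],
                     confounders = cbind(z = z))
  mu <- fit_unconstrained(d)
  expect_equal(mu$df, 5L)
  expect_equal(unname(mu$gamma), 0.7, tolerance = 0.15)
  mc <- fit_constrained(d)
  expect_equal(mc$df, 4L)
  expect_lt(abs(interaction_contrast(mc$theta)), 1e-8)
  expect_gte(gdev(mc) - gdev(mu), -1e-6)
})
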