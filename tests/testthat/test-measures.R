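test_that("measure algebra reproduces the scenario table", {
  # (or10, or01, or11) -> (RERI, AP, S) for the seven standard scenarios
  expected <- list(
    S1 = c(20, 12,  0.60, 2.71),
    S2 = c(16,  8,  0.50, 2.14),
    S3 = c(12,  4,  0.33, 1.57),
    S4 = c(8,   0,  0.00, 1.00),
    S5 = c(6,  -2, -0.33, 0.71),
    S6 = c(4,  -4, -1.00, 0.43),
    S7 = c(2,  -6, -3.00, 0.14))
  for (nm in names(expected)) {
    e <- expected[[nm]]
    th <- log(c(4, 5, e[1]))
    expect_equal(reri(th), e[2], tolerance = 1e-9)
    expect_equal(round(ap(th), 2), e[3])
    expect_equal(round(as.numeric(synergy_index(th)), 2), e[4])
  }
})

test_that("RERI, AP and S are coherent in sign and null value", {
  set.seed(1)
  for (i in 1:1000) {
    th <- stats::runif(3, -1.5, 2.5)
    r <- reri(th); a <- ap(th); s <- synergy_index(th)
    expect_equal(a * exp(th[3]), r, tolerance = 1e-12)
    expect_equal(sign(r), sign(a))
    if (!is.na(s)) {
      expect_equal(r == 0, abs(s - 1) < 1e-12)
      # S above/below 1 exactly when RERI above/below 0
      expect_equal(sign(r), sign(s - 1) * (abs(s - 1) > 0))
    }
  }
})

test_that("S is undefined exactly when its denominator is nonpositive", {
  u <- synergy_index(c(log(0.5), log(0.5), 1))
  expect_true(is.na(u))
  expect_true(attr(u, "undefined"))
  expect_false(is.na(synergy_index(log(c(2, 2, 3)))))
  expect_equal(as.numeric(synergy_index(log(c(2, 2, 3)))), 1)
})

test_that("measures increase with the joint-exposure coefficient", {
  th3 <- seq(0.2, 3, by = 0.2)
  r <- sapply(th3, function(t3) reri(c(log(2), log(3), t3)))
  a <- sapply(th3, function(t3) ap(c(log(2), log(3), t3)))
  s <- sapply(th3, function(t3) as.numeric(synergy_index(c(log(2), log(3), t3))))
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(a) > 0))
  expect_true(all(diff(s) > 0))
})

test_that("delta gradients match central finite differences", {
  fns <- list(RERI = reri, AP = ap,
              S = function(th) log(as.numeric(synergy_index(th))))
  set.seed(7)
  for (i in 1:20) {
    th <- stats::runif(3, 0.2, 2)   # S well-defined and positive
    for (m in names(fns)) {
      g <- addint:::.measure_gradient(m, th)
      h <- 1e-6
      num <- sapply(1:3, function(j) {
        e <- replace(numeric(3), j, h)
        (fns[[m]](th + e) - fns[[m]](th - e)) / (2 * h)
      })
      expect_equal(g, num, tolerance = 1e-4)
    }
  }
})

test_that("delta variance agrees with a parametric-bootstrap oracle", {
  # well-populated table so the first-order approximation is accurate
  fit <- fit_unconstrained(count_table(c(100, 120, 90, 110),
                                       c(95, 85, 105, 100)))
  est <- delta_ci(fit, "RERI")
  set.seed(99)
  Sg <- fit$vcov[2:4, 2:4]
  L <- chol(Sg)
  draws <- matrix(stats::rnorm(3 * 40000), ncol = 3) %*% L
  draws <- sweep(draws, 2, fit$theta, "+")
  boot_var <- stats::var(exp(draws[, 3]) - exp(draws[, 1]) -
                           exp(draws[, 2]) + 1)
  # first-order delta vs simulated variance of the nonlinear transform
  expect_equal(est$diagnostics$se^2, boot_var, tolerance = 0.1)
})

test_that("delta intervals and verdicts behave per the null-value rule", {
  fit <- fit_unconstrained(oral_tab())
  for (m in c("RERI", "AP", "S")) {
    est <- delta_ci(fit, m)
    expect_equal(est$verdict, "no_interaction")
    expect_lte(est$lower, est$point)
    expect_gte(est$upper, est$point)
  }
  expect_error(delta_ci(fit_constrained(oral_tab()), "RERI"), "unconstrained")
})

test_that("interval classification uses closed containment", {
  mk <- function(measure, lo, hi)
    addint:::new_measure_estimate(measure, (lo + hi) / 2, lo, hi, 0.95, "delta")
  expect_equal(mk("RERI", -0.2, 3.1)$verdict, "no_interaction")
  expect_equal(mk("S", 1.2, 4.0)$verdict, "interaction")
  expect_equal(mk("AP", 0.0, 0.4)$verdict, "no_interaction")  # boundary
  expect_equal(mk("S", 0.3, 0.9)$verdict, "interaction")
})
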