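# Additive-interaction measures on the odds-ratio scale.
#
# With theta = (theta1, theta2, theta3) the log odds ratios of the A-only,
# B-only and jointly exposed cells against the unexposed cell:
#   RERI = e^theta3 - e^theta1 - e^theta2 + 1      (0 under additivity)
#   AP   = RERI / e^theta3                         (0 under additivity)
#   S    = (e^theta3 - 1)/(e^theta1 + e^theta2 - 2) (1 under additivity)
# The interaction contrast IC coincides with RERI when the reference risk
# is 1, and IC = 0 <=> RERI = AP = 0 <=> S = 1 (where S is defined).

.theta3 <- function(x) {
  if (inherits(x, "addint_fit")) x$theta else {
    stopifnot(is.numeric(x), length(x) == 3L)
    x
  }
}

#' Additive-interaction measures
#'
#' Point estimators of the relative excess risk due to interaction (RERI),
#' the attributable proportion due to interaction (AP), the synergy index
#' (S) and the interaction contrast (IC) from the three non-reference
#' coefficients of the combined-level logistic model.
#'
#' @param theta numeric vector `(theta1, theta2, theta3)` of log odds
#'   ratios, or an `addint_fit`.
#' @return A single number. `synergy_index()` returns `NA` with attribute
#'   `undefined = TRUE` when its denominator
#'   \eqn{e^{\theta_1}+e^{\theta_2}-2} is zero or negative (both
#'   single-factor odds ratios on the protective side), a value state rather
#'   than an error.
#' @examples
#' reri(log(c(4, 5, 20)))           # 12
#' ap(log(c(4, 5, 12)))             # 1/3
#' synergy_index(log(c(4, 5, 20)))  # 19/7
#' @export
reri <- function(theta) {
  th <- .theta3(theta)
  if (any(!is.finite(th))) return(structure(NA_real_, undefined = TRUE))
  exp(th[3]) - exp(th[1]) - exp(th[2]) + 1
}

#' @rdname reri
#' @export
ap <- function(theta) {
  th <- .theta3(theta)
  if (any(!is.finite(th))) return(structure(NA_real_, undefined = TRUE))
  (exp(th[3]) - exp(th[1]) - exp(th[2]) + 1) / exp(th[3])
}

#' @rdname reri
#' @export
synergy_index <- function(theta) {
  th <- .theta3(theta)
  if (any(!is.finite(th))) return(structure(NA_real_, undefined = TRUE))
  den <- exp(th[1]) + exp(th[2]) - 2
  if (den <= 0 || abs(den) < 1e-12)
    return(structure(NA_real_, undefined = TRUE))
  (exp(th[3]) - 1) / den
}

#' @rdname reri
#' @export
interaction_contrast <- function(theta) reri(theta)

.null_value <- c(RERI = 0, AP = 0, S = 1, IC = 0)

new_measure_estimate <- function(measure, point, lower = NA_real_,
                                 upper = NA_real_, level = NA_real_,
                                 method = NA_character_,
                                 diagnostics = NULL) {
  est <- structure(
    list(measure = measure, point = point, lower = lower, upper = upper,
         level = level, method = method,
         null_value = unname(.null_value[measure]),
         verdict = NA_character_, diagnostics = diagnostics),
    class = "measure_estimate")
  est$verdict <- classify_interaction(est)
  est
}

#' Interaction verdict from a confidence interval
#'
#' A measure indicates no additive interaction when its confidence interval
#' contains the null value (0 for RERI, AP and IC; 1 for S); containment is
#' closed, so a bound exactly at the null counts as containing it. An
#' undefined estimate (e.g. S with nonpositive denominator) yields verdict
#' `"undefined"`.
#'
#' @param estimate a `measure_estimate` as returned by [delta_ci()] or
#'   [bootstrap_ci()].
#' @return `"interaction"`, `"no_interaction"` or `"undefined"`.
#' @export
classify_interaction <- function(estimate) {
  stopifnot(inherits(estimate, "measure_estimate"))
  if (!is.finite(estimate$point)) return("undefined")
  if (!is.finite(estimate$lower) || !is.finite(estimate$upper))
    return("undefined")
  nv <- estimate$null_value
  if (estimate$lower <= nv && nv <= estimate$upper) "no_interaction"
  else "interaction"
}

#' @export
print.measure_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4g", x$measure, x$point))
  if (is.finite(x$lower))
    cat(sprintf("  [%.4g, %.4g] (%.0f%% %s)",
                x$lower, x$upper, 100 * x$level, x$method))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

# gradients of the measures w.r.t. (theta1, theta2, theta3)
.measure_gradient <- function(measure, th) {
  e1 <- exp(th[1]); e2 <- exp(th[2]); e3 <- exp(th[3])
  switch(measure,
    RERI = ,
    IC = c(-e1, -e2, e3),
    AP = c(-e1 / e3, -e2 / e3, (e1 + e2 - 1) / e3),
    # gradient of log S (interval built on the log scale)
    S = {
      den <- e1 + e2 - 2
      c(-e1 / den, -e2 / den, e3 / (e3 - 1))
    })
}

#' Delta-method confidence interval for an interaction measure
#'
#' Propagates the covariance of \eqn{(\hat\theta_1,\hat\theta_2,
#' \hat\theta_3)} to the measure by a first-order Taylor expansion. RERI and
#' AP intervals are symmetric on the natural scale (normal approximation);
#' the S interval is built on the log scale and exponentiated back
#' (log-normal approximation).
#'
#' @param model an unconstrained `addint_fit` (the constrained fit has a
#'   degenerate measure distribution and is rejected).
#' @param measure one of `"RERI"`, `"AP"`, `"S"`, `"IC"`.
#' @param level confidence level, default 0.95.
#' @return A `measure_estimate` with point, bounds, standard error (in
#'   `diagnostics$se`, log-scale for S) and verdict.
#' @examples
#' fit <- fit_unconstrained(oral_cancer_counts())
#' delta_ci(fit, "RERI")
#' delta_ci(fit, "S")
#' @export
delta_ci <- function(model, measure = c("RERI", "AP", "S", "IC"),
                     level = 0.95) {
  measure <- match.arg(measure)
  stopifnot(inherits(model, "addint_fit"))
  if (model$constrained)
    stop("delta_ci() needs the unconstrained fit: the constrained model ",
         "fixes the measure at its null value", call. = FALSE)
  stopifnot(level > 0, level < 1)
  th <- model$theta
  pt <- switch(measure, RERI = reri(th), IC = reri(th), AP = ap(th),
               S = synergy_index(th))
  if (!is.finite(pt) || (measure == "S" && pt <= 0))
    return(new_measure_estimate(measure,
                                if (is.finite(pt)) pt else NA_real_,
                                level = level, method = "delta"))
  Sg <- model$vcov[2:4, 2:4]
  g <- .measure_gradient(measure, th)
  v <- drop(t(g) %*% Sg %*% g)
  z <- qnorm(1 - (1 - level) / 2)
  if (measure == "S") {
    se <- sqrt(v)                      # SE of log S
    lo <- pt * exp(-z * se); hi <- pt * exp(z * se)
    if (pt < 0) { tmp <- lo; lo <- hi; hi <- tmp }
  } else {
    se <- sqrt(v)
    lo <- pt - z * se; hi <- pt + z * se
  }
  new_measure_estimate(measure, pt, lo, hi, level, "delta",
                       diagnostics = list(se = se))
}

#' @export
as.data.frame.measure_estimate <- function(x, ...) {
  data.frame(measure = x$measure, point = x$point, lower = x$lower,
             upper = x$upper, level = x$level, method = x$method,
             verdict = x$verdict, stringsAsFactors = FALSE)
}
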