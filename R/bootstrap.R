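# Outcome-stratified bootstrap for RERI, AP and S.
#
# Case-control designs fix the numbers of cases and controls, so resampling
# is done with replacement separately within Y = 1 and Y = 0; every
# bootstrap sample has exactly the original stratum sizes. Without
# confounders the exposure-level counts within a stratum are a sufficient
# statistic, so the resample reduces to one multinomial draw per stratum and
# each refit to the closed-form saturated estimator.

#' Bootstrap settings
#'
#' @param replicates number of bootstrap resamples (default 300).
#' @param level confidence level for the percentile interval.
#' @param seed integer seed; every call with the same seed and data gives
#'   the identical interval.
#' @param zero_cell_policy what to do with a resample that empties a cell
#'   (or makes S undefined): `"correct"` applies the 0.5 continuity
#'   correction inside that resample only; `"drop"` discards it (the
#'   percentile denominator is the number of valid resamples; dropped ones
#'   are not replaced).
#' @return A list of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(replicates = 300L, level = 0.95, seed = 1L,
                           zero_cell_policy = c("correct", "drop")) {
  stopifnot(replicates >= 2L, level > 0, level < 1)
  structure(list(replicates = as.integer(replicates), level = level,
                 seed = as.integer(seed),
                 zero_cell_policy = match.arg(zero_cell_policy)),
            class = "bootstrap_spec")
}

#' One outcome-stratified resample
#'
#' Draws subjects with replacement within cases and within controls
#' independently, preserving both stratum sizes exactly.
#'
#' @param data an [exposure_data()].
#' @param seed integer seed for reproducibility.
#' @return An `exposure_data` of the same size and stratum composition.
#' @export
stratified_resample <- function(data, seed = NULL) {
  stopifnot(inherits(data, "exposure_data"))
  ix1 <- which(data$outcome == 1L); ix0 <- which(data$outcome == 0L)
  if (!length(ix1) || !length(ix0))
    stop("both outcome strata must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  take <- c(ix1[sample.int(length(ix1), replace = TRUE)],
            ix0[sample.int(length(ix0), replace = TRUE)])
  exposure_data(outcome = data$outcome[take],
                level = data$level[take],
                confounders = if (is.null(data$confounders)) NULL
                              else data$confounders[take, , drop = FALSE])
}

# B multinomial resamples of a count table's strata: returns list of
# cases (4 x B) and controls (4 x B) count matrices.
.resample_counts <- function(tab, B) {
  n1 <- sum(tab["cases", ]); n0 <- sum(tab["controls", ])
  list(cases = rmultinom(B, n1, tab["cases", ] / n1),
       controls = rmultinom(B, n0, tab["controls", ] / n0))
}

#' Percentile bootstrap confidence interval for an interaction measure
#'
#' Refits the saturated model on each outcome-stratified resample and takes
#' the percentile interval of the measure. Without confounders the refit
#' uses the closed-form saturated estimator on multinomially resampled cell
#' counts, which is distributionally identical to row resampling and much
#' faster; with confounders each resample is refit by maximum likelihood.
#'
#' @param data an [exposure_data()] or [count_table()].
#' @param measure one of `"RERI"`, `"AP"`, `"S"`.
#' @param spec a [bootstrap_spec()].
#' @return A `measure_estimate` with `method = "bootstrap"`; its
#'   `diagnostics` record the resamples run, the degenerate count and the
#'   policy applied.
#' @examples
#' bootstrap_ci(oral_cancer_counts(), "RERI", bootstrap_spec(seed = 42))
#' @export
bootstrap_ci <- function(data, measure = c("RERI", "AP", "S"),
                         spec = bootstrap_spec()) {
  measure <- match.arg(measure)
  stopifnot(inherits(spec, "bootstrap_spec"))
  fn <- switch(measure, RERI = reri, AP = ap, S = synergy_index)
  stats <- .bootstrap_measures(data, spec)
  vals <- stats$draws[[measure]]
  point <- fn(stats$point_theta)
  valid <- vals[is.finite(vals)]
  n_bad <- spec$replicates - length(valid)
  if (length(valid) < spec$replicates / 2)
    stop("more than half of the bootstrap resamples were degenerate (",
         n_bad, " of ", spec$replicates, ")", call. = FALSE)
  alpha <- 1 - spec$level
  qq <- unname(stats::quantile(valid, c(alpha / 2, 1 - alpha / 2),
                               type = 7, names = FALSE))
  new_measure_estimate(measure, point, qq[1], qq[2], spec$level,
                       "bootstrap",
                       diagnostics = list(replicates = spec$replicates,
                                          valid = length(valid),
                                          degenerate = n_bad,
                                          policy = spec$zero_cell_policy))
}

# Shared resampling engine: one stream of resamples, all three measures
# computed on each, so RERI/AP/S intervals from one call are coherent.
.bootstrap_measures <- function(data, spec) {
  if (inherits(data, "exposure_data") && is.null(data$confounders))
    data <- as_count_table(data)
  set.seed(spec$seed)
  if (inherits(data, "count_table")) {
    tab <- data
    if (any(tab == 0)) {
      if (spec$zero_cell_policy == "correct") tab <- continuity_correct(tab)
      else stop("original table has an empty cell; use",
                " continuity_correct() first", call. = FALSE)
    }
    point_theta <- saturated_from_counts(tab)$theta
    rs <- .resample_counts(tab, spec$replicates)
    draws <- .theta_draws_from_counts(rs$cases, rs$controls,
                                      spec$zero_cell_policy)
  } else {
    stopifnot(inherits(data, "exposure_data"))
    point_theta <- fit_unconstrained(data)$theta
    ix1 <- which(data$outcome == 1L); ix0 <- which(data$outcome == 0L)
    if (!length(ix1) || !length(ix0))
      stop("both outcome strata must be non-empty", call. = FALSE)
    th <- matrix(NA_real_, spec$replicates, 3)
    for (b in seq_len(spec$replicates)) {
      take <- c(ix1[sample.int(length(ix1), replace = TRUE)],
                ix0[sample.int(length(ix0), replace = TRUE)])
      d <- exposure_data(outcome = data$outcome[take],
                         level = data$level[take],
                         confounders = data$confounders[take, , drop = FALSE])
      f <- tryCatch(fit_unconstrained(d), error = function(e) NULL)
      if (!is.null(f)) th[b, ] <- f$theta
    }
    draws <- list(RERI = apply(th, 1, function(x) reri(x)),
                  AP = apply(th, 1, function(x) ap(x)),
                  S = apply(th, 1, function(x) as.numeric(synergy_index(x))))
  }
  list(point_theta = point_theta, draws = draws)
}

# vectorized saturated-theta computation over resampled count columns
.theta_draws_from_counts <- function(cases, controls, policy) {
  zero <- colSums(cases == 0 | controls == 0) > 0
  if (any(zero)) {
    if (policy == "correct") {
      cases[, zero] <- cases[, zero] + 0.5
      controls[, zero] <- controls[, zero] + 0.5
    } else {
      cases[, zero] <- NA_real_
      controls[, zero] <- NA_real_
    }
  }
  lo <- log(cases) - log(controls)
  e1 <- exp(lo[2, ] - lo[1, ]); e2 <- exp(lo[3, ] - lo[1, ])
  e3 <- exp(lo[4, ] - lo[1, ])
  den <- e1 + e2 - 2
  s <- ifelse(den > 1e-12, (e3 - 1) / den, NA_real_)
  list(RERI = e3 - e1 - e2 + 1,
       AP = (e3 - e1 - e2 + 1) / e3,
       S = s)
}
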