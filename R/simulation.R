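# Simulation harness: data generation under the four-cell logistic model
# and the head-to-head comparison of model selection (AIC/HQ/BIC), the
# delta method and the stratified bootstrap across interaction scenarios.

#' Simulation scenario defined by three odds ratios
#'
#' A scenario fixes the odds ratios of the A-only, B-only and jointly
#' exposed cells against the unexposed cell (plus a baseline log-odds), and
#' so the implied coefficients and the implied RERI, AP and S. The seven
#' standard scenarios span strong synergy (`or11 = 20`) through exact
#' additivity (`or11 = 8` with `or10 = 4`, `or01 = 5`) to strong antagonism
#' (`or11 = 2`).
#'
#' @param name scenario label.
#' @param or10,or01,or11 positive odds ratios for the three exposed cells.
#' @param theta0 baseline log-odds of the outcome in the unexposed cell
#'   (default 0, i.e. baseline risk 1/2).
#' @return A list of class `scenario_spec` with the odds ratios, `theta`
#'   (the implied coefficients `(theta0, log or10, log or01, log or11)`)
#'   and implied `reri`, `ap`, `s`.
#' @examples
#' scenario_spec("S1", 4, 5, 20)
#' standard_scenarios()
#' @export
scenario_spec <- function(name, or10, or01, or11, theta0 = 0) {
  stopifnot(or10 > 0, or01 > 0, or11 > 0)
  th <- c(log(or10), log(or01), log(or11))
  structure(list(name = name, or10 = or10, or01 = or01, or11 = or11,
                 theta0 = theta0,
                 theta = c(theta0, th),
                 reri = reri(th), ap = ap(th),
                 s = as.numeric(synergy_index(th))),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param names which of the seven standard scenarios to return.
#' @export
standard_scenarios <- function(names = paste0("S", 1:7)) {
  or11 <- c(S1 = 20, S2 = 16, S3 = 12, S4 = 8, S5 = 6, S6 = 4, S7 = 2)
  stopifnot(all(names %in% names(or11)))
  out <- lapply(names, function(nm) scenario_spec(nm, 4, 5, or11[[nm]]))
  names(out) <- names
  out
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario %s: OR10 = %g, OR01 = %g, OR11 = %g (theta0 = %g)\n",
    x$name, x$or10, x$or01, x$or11, x$theta0))
  cat(sprintf("  implied RERI = %g, AP = %.3g, S = %.3g\n",
              x$reri, x$ap, x$s))
  invisible(x)
}

#' Generate a dataset under a scenario
#'
#' Assigns each subject to one of the four exposure cells (by default with
#' equal probability 1/4 each, multinomially) and draws the binary outcome
#' from the cell's logistic probability.
#'
#' @param spec a [scenario_spec()].
#' @param n number of subjects (at least 4).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param allocation cell probabilities for (neither, A only, B only,
#'   both); must sum to 1.
#' @return An [exposure_data()] with no confounders.
#' @examples
#' d <- generate_dataset(scenario_spec("S4", 4, 5, 8), n = 400, seed = 7)
#' as_count_table(d)
#' @export
generate_dataset <- function(spec, n, seed = NULL,
                             allocation = rep(1 / 4, 4)) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 4)
  if (abs(sum(allocation) - 1) > 1e-8 || any(allocation < 0))
    stop("`allocation` must be nonnegative probabilities summing to 1",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cell <- sample.int(4L, n, replace = TRUE, prob = allocation)
  eta <- spec$theta0 + c(0, spec$theta[2:4])[cell]
  y <- rbinom(n, 1L, plogis(eta))
  exposure_data(outcome = y, level = .levels[cell])
}

.all_methods <- c("AIC", "HQ", "BIC", "RERI_D", "AP_D", "S_D",
                  "RERI_B", "AP_B", "S_B")

#' Monte-Carlo comparison of interaction-detection methods
#'
#' For each replicate, generates a dataset under `spec`, applies the
#' requested methods and records whether each declares no additive
#' interaction; returns the fraction of no-interaction verdicts per method.
#' Under the additive-null scenario this fraction is one minus the type-I
#' error rate; under interaction scenarios it is one minus the power.
#'
#' Methods: `AIC`/`HQ`/`BIC` compare the constrained and unconstrained fits
#' by [gaic()]; `RERI_D`/`AP_D`/`S_D` are 95% delta-method intervals;
#' `RERI_B`/`AP_B`/`S_B` are 95% percentile intervals from the
#' outcome-stratified bootstrap (300 resamples each, sharing one resample
#' stream per replicate). Replicates where a measure is undefined (e.g. S
#' with nonpositive denominator) are excluded from that method's
#' denominator and counted.
#'
#' @param spec a [scenario_spec()].
#' @param n subjects per replicate.
#' @param replicates number of Monte-Carlo replicates (default 1000).
#' @param methods subset of the nine method labels.
#' @param seed master seed; per-replicate seeds are spawned from it so
#'   results do not depend on evaluation order.
#' @param level confidence level for the interval methods.
#' @param boot_replicates bootstrap resamples per replicate (default 300).
#' @param allocation passed to [generate_dataset()].
#' @return A list of class `experiment_result`: `fractions` (named
#'   no-interaction fractions), `counts`, `undefined` (exclusions per
#'   method), plus the design fields.
#' @examples
#' run_experiment(scenario_spec("S7", 4, 5, 2), n = 400, replicates = 20,
#'                methods = c("AIC", "RERI_D"), seed = 1)
#' @export
run_experiment <- function(spec, n, replicates = 1000L,
                           methods = .all_methods, seed = 1L,
                           level = 0.95, boot_replicates = 300L,
                           allocation = rep(1 / 4, 4)) {
  stopifnot(inherits(spec, "scenario_spec"), replicates >= 1)
  methods <- match.arg(methods, .all_methods, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  hits <- setNames(numeric(length(methods)), methods)
  valid <- setNames(numeric(length(methods)), methods)
  want_crit <- intersect(methods, c("AIC", "HQ", "BIC"))
  want_delta <- intersect(methods, c("RERI_D", "AP_D", "S_D"))
  want_boot <- intersect(methods, c("RERI_B", "AP_B", "S_B"))
  kappa <- c(AIC = 2, HQ = 2 * log(log(n)), BIC = log(n))

  for (r in seq_len(replicates)) {
    d <- generate_dataset(spec, n, seed = rep_seeds[r],
                          allocation = allocation)
    tab <- as_count_table(d)
    if (any(tab == 0)) tab <- continuity_correct(tab)
    fit <- saturated_from_counts(tab)

    if (length(want_crit)) {
      m2 <- tryCatch(fit_constrained(tab), error = function(e) NULL)
      if (!is.null(m2) && m2$converged) {
        lam <- gdev(m2) - gdev(fit)
        for (m in want_crit) {
          valid[m] <- valid[m] + 1
          if (lam <= kappa[[m]]) hits[m] <- hits[m] + 1
        }
      }
    }
    if (length(want_delta)) {
      for (m in want_delta) {
        meas <- sub("_D$", "", m)
        est <- delta_ci(fit, meas, level = level)
        if (est$verdict != "undefined") {
          valid[m] <- valid[m] + 1
          if (est$verdict == "no_interaction") hits[m] <- hits[m] + 1
        }
      }
    }
    if (length(want_boot)) {
      bspec <- bootstrap_spec(replicates = boot_replicates, level = level,
                              seed = rep_seeds[r])
      stream <- .bootstrap_measures(tab, bspec)
      alpha <- 1 - level
      for (m in want_boot) {
        meas <- sub("_B$", "", m)
        vals <- stream$draws[[meas]]
        ok <- vals[is.finite(vals)]
        if (length(ok) >= boot_replicates / 2) {
          qq <- stats::quantile(ok, c(alpha / 2, 1 - alpha / 2),
                                type = 7, names = FALSE)
          valid[m] <- valid[m] + 1
          nv <- .null_value[[meas]]
          if (qq[1] <= nv && nv <= qq[2]) hits[m] <- hits[m] + 1
        }
      }
    }
  }
  structure(list(scenario = spec$name, n = n, replicates = replicates,
                 seed = seed,
                 fractions = ifelse(valid > 0, hits / valid, NA_real_),
                 counts = hits, valid = valid,
                 undefined = replicates - valid,
                 level = level, boot_replicates = boot_replicates),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "Scenario %s, n = %d, %d replicates: fraction of no-interaction verdicts\n",
    x$scenario, x$n, x$replicates))
  print(round(x$fractions, 3))
  if (any(x$undefined > 0)) {
    ex <- x$undefined[x$undefined > 0]
    cat("  excluded (undefined/failed):",
        paste(names(ex), ex, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
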