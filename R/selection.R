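# Model selection between the unconstrained model M1 and the additive-null
# constrained model M2. The models are nested with one constraint, so
# df(M1) - df(M2) = 1 and any GAIC(kappa) criterion prefers M1 exactly when
# the deviance gap Lambda = GDEV2 - GDEV1 exceeds kappa.

#' Generalized Akaike information criterion
#'
#' \eqn{GAIC(\kappa) = GDEV + \kappa\,df}. Special cases: AIC
#' (\eqn{\kappa = 2}), BIC (\eqn{\kappa = \ln n}) and Hannan-Quinn
#' (\eqn{\kappa = 2\ln\ln n}); for \eqn{n \ge 16} the HQ penalty lies
#' strictly between the AIC and BIC penalties.
#'
#' @param model an `addint_fit`.
#' @param kappa positive per-parameter penalty.
#' @return A single number.
#' @examples
#' fit <- fit_unconstrained(oral_cancer_counts())
#' gaic(fit, 2)                 # AIC
#' gaic(fit, log(fit$n))        # BIC
#' gaic(fit, 2 * log(log(fit$n)))  # HQ
#' @export
gaic <- function(model, kappa) {
  stopifnot(inherits(model, "addint_fit"))
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("`kappa` must be a single positive number", call. = FALSE)
  -2 * model$loglik + kappa * model$df
}

#' Likelihood-ratio test of the additive null
#'
#' Tests the constrained model (zero interaction contrast) against the
#' unconstrained model. The statistic \eqn{\Lambda = GDEV_2 - GDEV_1} is
#' referred to a chi-squared distribution with `df1 - df2` degrees of
#' freedom (one, for the single constraint); numerical noise can make
#' \eqn{\Lambda} slightly negative, so it is floored at zero.
#'
#' @param m1 the unconstrained `addint_fit`.
#' @param m2 the constrained `addint_fit`, nested in `m1`.
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
likelihood_ratio_test <- function(m1, m2) {
  stopifnot(inherits(m1, "addint_fit"), inherits(m2, "addint_fit"))
  d <- m1$df - m2$df
  if (d < 1L)
    stop("models are not nested: df of `m1` must exceed df of `m2`",
         call. = FALSE)
  lambda <- max(gdev(m2) - gdev(m1), 0)
  list(statistic = lambda, df = d,
       p.value = pchisq(lambda, df = d, lower.tail = FALSE))
}

#' Compare the unconstrained and constrained models
#'
#' Fits both models and compares them by AIC, BIC and Hannan-Quinn (HQ),
#' plus the likelihood-ratio test. A criterion declares additive
#' interaction exactly when it prefers the unconstrained model, i.e. when
#' the deviance gap exceeds its penalty \eqn{\kappa}; at exactly equal GAIC
#' the simpler constrained model is preferred.
#'
#' @param data an [exposure_data()] or [count_table()].
#' @param criteria named numeric vector of \eqn{\kappa} values; defaults to
#'   AIC, HQ and BIC for the fitted sample size (number of subjects).
#' @return A list of class `selection_report`: the two fits, their
#'   deviances, `delta_gdev`, a per-criterion data frame (`kappa`, both
#'   GAIC values, preferred model, verdict) and the LRT.
#' @examples
#' select_interaction(oral_cancer_counts())
#' @export
select_interaction <- function(data, criteria = NULL) {
  m1 <- fit_unconstrained(data)
  m2 <- tryCatch(fit_constrained(data), error = function(e) e)
  if (inherits(m2, "error") || !m2$converged) {
    msg <- if (inherits(m2, "error")) conditionMessage(m2) else m2$message
    return(structure(list(unconstrained = m1, constrained = NULL,
                          gdev_unconstrained = gdev(m1),
                          gdev_constrained = NA_real_,
                          delta_gdev = NA_real_, criteria = NULL,
                          lrt = NULL, verdict = "undefined",
                          message = msg),
                     class = "selection_report"))
  }
  n <- m1$n
  if (is.null(criteria))
    criteria <- c(AIC = 2, HQ = 2 * log(log(n)), BIC = log(n))
  g1 <- gdev(m1); g2 <- gdev(m2)
  lambda <- g2 - g1
  tab <- data.frame(
    criterion = names(criteria),
    kappa = unname(criteria),
    gaic_unconstrained = vapply(criteria, function(k) gaic(m1, k), 0),
    gaic_constrained = vapply(criteria, function(k) gaic(m2, k), 0),
    stringsAsFactors = FALSE)
  # ties (equal GAIC) go to the simpler constrained model
  tab$preferred <- ifelse(tab$gaic_unconstrained < tab$gaic_constrained,
                          "unconstrained", "constrained")
  tab$verdict <- ifelse(tab$preferred == "unconstrained",
                        "interaction", "no_interaction")
  structure(list(unconstrained = m1, constrained = m2,
                 gdev_unconstrained = g1, gdev_constrained = g2,
                 delta_gdev = max(lambda, 0), criteria = tab,
                 lrt = likelihood_ratio_test(m1, m2)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Additive-interaction model selection\n")
  if (is.null(x$constrained)) {
    cat("  constrained fit unavailable:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  GDEV: unconstrained %.3f, constrained %.3f (gap %.3f)\n",
              x$gdev_unconstrained, x$gdev_constrained, x$delta_gdev))
  print(x$criteria, digits = 4, row.names = FALSE)
  cat(sprintf("  LRT: Lambda = %.3f on %d df, p = %.3f\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p.value))
  invisible(x)
}
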