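# Penalized estimation: minimize -l(theta) + lambda * |IC(theta)| with
# IC(theta) = e^theta3 - e^theta1 - e^theta2 + 1. The L1-type penalty on the
# interaction contrast shrinks it exactly to zero for large lambda, at which
# point the fit coincides with the constrained model. The absolute value is
# smoothed as s(x) = sqrt(x^2 + eps^2) for gradient-based optimization, and
# any solution with |IC| below `zero_tolerance` is snapped to the exact
# constrained fit so verdicts do not depend on eps.

#' Penalty and tuning settings for the regularization path
#'
#' @param lambda_grid strictly increasing positive penalty weights; the
#'   default is 41 log-spaced points in `[1e-3, 1e3]`, wide enough to
#'   bracket the unconstrained regime at one end and the fully constrained
#'   regime at the other.
#' @param smoothing_eps smoothing width for the absolute-value penalty.
#' @param zero_tolerance |IC| below which the fit is declared on the
#'   constraint and snapped to the exact constrained solution.
#' @param split_fraction share of subjects in the training split when
#'   tuning by generalization error.
#' @param seed integer seed controlling the train/test split.
#' @return A list of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda_grid = 10^seq(-3, 3, length.out = 41),
                         smoothing_eps = 1e-8, zero_tolerance = 1e-4,
                         split_fraction = 2 / 3, seed = 1L) {
  stopifnot(all(lambda_grid >= 0), !is.unsorted(lambda_grid, strictly = TRUE),
            smoothing_eps > 0, zero_tolerance > 0,
            split_fraction > 0, split_fraction < 1)
  structure(list(lambda_grid = lambda_grid, smoothing_eps = smoothing_eps,
                 zero_tolerance = zero_tolerance,
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "penalty_spec")
}

#' Penalized fit at a single penalty weight
#'
#' Minimizes \eqn{-l(\theta) + \lambda\,s(\mathrm{IC}(\theta))} where
#' \eqn{s(x)=\sqrt{x^2+\epsilon^2}} smooths the absolute value. At
#' \eqn{\lambda = 0} this reproduces [fit_unconstrained()]; for large
#' \eqn{\lambda} the interaction contrast is driven to zero and the result
#' is snapped to [fit_constrained()] and flagged `constrained`.
#'
#' @param data an [exposure_data()] or [count_table()].
#' @param lambda nonnegative penalty weight.
#' @param spec a [penalty_spec()] (for `smoothing_eps`/`zero_tolerance`).
#' @param start optional starting coefficient vector
#'   `(theta0, theta1, theta2, theta3, gamma)` for warm starts.
#' @return An `addint_fit`; `$penalty` records lambda and the achieved
#'   `|IC|`, and `$loglik` is the unpenalized log-likelihood at the optimum.
#' @examples
#' penalized_fit(oral_cancer_counts(), lambda = 0.5)
#' @export
penalized_fit <- function(data, lambda, spec = penalty_spec(),
                          start = NULL) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  is_counts <- inherits(data, "count_table")
  if (!is_counts) stopifnot(inherits(data, "exposure_data"))
  p <- if (is_counts || is.null(data$confounders)) 0L
       else ncol(data$confounders)
  use_cells <- p == 0L
  cl <- if (is_counts) list(cases = as.numeric(data["cases", ]),
                            totals = as.numeric(colSums(data)))
        else if (use_cells) .cells(data)
  X <- if (!use_cells) .design(data)
  y <- if (!is_counts) data$outcome
  eps <- spec$smoothing_eps

  negll <- function(th) {
    if (use_cells) -.loglik_cells(cl$cases, cl$totals, th[1] + c(0, th[2:4]))
    else -.loglik_rows(y, drop(X %*% th))
  }
  obj <- function(th) {
    ic <- exp(th[4]) - exp(th[2]) - exp(th[3]) + 1
    negll(th) + lambda * sqrt(ic^2 + eps^2)
  }

  mle <- fit_unconstrained(data)
  if (lambda == 0) return(mle)
  if (is.null(start)) start <- c(mle$theta0, mle$theta, mle$gamma)
  opt <- optim(start, obj, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-12))
  # the smoothed |.| is nearly nonsmooth at IC = 0, where BFGS can stall a
  # hair off the kink; restart from the exactly-constrained solution and
  # keep the better of the two minima
  confit <- fit_constrained(data)
  opt2 <- optim(c(confit$theta0, confit$theta, confit$gamma), obj,
                method = "BFGS", control = list(maxit = 200, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2
  th <- opt$par
  ic <- exp(th[4]) - exp(th[2]) - exp(th[3]) + 1
  if (abs(ic) < spec$zero_tolerance) {
    out <- confit
    out$penalty <- list(lambda = lambda, abs_ic = 0, snapped = TRUE)
    return(out)
  }
  nm <- c(.param_names, if (p > 0) colnames(data$confounders))
  out <- new_addint_fit(theta0 = th[1], theta = th[2:4],
                        gamma = if (p > 0) setNames(th[-(1:4)],
                                                    colnames(data$confounders))
                                else numeric(0),
                        vcov = matrix(NA_real_, 4 + p, 4 + p,
                                      dimnames = list(nm, nm)),
                        loglik = -negll(th), df = 4L + p,
                        constrained = FALSE,
                        converged = opt$convergence == 0L,
                        n = as.integer(round(if (is_counts) sum(data)
                                             else data$n)))
  out$penalty <- list(lambda = lambda, abs_ic = abs(ic), snapped = FALSE)
  out
}

#' Regularization path over a grid of penalty weights
#'
#' Solves the penalized problem along an increasing lambda grid with warm
#' starts, recording for each grid point the coefficients, the achieved
#' penalty term |IC| and the training deviance (plus a held-out deviance
#' when `test_data` is given). The path interpolates between the
#' unconstrained fit (small lambda) and the constrained fit (large lambda).
#'
#' @inheritParams penalized_fit
#' @param test_data optional held-out [exposure_data()] scored at each
#'   path solution (the generalization error used for tuning).
#' @return A list of class `lambda_path`: `path` (a data frame with one row
#'   per lambda: lambda, theta1..theta3, abs_ic, constrained, train_gdev,
#'   test_gdev), and the endpoint fits `fit_unconstrained`,
#'   `fit_constrained`.
#' @export
lambda_path <- function(data, spec = penalty_spec(), test_data = NULL) {
  stopifnot(length(spec$lambda_grid) >= 1)
  fits <- vector("list", length(spec$lambda_grid))
  start <- NULL
  for (i in seq_along(spec$lambda_grid)) {
    f <- penalized_fit(data, spec$lambda_grid[i], spec, start = start)
    fits[[i]] <- f
    if (!isTRUE(f$constrained))
      start <- c(f$theta0, f$theta, f$gamma)
  }
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(lambda = spec$lambda_grid[i],
               theta1 = unname(f$theta[1]), theta2 = unname(f$theta[2]),
               theta3 = unname(f$theta[3]),
               abs_ic = abs(interaction_contrast(f$theta)),
               constrained = isTRUE(f$constrained),
               train_gdev = gdev(f, data),
               test_gdev = if (is.null(test_data)) NA_real_
                           else gdev(f, test_data),
               converged = f$converged)
  })
  structure(list(path = do.call(rbind, rows), fits = fits,
                 unconstrained = fit_unconstrained(data),
                 constrained = fit_constrained(data)),
            class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat("Regularization path over", nrow(x$path), "penalty weights\n")
  print(x$path[, setdiff(names(x$path), "converged")], digits = 4,
        row.names = FALSE)
  invisible(x)
}

#' Tune the penalty weight by generalization error
#'
#' Splits the data once into a training and a testing part, fits the
#' regularization path on the training part, and picks the lambda whose
#' path solution has the smallest deviance on the testing part
#' (generalization error), breaking ties toward the larger lambda. The
#' verdict is `no_interaction` exactly when the chosen solution lies on the
#' constraint (its interaction contrast is zero).
#'
#' @inheritParams penalized_fit
#' @return A list of class `lambda_tuning`: `chosen_lambda`, `verdict`,
#'   `fit` (the chosen path fit, refit on the full data), `path` (the
#'   training-set [lambda_path()]), and the split indices.
#' @export
tune_lambda <- function(data, spec = penalty_spec()) {
  if (inherits(data, "count_table")) data <- as_exposure_data(data)
  stopifnot(inherits(data, "exposure_data"))
  set.seed(spec$seed)
  n <- data$n
  n_train <- round(spec$split_fraction * n)
  if (n_train < 8 || n - n_train < 8)
    stop("too few subjects to split for tuning", call. = FALSE)
  split_ok <- function(ix) {
    all(.levels %in% data$level[ix]) && all(.levels %in% data$level[-ix])
  }
  ix <- NULL
  for (try in 1:10) {
    cand <- sample.int(n, n_train)
    if (split_ok(cand)) { ix <- cand; break }
  }
  if (is.null(ix))
    stop("could not find a train/test split containing all four exposure ",
         "levels in both parts (10 attempts)", call. = FALSE)
  subset_data <- function(keep) {
    exposure_data(outcome = data$outcome[keep], level = data$level[keep],
                  confounders = if (is.null(data$confounders)) NULL
                                else data$confounders[keep, , drop = FALSE])
  }
  train <- subset_data(ix); test <- subset_data(setdiff(seq_len(n), ix))
  path <- lambda_path(train, spec, test_data = test)
  gd <- path$path$test_gdev
  # ties toward the larger lambda: last index attaining the minimum
  best <- max(which(gd <= min(gd) + 1e-9))
  chosen <- spec$lambda_grid[best]
  on_constraint <- path$path$constrained[best]
  full_fit <- penalized_fit(data, chosen, spec)
  structure(list(chosen_lambda = chosen,
                 verdict = if (on_constraint) "no_interaction"
                           else "interaction",
                 fit = full_fit, path = path,
                 train_index = sort(ix),
                 test_gdev = gd[best]),
            class = "lambda_tuning")
}

#' @export
print.lambda_tuning <- function(x, ...) {
  cat("Penalty tuning by generalization error\n")
  cat(sprintf("  chosen lambda = %.4g (held-out GDEV = %.3f)\n",
              x$chosen_lambda, x$test_gdev))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
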