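# Maximum-likelihood fitting of the combined-level logistic model
#
#   logit P(y = 1) = theta0 + theta1 I(A1B0) + theta2 I(A0B1)
#                  + theta3 I(A1B1) + z' gamma
#
# both unconstrained and under the additive-null constraint
# IC(theta) = e^theta3 - e^theta1 - e^theta2 + 1 = 0.

.param_names <- c("theta0", "theta1", "theta2", "theta3")

new_addint_fit <- function(theta0, theta, gamma, vcov, loglik, df,
                           constrained, converged, n, message = NULL) {
  names(theta) <- .param_names[2:4]
  structure(
    list(theta0 = theta0, theta = theta, gamma = gamma, vcov = vcov,
         loglik = loglik, df = df, constrained = constrained,
         converged = converged, n = n, message = message),
    class = "addint_fit")
}

#' @export
print.addint_fit <- function(x, ...) {
  cat(if (x$constrained) "Constrained" else "Unconstrained",
      "logistic fit (combined exposure levels)\n")
  cat(sprintf("  theta0 = %.3f, theta = (%.3f, %.3f, %.3f)\n",
              x$theta0, x$theta[1], x$theta[2], x$theta[3]))
  if (length(x$gamma))
    cat("  gamma  =", paste(sprintf("%.3f", x$gamma), collapse = ", "), "\n")
  cat(sprintf("  log-likelihood = %.3f  (GDEV = %.3f), df = %d, n = %d\n",
              x$loglik, -2 * x$loglik, x$df, x$n))
  cat(sprintf("  IC = %.4g%s\n", interaction_contrast(x$theta),
              if (x$constrained) " (constrained to 0)" else ""))
  if (!x$converged) cat("  WARNING: did not converge:", x$message, "\n")
  invisible(x)
}

# numerically safe log(1 + e^x)
.log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(pmin(x, 33))))

# Bernoulli log-likelihood sum(y*eta - log(1 + e^eta)), aggregated over the
# four cells when there are no confounders.
.loglik_cells <- function(cases, totals, eta) {
  sum(cases * eta - totals * .log1pexp(eta))
}

.loglik_rows <- function(y, eta) {
  sum(y * eta - .log1pexp(eta))
}

.design <- function(data) {
  X <- cbind(`(Intercept)` = 1,
             theta1 = as.numeric(data$level == "A1B0"),
             theta2 = as.numeric(data$level == "A0B1"),
             theta3 = as.numeric(data$level == "A1B1"))
  if (!is.null(data$confounders)) X <- cbind(X, data$confounders)
  X
}

#' Unconstrained maximum-likelihood fit
#'
#' Fits the four-level logistic model by maximum likelihood, with the
#' unexposed cell A0B0 as reference. With no confounders this is the
#' saturated model and the estimates are the observed cell log odds ratios.
#'
#' @param data an [exposure_data()] or [count_table()].
#' @return An object of class `addint_fit` with components `theta0`, `theta`
#'   (the three log odds ratios), `gamma`, `vcov` (covariance of all
#'   coefficients, inverse observed information), `loglik`, `df`,
#'   `constrained = FALSE`, `converged` and `n`.
#' @examples
#' fit_unconstrained(oral_cancer_counts())
#' @export
fit_unconstrained <- function(data) {
  if (inherits(data, "count_table")) {
    # the confounder-free MLE is the saturated closed form; this also
    # covers continuity-corrected (fractional) tables
    empty <- which(colSums(data) == 0)
    if (length(empty))
      stop("empty exposure cell(s): ",
           paste(.level_labels[empty], collapse = ", "),
           "; the model is not identified", call. = FALSE)
    zero <- which(colSums(data == 0) > 0)
    if (length(zero))
      stop("separation: cell(s) ",
           paste(.level_labels[zero], collapse = ", "),
           " contain only cases or only controls; consider",
           " continuity_correct()", call. = FALSE)
    return(saturated_from_counts(data))
  }
  stopifnot(inherits(data, "exposure_data"))
  if (length(unique(data$outcome)) < 2L)
    stop("degenerate data: all subjects share the same outcome",
         call. = FALSE)
  if (is.null(data$confounders)) {
    cl <- .cells(data)
    empty <- which(cl$totals == 0)
    if (length(empty))
      stop("empty exposure cell(s): ",
           paste(.level_labels[empty], collapse = ", "),
           "; the model is not identified", call. = FALSE)
    sep <- which(cl$cases == 0 | cl$cases == cl$totals)
    if (length(sep))
      stop("separation: cell(s) ", paste(.level_labels[sep], collapse = ", "),
           " contain only cases or only controls; consider",
           " continuity_correct()", call. = FALSE)
  }
  fit <- stats::glm.fit(x = .design(data), y = data$outcome,
                        family = stats::binomial())
  beta <- fit$coefficients
  eta <- drop(.design(data) %*% beta)
  ll <- .loglik_rows(data$outcome, eta)
  # inverse observed information (equals expected information for logistic)
  w <- fit$weights
  info <- crossprod(.design(data) * sqrt(w))
  vc <- solve(info)
  p <- length(beta) - 4L
  dimnames(vc) <- list(names(beta), names(beta))
  new_addint_fit(theta0 = unname(beta[1]), theta = unname(beta[2:4]),
                 gamma = if (p > 0) beta[-(1:4)] else numeric(0),
                 vcov = vc, loglik = ll, df = 4L + p,
                 constrained = FALSE, converged = fit$converged,
                 n = data$n,
                 message = if (!fit$converged) "IRLS did not converge")
}

#' Closed-form saturated fit from cell counts
#'
#' For a confounder-free 2 x 4 table the saturated MLE has a closed form:
#' each coefficient is a log cross-product ratio against the reference cell
#' and the covariance is a sum of reciprocal cell counts. Agrees with
#' [fit_unconstrained()] to optimizer tolerance and is the fast path used
#' inside the bootstrap.
#'
#' @param table a [count_table()] with all eight cells positive.
#' @return An `addint_fit`, as for [fit_unconstrained()].
#' @examples
#' saturated_from_counts(oral_cancer_counts())
#' @export
saturated_from_counts <- function(table) {
  stopifnot(inherits(table, "count_table"))
  zero <- which(table == 0, arr.ind = TRUE)
  if (nrow(zero))
    stop("zero cell(s): ",
         paste(rownames(table)[zero[, 1]], .level_labels[zero[, 2]],
               sep = "/", collapse = ", "),
         "; apply continuity_correct() if appropriate", call. = FALSE)
  a <- table["cases", ]; b <- table["controls", ]
  lo <- log(a / b)                      # cell log odds
  theta0 <- lo[[1]]
  theta <- unname(lo[2:4] - theta0)
  v <- 1 / a + 1 / b                    # per-cell log-odds variance
  vc <- matrix(v[[1]], 4, 4)            # shared reference-cell terms
  diag(vc) <- v[[1]] + c(0, v[2:4])
  vc[1, 2:4] <- vc[2:4, 1] <- -v[[1]]   # cov(theta0, thetaj) = -v_ref... see below
  # theta0 = lo_ref, thetaj = lo_j - lo_ref; Var(theta0) = v_ref,
  # Cov(theta0, thetaj) = -v_ref, Cov(thetai, thetaj) = v_ref (i != j),
  # Var(thetaj) = v_j + v_ref.
  vc[1, 1] <- v[[1]]
  dimnames(vc) <- list(.param_names, .param_names)
  p <- a / (a + b)
  ll <- sum(a * log(p) + b * log(1 - p))
  new_addint_fit(theta0 = theta0, theta = theta, gamma = numeric(0),
                 vcov = vc, loglik = ll, df = 4L, constrained = FALSE,
                 converged = TRUE, n = as.integer(sum(a + b)))
}

# Constrained parameterization: the manifold e^t3 = e^t1 + e^t2 - 1 is
# covered smoothly by (t3, phi) with
#   e^t1 = (e^t3 + 1) * plogis(phi),  e^t2 = (e^t3 + 1) * (1 - plogis(phi)),
# so the reduced parameter vector (theta0, t3, phi, gamma) is free in R^(3+p).
.constr_expand <- function(par, p) {
  t3 <- par[2]; s <- exp(t3) + 1
  q <- plogis(par[3])
  c(par[1], log(s * q), log(s * (1 - q)), t3,
    if (p > 0) par[-(1:3)] else NULL)
}

# Jacobian d(theta0,t1,t2,t3,gamma)/d(theta0,t3,phi,gamma) for the delta map
.constr_jacobian <- function(par, p) {
  t3 <- par[2]; s <- exp(t3) + 1
  q <- plogis(par[3]); dq <- q * (1 - q)
  J <- matrix(0, 4 + p, 3 + p)
  J[1, 1] <- 1
  J[2, 2] <- exp(t3) / s;  J[2, 3] <- dq / q
  J[3, 2] <- exp(t3) / s;  J[3, 3] <- -dq / (1 - q)
  J[4, 2] <- 1
  if (p > 0) J[4 + seq_len(p), 3 + seq_len(p)] <- diag(p)
  J
}

#' Maximum likelihood under the additive-null constraint
#'
#' Maximizes the logistic likelihood subject to
#' \eqn{e^{\theta_3} - e^{\theta_1} - e^{\theta_2} + 1 = 0}, i.e. a zero
#' interaction contrast. The constraint manifold is parameterized smoothly
#' (see Details) and the reduced problem solved by BFGS; the covariance of
#' the full coefficient vector is recovered by the delta method.
#'
#' @details Writing \eqn{e^{\theta_3} + 1 = e^{\theta_1} + e^{\theta_2}},
#' the manifold is covered by \eqn{(\theta_3, \phi)} with
#' \eqn{e^{\theta_1} = (e^{\theta_3}+1)\sigma(\phi)} and
#' \eqn{e^{\theta_2} = (e^{\theta_3}+1)(1-\sigma(\phi))}, \eqn{\sigma} the
#' logistic function, which removes the equality constraint exactly and
#' keeps the whole reduced parameter space unconstrained.
#'
#' @inheritParams fit_unconstrained
#' @param start optional starting values for the reduced parameters.
#' @return An `addint_fit` with `constrained = TRUE` and `df = 3 + p`; its
#'   `loglik` never exceeds the unconstrained fit's on the same data.
#' @examples
#' fit_constrained(oral_cancer_counts())
#' @export
fit_constrained <- function(data, start = NULL) {
  is_counts <- inherits(data, "count_table")
  if (!is_counts) stopifnot(inherits(data, "exposure_data"))
  if (!is_counts && length(unique(data$outcome)) < 2L)
    stop("degenerate data: all subjects share the same outcome",
         call. = FALSE)
  if (is_counts && (sum(data["cases", ]) == 0 || sum(data["controls", ]) == 0))
    stop("degenerate data: all subjects share the same outcome",
         call. = FALSE)
  p <- if (is_counts || is.null(data$confounders)) 0L
       else ncol(data$confounders)
  use_cells <- p == 0L
  cl <- if (is_counts) list(cases = as.numeric(data["cases", ]),
                            totals = as.numeric(colSums(data)))
        else if (use_cells) .cells(data)
  X <- if (!use_cells) .design(data)
  y <- if (!is_counts) data$outcome
  n_fit <- if (is_counts) sum(data) else data$n

  nll <- function(par) {
    th <- .constr_expand(par, p)
    if (use_cells) {
      eta <- th[1] + c(0, th[2:4])
      -.loglik_cells(cl$cases, cl$totals, eta)
    } else {
      -.loglik_rows(y, drop(X %*% th))
    }
  }

  if (is.null(start)) {
    # start from the unconstrained fit projected onto the manifold
    st <- tryCatch(fit_unconstrained(data), error = function(e) NULL)
    if (!is.null(st)) {
      e1 <- exp(st$theta[1]); e2 <- exp(st$theta[2])
      t3 <- log(max(e1 + e2 - 1, 0.05))
      phi <- stats::qlogis(e1 / (e1 + e2))
      start <- c(st$theta0, t3, phi, st$gamma)
    } else {
      start <- c(0, 0.5, 0, rep(0, p))
    }
  }

  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-12))
  converged <- opt$convergence == 0L
  # polish + Hessian at the optimum
  H <- optimHess(opt$par, nll)
  vc_red <- tryCatch(solve(H), error = function(e) NULL)
  th <- .constr_expand(opt$par, p)
  vc <- if (!is.null(vc_red)) {
    J <- .constr_jacobian(opt$par, p)
    J %*% vc_red %*% t(J)
  } else matrix(NA_real_, 4 + p, 4 + p)
  nm <- c(.param_names, if (p > 0) colnames(data$confounders))
  dimnames(vc) <- list(nm, nm)
  theta <- th[2:4]
  if (exp(theta[1]) + exp(theta[2]) <= 1 + 1e-10)
    converged <- FALSE
  new_addint_fit(theta0 = th[1], theta = theta,
                 gamma = if (p > 0) setNames(th[-(1:4)],
                                             colnames(data$confounders))
                         else numeric(0),
                 vcov = vc, loglik = -opt$value, df = 3L + p,
                 constrained = TRUE, converged = converged,
                 n = as.integer(round(n_fit)),
                 message = if (!converged)
                   "constrained optimizer at domain boundary or not converged")
}

#' Global deviance
#'
#' The global deviance GDEV of a fitted model is minus twice its maximized
#' Bernoulli log-likelihood. With `data` supplied, the deviance is
#' recomputed by scoring `data` at the model's coefficients, which is how
#' the generalization error on a held-out split is obtained.
#'
#' @param model an `addint_fit`.
#' @param data optional [exposure_data()] or [count_table()] to score at the
#'   fitted coefficients; defaults to the training deviance
#'   `-2 * model$loglik`.
#' @return A single number, \eqn{-2 l(\hat\theta)}.
#' @examples
#' gdev(fit_unconstrained(oral_cancer_counts()))
#' @export
gdev <- function(model, data = NULL) {
  stopifnot(inherits(model, "addint_fit"))
  if (is.null(data)) return(-2 * model$loglik)
  if (inherits(data, "count_table")) {
    if (length(model$gamma))
      stop("model has confounder coefficients but count data have none",
           call. = FALSE)
    eta <- model$theta0 + c(0, model$theta)
    return(-2 * .loglik_cells(as.numeric(data["cases", ]),
                              as.numeric(colSums(data)), eta))
  }
  p <- length(model$gamma)
  pd <- if (is.null(data$confounders)) 0L else ncol(data$confounders)
  if (p != pd)
    stop("model has ", p, " confounder coefficients but data has ", pd,
         " confounder columns", call. = FALSE)
  th <- c(model$theta0, model$theta, model$gamma)
  -2 * .loglik_rows(data$outcome, drop(.design(data) %*% th))
}

#' @export
deviance.addint_fit <- function(object, ...) gdev(object)

#' @export
logLik.addint_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
vcov.addint_fit <- function(object, ...) object$vcov
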