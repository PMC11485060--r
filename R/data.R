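#' @importFrom stats plogis qnorm rbinom rmultinom optim optimHess
#'   pchisq setNames
#' @importFrom utils read.csv write.csv
NULL

# Fixed ordering of the four combined exposure levels. A1B0 is "A only",
# A0B1 is "B only"; A0B0 is always the reference.
.levels <- c("A0B0", "A1B0", "A0B1", "A1B1")
.level_labels <- c("neither", "a_only", "b_only", "both")

#' Per-subject exposure data for a two-factor interaction analysis
#'
#' Bundles a binary outcome, the combined four-level exposure variable built
#' from two binary risk factors A and B, and an optional matrix of
#' confounders to be adjusted linearly on the logit scale.
#'
#' @param outcome integer/logical vector of 0/1 outcomes (1 = case).
#' @param a,b binary (0/1) vectors for the two risk factors. Alternatively
#'   supply `level` directly.
#' @param level factor or character vector with values in
#'   `c("A0B0","A1B0","A0B1","A1B1")`; overrides `a`/`b` when given.
#' @param confounders optional numeric matrix or data frame with one row per
#'   subject; its columns enter the linear predictor with unconstrained
#'   coefficients.
#' @return An object of class `exposure_data`: a list with elements
#'   `outcome`, `level` (factor with reference level `A0B0`), `confounders`
#'   (numeric matrix or `NULL`) and `n`.
#' @examples
#' d <- exposure_data(outcome = c(1, 0, 1, 0),
#'                    a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' table(d$level, d$outcome)
#' @export
exposure_data <- function(outcome, a = NULL, b = NULL, level = NULL,
                          confounders = NULL) {
  outcome <- as.integer(outcome)
  if (length(outcome) < 1L)
    stop("need at least one subject", call. = FALSE)
  if (!all(outcome %in% c(0L, 1L)))
    stop("`outcome` must be strictly binary (0/1)", call. = FALSE)
  if (is.null(level)) {
    if (is.null(a) || is.null(b))
      stop("supply either `level` or both `a` and `b`", call. = FALSE)
    a <- as.integer(a); b <- as.integer(b)
    if (!all(a %in% 0:1) || !all(b %in% 0:1))
      stop("`a` and `b` must be binary (0/1)", call. = FALSE)
    if (length(a) != length(outcome) || length(b) != length(outcome))
      stop("`a`, `b` and `outcome` must have equal length", call. = FALSE)
    level <- paste0("A", a, "B", b)
  }
  level <- as.character(level)
  bad <- setdiff(unique(level), .levels)
  if (length(bad))
    stop("unknown exposure level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(level) != length(outcome))
    stop("`level` and `outcome` must have equal length", call. = FALSE)
  if (!is.null(confounders)) {
    confounders <- as.matrix(confounders)
    storage.mode(confounders) <- "double"
    if (nrow(confounders) != length(outcome))
      stop("`confounders` must have one row per subject", call. = FALSE)
    if (is.null(colnames(confounders)))
      colnames(confounders) <- paste0("z", seq_len(ncol(confounders)))
    if (ncol(confounders) == 0L) confounders <- NULL
  }
  structure(
    list(outcome = outcome,
         level = factor(level, levels = .levels),
         confounders = confounders,
         n = length(outcome)),
    class = "exposure_data")
}

#' @export
print.exposure_data <- function(x, ...) {
  cat("Exposure data: ", x$n, " subjects (",
      sum(x$outcome), " cases, ", sum(1L - x$outcome), " controls)\n",
      sep = "")
  print(table(level = x$level, outcome = x$outcome))
  if (!is.null(x$confounders))
    cat("Confounders:", paste(colnames(x$confounders), collapse = ", "), "\n")
  invisible(x)
}

#' 2 x 4 case/control count table
#'
#' Cell counts of cases and controls across the four combined exposure
#' levels, in the fixed order neither, A only, B only, both. This is the
#' sufficient statistic for the saturated (confounder-free) logistic model.
#'
#' @param cases,controls nonnegative integer vectors of length 4.
#' @return An object of class `count_table`: a 2 x 4 integer-like matrix
#'   with rows `cases`/`controls` and columns
#'   `neither`/`a_only`/`b_only`/`both`.
#' @examples
#' oral_cancer_counts()
#' @export
count_table <- function(cases, controls) {
  cases <- as.numeric(cases); controls <- as.numeric(controls)
  if (length(cases) != 4L || length(controls) != 4L)
    stop("`cases` and `controls` must each have 4 cells", call. = FALSE)
  if (any(cases < 0) || any(controls < 0))
    stop("cell counts must be nonnegative", call. = FALSE)
  if (sum(cases) + sum(controls) <= 0)
    stop("total count must be positive", call. = FALSE)
  m <- rbind(cases = cases, controls = controls)
  colnames(m) <- .level_labels
  structure(m, class = c("count_table", class(m)))
}

#' @export
print.count_table <- function(x, ...) {
  cat("Case/control counts by combined exposure level:\n")
  print(unclass(x))
  invisible(x)
}

#' Smoking-and-alcohol oral cancer counts
#'
#' Cell counts from a male-veteran case-control study of oral cancer with
#' smoking and alcohol use as the two risk factors (458 participants), the
#' classic worked example for additive-interaction confidence intervals.
#'
#' @return A [count_table()] with cases (3, 8, 6, 225) and controls
#'   (20, 18, 12, 166).
#' @export
oral_cancer_counts <- function() {
  count_table(cases = c(3, 8, 6, 225), controls = c(20, 18, 12, 166))
}

#' Convert between counts and subject-level data
#'
#' `as_exposure_data()` expands a [count_table()] into one row per subject;
#' `as_count_table()` aggregates subject-level data (ignoring confounders)
#' back into cell counts. The two are inverse up to row order.
#'
#' @param x a `count_table` or `exposure_data` object.
#' @return An `exposure_data` or `count_table`, respectively.
#' @export
as_exposure_data <- function(x) {
  stopifnot(inherits(x, "count_table"))
  if (any(x != round(x)))
    stop("cannot expand non-integer counts to subjects", call. = FALSE)
  lev <- rep(rep(.levels, 2L), times = as.vector(t(x)))
  y <- rep(c(1L, 0L), times = c(sum(x["cases", ]), sum(x["controls", ])))
  exposure_data(outcome = y, level = lev)
}

#' @rdname as_exposure_data
#' @export
as_count_table <- function(x) {
  stopifnot(inherits(x, "exposure_data"))
  tab <- table(factor(x$outcome, levels = 0:1), x$level)
  count_table(cases = as.numeric(tab["1", .levels]),
              controls = as.numeric(tab["0", .levels]))
}

#' Continuity correction for sparse tables
#'
#' Adds 0.5 to all eight cells (Haldane-Anscombe) so that log odds ratios and
#' their variances are finite when some cell is empty. The correction is
#' opt-in and recorded on the result so downstream reports can disclose it.
#'
#' @param x a [count_table()].
#' @return The corrected `count_table`, with attribute `corrected = TRUE`.
#' @export
continuity_correct <- function(x) {
  stopifnot(inherits(x, "count_table"))
  out <- count_table(x["cases", ] + 0.5, x["controls", ] + 0.5)
  attr(out, "corrected") <- TRUE
  out
}

# cell counts (cases, totals) and design info shared by the likelihood code
.cells <- function(data) {
  if (inherits(data, "count_table")) data <- as_exposure_data(data)
  stopifnot(inherits(data, "exposure_data"))
  tab <- table(factor(data$outcome, levels = 0:1), data$level)
  list(cases = as.numeric(tab["1", .levels]),
       totals = as.numeric(tab["1", .levels] + tab["0", .levels]))
}
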