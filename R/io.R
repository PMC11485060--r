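# Readers and writers for the two input layouts, plus deterministic
# example-fixture generation. Counts travel as CSV (rows cases/controls,
# columns neither/a_only/b_only/both) or as JSON with the same names;
# subject-level data as delimited text with header columns
# outcome, factor_a, factor_b, then optional confounders.

#' Read and write 2 x 4 count tables
#'
#' CSV layout: a `group` column with values `cases`/`controls` and the four
#' level columns `neither`, `a_only`, `b_only`, `both`. JSON layout: an
#' object with `cases` and `controls` arrays of length 4 in the same order.
#' The format is chosen by file extension (`.json` vs anything else).
#'
#' @param path file path.
#' @return `read_counts()` returns a [count_table()]; `write_counts()`
#'   invisibly returns `path`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!all(c("cases", "controls") %in% names(x)))
      stop("JSON counts need `cases` and `controls` arrays", call. = FALSE)
    return(count_table(x$cases, x$controls))
  }
  df <- tryCatch(read.csv(path, sep = .detect_sep(path),
                          strip.white = TRUE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0) stop("empty counts file: ", path, call. = FALSE)
  need <- c("group", .level_labels)
  if (!all(need %in% names(df)))
    stop("counts file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  get_row <- function(g) {
    r <- df[df$group == g, .level_labels]
    if (nrow(r) != 1) stop("need exactly one `", g, "` row", call. = FALSE)
    v <- as.numeric(r)
    if (any(is.na(v) | v < 0))
      stop("negative or missing cell in row `", g, "`", call. = FALSE)
    v
  }
  count_table(get_row("cases"), get_row("controls"))
}

#' @rdname read_counts
#' @param table a [count_table()] to write.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(cases = unname(table["cases", ]),
                              controls = unname(table["controls", ])),
                         path, digits = NA)
  } else {
    df <- data.frame(group = rownames(table), unclass(table),
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("\t", first)) "\t" else ","
}

#' Read and write subject-level data
#'
#' Delimited text (comma default, tab accepted) with a header; required
#' columns `outcome`, `factor_a`, `factor_b` (all 0/1), with any further
#' numeric columns treated as confounders in order.
#'
#' @param path file path.
#' @return `read_individuals()` returns an [exposure_data()];
#'   `write_individuals()` invisibly returns `path`.
#' @export
read_individuals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, sep = .detect_sep(path))
  need <- c("outcome", "factor_a", "factor_b")
  if (!all(need %in% names(df)))
    stop("individual-level file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  for (cn in need) {
    bad <- which(!(df[[cn]] %in% c(0, 1)))
    if (length(bad))
      stop("non-binary value in column `", cn, "` at data line ", bad[1],
           call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  exposure_data(outcome = df$outcome, a = df$factor_a, b = df$factor_b,
                confounders = if (length(extra))
                  as.matrix(df[, extra, drop = FALSE]) else NULL)
}

#' @rdname read_individuals
#' @param data an [exposure_data()] to write.
#' @export
write_individuals <- function(data, path) {
  stopifnot(inherits(data, "exposure_data"))
  df <- data.frame(outcome = data$outcome,
                   factor_a = as.integer(data$level %in% c("A1B0", "A1B1")),
                   factor_b = as.integer(data$level %in% c("A0B1", "A1B1")))
  if (!is.null(data$confounders)) df <- cbind(df, data$confounders)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write deterministic example inputs
#'
#' `"oral_cancer"` writes the smoking/alcohol count table;
#' `"S1"`...`"S7"` write a simulated subject-level dataset under the named
#' scenario; `"additive_null"` writes a large dataset generated under exact
#' additivity (the S4 odds ratios).
#'
#' @param kind one of `"oral_cancer"`, `"S1"`..`"S7"`, `"additive_null"`.
#' @param path output file path.
#' @param seed seed for the simulated kinds.
#' @param n subjects for the simulated kinds.
#' @return The path, invisibly.
#' @export
make_fixture <- function(kind, path, seed = 1L, n = 400L) {
  sims <- paste0("S", 1:7)
  if (kind == "oral_cancer") {
    write_counts(oral_cancer_counts(), path)
  } else if (kind %in% sims) {
    write_individuals(
      generate_dataset(standard_scenarios(kind)[[1]], n = n, seed = seed),
      path)
  } else if (kind == "additive_null") {
    write_individuals(
      generate_dataset(scenario_spec("additive_null", 4, 5, 8),
                       n = max(n, 10000L), seed = seed),
      path)
  } else {
    stop("unknown fixture kind: ", kind, call. = FALSE)
  }
  invisible(path)
}
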