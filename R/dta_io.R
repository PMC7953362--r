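#' Construct a diagnostic test accuracy dataset
#'
#' A `dta_dataset` holds one 2x2 table per primary study: true positives
#' (TP), false negatives (FN), false positives (FP) and true negatives (TN),
#' keyed by a free-text study identifier. It is a thin `data.frame`
#' subclass, so all the usual subsetting and printing tools apply.
#'
#' @param study_name character (or coercible) vector of unique study IDs.
#' @param tp,fn,fp,tn non-negative integer count vectors, one per study.
#'
#' @details Each study must contribute at least one diseased subject
#'   (`tp + fn >= 1`) and one non-diseased subject (`fp + tn >= 1`), and at
#'   least two studies are required: the between-study standard deviations
#'   of the hierarchical model are unidentifiable from a single study.
#'
#' @return An object of class `dta_dataset` (a `data.frame` with columns
#'   `study_name`, `tp`, `fn`, `fp`, `tn`).
#' @seealso [read_dsv()], [validate_dataset()], [example_dataset()]
#' @export
#' @examples
#' dta_dataset(c("A", "B"), tp = c(9, 8), fn = c(1, 2),
#'             fp = c(2, 1), tn = c(8, 9))
dta_dataset <- function(study_name, tp, fn, fp, tn) {
  study_name <- as.character(study_name)
  counts <- list(tp = tp, fn = fn, fp = fp, tn = tn)
  n <- length(study_name)
  for (nm in names(counts)) {
    counts[[nm]] <- coerce_count(counts[[nm]], nm)
    if (length(counts[[nm]]) != n)
      stop("'", nm, "' must have one value per study", call. = FALSE)
  }
  d <- data.frame(study_name = study_name, counts,
                  stringsAsFactors = FALSE)
  class(d) <- c("dta_dataset", "data.frame")
  validate_dataset(d, warn = FALSE)
  d
}

# Coerce numeric-looking counts to integer; "90.0" is fine, "90.5" is not.
coerce_count <- function(x, field, rows = NULL) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    x <- trimws(x)
    suppressWarnings(xn <- as.numeric(x))
    bad <- is.na(xn) & !is.na(x)
    if (any(bad))
      stop(sprintf("non-numeric count in field '%s' (row %d): '%s'",
                   field, row_label(bad, rows), x[which(bad)[1L]]),
           call. = FALSE)
    x <- xn
  }
  if (!is.numeric(x))
    stop("counts in field '", field, "' must be numeric", call. = FALSE)
  if (anyNA(x))
    stop(sprintf("missing count in field '%s' (row %d)",
                 field, row_label(is.na(x), rows)), call. = FALSE)
  if (any(x < 0))
    stop(sprintf("negative count in field '%s' (row %d)",
                 field, row_label(x < 0, rows)), call. = FALSE)
  frac <- abs(x - round(x)) > 1e-8
  if (any(frac))
    stop(sprintf("non-integer count in field '%s' (row %d): %s",
                 field, row_label(frac, rows), x[which(frac)[1L]]),
         call. = FALSE)
  as.integer(round(x))
}

row_label <- function(bad, rows) {
  i <- which(bad)[1L]
  if (is.null(rows)) i else rows[i]
}

#' Read per-study 2x2 tables from a delimiter-separated file
#'
#' Reads a five-column table (`study_name`, `TP`, `FN`, `FP`, `TN`) from a
#' text file or literal text. Header names are matched case-insensitively
#' after trimming whitespace and may appear in any column order; exactly
#' those five columns must be present. Standard CSV quoting is honoured and
#' fully blank lines are skipped.
#'
#' @param source path to a file, or a character string containing the data
#'   itself (anything with an embedded newline is treated as literal text).
#' @param delimiter one of `"comma"`, `"semicolon"`, `"tab"`, `"space"`.
#'   There is no auto-detection: state the delimiter the file actually
#'   uses. For space-delimited files any run of spaces is one separator,
#'   so study names must not contain spaces there.
#'
#' @return A [dta_dataset()] whose rows preserve file order.
#' @export
#' @examples
#' txt <- "study_name,TP,FN,FP,TN\nA,9,1,2,8\nB,8,2,1,9\n"
#' read_dsv(txt, "comma")
read_dsv <- function(source,
                     delimiter = c("comma", "semicolon", "tab", "space")) {
  delimiter <- match.arg(delimiter)
  sep <- switch(delimiter, comma = ",", semicolon = ";",
                tab = "\t", space = "")
  con <- if (length(source) == 1L && !grepl("\n", source) &&
             file.exists(source)) source else textConnection(source)
  raw <- utils::read.table(con, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           blank.lines.skip = TRUE, comment.char = "",
                           strip.white = TRUE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("study_name", "tp", "fn", "fp", "tn")
  got <- tolower(trimws(names(raw)))
  for (nm in required) {
    k <- sum(got == nm)
    if (k == 0L)
      stop("missing required column '", nm, "'", call. = FALSE)
    if (k > 1L)
      stop("duplicated required column '", nm, "'", call. = FALSE)
  }
  extra <- setdiff(got, required)
  if (length(extra))
    stop("unexpected column(s): ", paste(extra, collapse = ", "),
         "; exactly study_name, TP, FN, FP, TN are allowed", call. = FALSE)
  if (nrow(raw) == 0L)
    stop("no data rows found below the header", call. = FALSE)
  names(raw) <- got
  rows <- seq_len(nrow(raw)) + 1L  # file rows, counting the header
  counts <- lapply(c(tp = "tp", fn = "fn", fp = "fp", tn = "tn"),
                   function(nm) coerce_count(raw[[nm]], toupper(nm), rows))
  d <- data.frame(study_name = as.character(raw$study_name), counts,
                  stringsAsFactors = FALSE)
  class(d) <- c("dta_dataset", "data.frame")
  validate_dataset(d, warn = FALSE)
  d
}

#' Write a dataset back to a delimiter-separated file
#'
#' Inverse of [read_dsv()]: the written file re-reads to an identical
#' dataset with the matching delimiter.
#'
#' @param d a [dta_dataset()].
#' @param path output file path.
#' @inheritParams read_dsv
#' @return `path`, invisibly.
#' @export
write_dsv <- function(d, path,
                      delimiter = c("comma", "semicolon", "tab", "space")) {
  delimiter <- match.arg(delimiter)
  sep <- switch(delimiter, comma = ",", semicolon = ";",
                tab = "\t", space = " ")
  if (delimiter == "space" && any(grepl(" ", d$study_name)))
    stop("study names must not contain spaces in space-delimited files",
         call. = FALSE)
  out <- data.frame(study_name = d$study_name, TP = d$tp, FN = d$fn,
                    FP = d$fp, TN = d$tn)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a diagnostic test accuracy dataset
#'
#' Raises an error on structural violations (fewer than two studies,
#' duplicated study names, a study with no diseased or no non-diseased
#' subjects, negative or non-integer counts) and returns character warnings
#' for non-fatal oddities: fewer than five studies (hyper-parameters will
#' be poorly identified) and zero cells (permitted — the exact binomial
#' likelihood needs no continuity correction — but they widen posteriors).
#'
#' @param d a [dta_dataset()] or compatible data.frame.
#' @param warn if `TRUE` (default) also emit the warnings via [warning()].
#' @return invisibly, a character vector of warning messages (possibly
#'   empty).
#' @export
validate_dataset <- function(d, warn = TRUE) {
  required <- c("study_name", "tp", "fn", "fp", "tn")
  if (!all(required %in% names(d)))
    stop("dataset must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (nrow(d) < 2L)
    stop("at least 2 studies are required (between-study standard ",
         "deviations are unidentifiable from fewer)", call. = FALSE)
  dup <- unique(d$study_name[duplicated(d$study_name)])
  if (length(dup))
    stop("duplicated study_name: ", paste(dup, collapse = ", "),
         call. = FALSE)
  for (nm in c("tp", "fn", "fp", "tn")) {
    x <- d[[nm]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) ||
        any(abs(x - round(x)) > 1e-8))
      stop("counts in '", nm, "' must be non-negative integers",
           call. = FALSE)
  }
  if (any(d$tp + d$fn < 1L))
    stop("every study needs at least one diseased subject (TP + FN >= 1)",
         call. = FALSE)
  if (any(d$fp + d$tn < 1L))
    stop("every study needs at least one non-diseased subject ",
         "(FP + TN >= 1)", call. = FALSE)
  msgs <- character()
  if (nrow(d) < 5L)
    msgs <- c(msgs, sprintf(
      "only %d studies: hierarchical variance estimates will be imprecise",
      nrow(d)))
  zc <- d$tp == 0L | d$fn == 0L | d$fp == 0L | d$tn == 0L
  if (any(zc))
    msgs <- c(msgs, sprintf(
      "zero cell(s) in study %s: allowed, but posteriors will be wide",
      paste(d$study_name[zc], collapse = ", ")))
  if (warn) for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}

#' The packaged nine-study example dataset
#'
#' A well-known worked example of nine diagnostic accuracy studies with
#' numeric study IDs, shipped as `extdata/example_data_set.csv`. A variant
#' with author-year style character IDs and identical counts is available
#' via `named_example_dataset()` (`extdata/sample_named_studies.csv`).
#'
#' @return A [dta_dataset()] with 9 studies.
#' @export
#' @examples
#' example_dataset()
example_dataset <- function() {
  read_dsv(system.file("extdata", "example_data_set.csv",
                       package = "hsrocpoint", mustWork = TRUE), "comma")
}

#' @rdname example_dataset
#' @export
named_example_dataset <- function() {
  read_dsv(system.file("extdata", "sample_named_studies.csv",
                       package = "hsrocpoint", mustWork = TRUE), "comma")
}

#' @export
print.dta_dataset <- function(x, ...) {
  cat(sprintf("Diagnostic test accuracy dataset: %d studies\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
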