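#' Log-bounds randomness test
#'
#' Runs the log-bounds test on a symbol string: for each prefix length in
#' the schedule, the suffix structure of the prefix is rebuilt, its minimum
#' hapax length `mhl` and maximum repeat length `mrl` are computed, and
#' both are compared against the logarithmic reference values
#' `ceiling(log(n, m))` and `ceiling(2 * log(n, m))` with a tolerance of
#' one ([check_row()]).  A prefix showing both coincidences is a positive
#' symptom of randomness; the aggregate score is the fraction of prefixes
#' passing both checks, and the signed deviations are summarised by their
#' mean and standard deviation.
#'
#' @param x A `symbol_string`, or anything [symbol_string()] accepts.
#' @param prefixes Integer vector of prefix lengths (sorted, each at most
#'   the string length).  Default: [default_prefixes()].
#' @param m Optional alphabet-size override (a nominal size such as 4 for
#'   DNA, 26 for letters, 256 for bytes); defaults to the string's
#'   declared size.
#' @param verbose When `TRUE`, log the elapsed time of each prefix
#'   computation.
#' @return An object of class `lbt`: `rows` (one [check_row()] per prefix),
#'   `score`, `mean_dev_mhl`, `sd_dev_mhl`, `mean_dev_mrl`, `sd_dev_mrl`,
#'   `n`, `m`.
#' @examples
#' r <- lbt(uniform_string(10000, m = 10, seed = 1))
#' r$score
#' @seealso [run_lbt()] for the file-in/report-out wrapper,
#'   [write_lbt()] for TSV/JSON serialization.
#' @export
lbt <- function(x, prefixes = NULL, m = NULL, verbose = FALSE) {
  s <- symbol_string(x, m = m)
  if (!is.null(m)) {
    if (m < s$m) stop("declared m smaller than alphabet")
    s$m <- as.integer(m)
  }
  if (s$m < 2L) stop("degenerate alphabet")
  if (is.null(prefixes)) prefixes <- default_prefixes(s$n)
  prefixes <- sort(unique(as.numeric(prefixes)))
  if (any(prefixes > s$n)) stop("prefix exceeds string")
  if (any(prefixes < 1)) stop("prefix lengths must be >= 1")
  rows <- do.call(rbind, lapply(prefixes, function(p) {
    t0 <- proc.time()[["elapsed"]]
    idx <- suffix_index(prefix(s, p))
    row <- check_row(min_hapax_length(idx), max_repeat_length(idx),
                     log_bounds(p, s$m))
    if (verbose) {
      message(sprintf("lbt: prefix n = %g done in %.2f s",
                      p, proc.time()[["elapsed"]] - t0))
    }
    row
  }))
  new_lbt(rows, s$n, s$m)
}

new_lbt <- function(rows, n, m) {
  structure(
    list(
      rows = rows,
      score = mean(rows$mhl_check & rows$mrl_check),
      mean_dev_mhl = mean(rows$dev_mhl),
      sd_dev_mhl = stats::sd(rows$dev_mhl),
      mean_dev_mrl = mean(rows$dev_mrl),
      sd_dev_mrl = stats::sd(rows$dev_mrl),
      n = n, m = m
    ),
    class = "lbt"
  )
}

#' @export
print.lbt <- function(x, ...) {
  cat(sprintf("Log-bounds randomness test  (n = %s, m = %d)\n\n",
              format(x$n, big.mark = ","), x$m))
  tab <- data.frame(
    n = format(x$rows$n, big.mark = ",", scientific = FALSE),
    mhl = x$rows$mhl,
    `ceil(LG)` = x$rows$ceil_lg,
    check = ifelse(x$rows$mhl_check, "✓", "✗"),
    `mrl+1` = x$rows$mrl_plus1,
    `ceil(2LG)` = x$rows$ceil_two_lg,
    check2 = ifelse(x$rows$mrl_check, "✓", "✗"),
    check.names = FALSE
  )
  names(tab)[7] <- "check"
  print(tab, row.names = FALSE, right = TRUE)
  cat(sprintf("\nscore: %.3f  (%d/%d prefixes pass both checks)\n",
              x$score, sum(x$rows$mhl_check & x$rows$mrl_check),
              nrow(x$rows)))
  invisible(x)
}

#' @export
summary.lbt <- function(object, ...) {
  cat(sprintf("Log-bounds test: %d prefixes of a string with n = %s, m = %d\n",
              nrow(object$rows), format(object$n, big.mark = ","), object$m))
  cat(sprintf("  score                : %.3f\n", object$score))
  cat(sprintf("  mhl - ceil(LG)       : mean %+.3f, sd %.3f\n",
              object$mean_dev_mhl, object$sd_dev_mhl))
  cat(sprintf("  mrl+1 - ceil(2LG)    : mean %+.3f, sd %.3f\n",
              object$mean_dev_mrl, object$sd_dev_mrl))
  invisible(object)
}

#' @export
as.data.frame.lbt <- function(x, ...) x$rows

#' @export
plot.lbt <- function(x, ...) {
  r <- x$rows
  lx <- log10(r$n)
  ylim <- range(c(r$dev_mhl, r$dev_mrl, -2, 2))
  graphics::plot(lx, r$dev_mrl, type = "b", pch = 19, ylim = ylim,
       xlab = "log10(prefix length)", ylab = "deviation from bound",
       main = "Log-bounds test deviations", ...)
  graphics::lines(lx, r$dev_mhl, type = "b", pch = 1, lty = 2)
  graphics::abline(h = c(-1, 1), col = "grey60", lty = 3)
  graphics::legend("topleft", bty = "n", pch = c(19, 1), lty = c(1, 2),
                   legend = c("mrl+1 - ceil(2LG)", "mhl - ceil(LG)"))
  invisible(x)
}

#' Run the log-bounds test and serialize the report
#'
#' Convenience wrapper: encodes the input if needed, runs [lbt()] and
#' optionally writes the report table ([write_lbt()]).
#'
#' @inheritParams lbt
#' @param out Optional output path for the report.
#' @param format `"tsv"` (table mirroring the per-prefix checks) or
#'   `"json"` (rows plus score and deviation statistics).
#' @return The `lbt` object, invisibly when `out` is given.
#' @export
run_lbt <- function(x, prefixes = NULL, m = NULL, out = NULL,
                    format = c("tsv", "json"), verbose = FALSE) {
  format <- match.arg(format)
  rep <- lbt(x, prefixes = prefixes, m = m, verbose = verbose)
  if (!is.null(out)) {
    write_lbt(rep, out, format = format)
    return(invisible(rep))
  }
  rep
}

#' Write a log-bounds report to TSV or JSON
#'
#' TSV columns are `n, mhl, ceil_LG, check1, mrl_plus_1, ceil_2LG, check2`
#' with checks rendered `PASS`/`FAIL` (encoding-safe); JSON carries the
#' rows plus the score and deviation statistics.
#'
#' @param x An `lbt` object.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_lbt <- function(x, path, format = c("tsv", "json")) {
  stopifnot(inherits(x, "lbt"))
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(
      n = x$rows$n,
      mhl = x$rows$mhl,
      ceil_LG = x$rows$ceil_lg,
      check1 = ifelse(x$rows$mhl_check, "PASS", "FAIL"),
      mrl_plus_1 = x$rows$mrl_plus1,
      ceil_2LG = x$rows$ceil_two_lg,
      check2 = ifelse(x$rows$mrl_check, "PASS", "FAIL")
    )
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    obj <- list(
      n = x$n, m = x$m,
      rows = x$rows,
      score = x$score,
      mean_dev_mhl = x$mean_dev_mhl, sd_dev_mhl = x$sd_dev_mhl,
      mean_dev_mrl = x$mean_dev_mrl, sd_dev_mrl = x$sd_dev_mrl
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  }
  invisible(path)
}

#' Read back a serialized log-bounds report
#'
#' Inverse of [write_lbt()]; reconstructs the `lbt` object (checks and
#' aggregate statistics are recomputed from the rows, so a round trip is
#' exact).
#'
#' @param path File written by [write_lbt()].
#' @param format `"tsv"` or `"json"`; default guesses from the extension.
#' @return An `lbt` object.
#' @export
read_lbt <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    rows <- as.data.frame(obj$rows)
    return(new_lbt(rows, obj$n, obj$m))
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  rows <- data.frame(
    n = tab$n,
    mhl = tab$mhl,
    ceil_lg = tab$ceil_LG,
    mhl_check = tab$check1 == "PASS",
    mrl_plus1 = tab$mrl_plus_1,
    ceil_two_lg = tab$ceil_2LG,
    mrl_check = tab$check2 == "PASS",
    dev_mhl = tab$mhl - tab$ceil_LG,
    dev_mrl = tab$mrl_plus_1 - tab$ceil_2LG
  )
  new_lbt(rows, max(tab$n), NA_integer_)
}
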