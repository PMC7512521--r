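#' Read a plain-text symbol string
#'
#' Reads a file as one symbol string, one symbol per byte/character.
#' Characters outside the filter are discarded (never an error) and never
#' reordered; `filter = "letters"` also case-folds to lower case.  With
#' `filter = "none"` the file is read byte-wise, so arbitrary binary
#' alphabets (up to 256 symbols) are supported.
#'
#' @param path Path to the input file.
#' @param filter `"none"`, `"digits"`, `"letters"`, or a character vector
#'   giving a custom set of symbols to retain.
#' @param alphabet Optional explicit alphabet passed to [symbol_string()].
#' @param m Optional declared alphabet size.
#' @return A [symbol_string()]; the number of discarded characters is
#'   recorded in `attr(, "dropped")` and the source path in
#'   `attr(, "source")`.
#' @examples
#' f <- tempfile(); writeLines("3.14159", f)
#' format(read_symbols(f, filter = "digits"))  # "314159"
#' @export
read_symbols <- function(path, filter = "none", alphabet = NULL, m = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (identical(filter, "none")) {
    bytes <- readBin(path, what = "raw", n = file.size(path))
    codes <- as.integer(bytes)
    if (length(codes) == 0L) stop("no symbols retained")
    if (is.null(m)) m <- max(codes) + 1L
    s <- symbol_string(codes, m = m)
    s$alphabet <- vapply(seq_len(s$m) - 1L, function(b) {
      if (b >= 32L && b <= 126L) rawToChar(as.raw(b)) else sprintf("\\x%02x", b)
    }, character(1))
    attr(s, "dropped") <- 0L
    attr(s, "source") <- path
    attr(s, "filter") <- "none"
    return(s)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  if (length(filter) == 1L && filter %in% c("digits", "letters")) {
    if (filter == "digits") {
      keep <- chars %in% as.character(0:9)
      chars <- chars[keep]
    } else {
      keep <- grepl("[A-Za-z]", chars)
      chars <- tolower(chars[keep])
    }
  } else {
    keep <- chars %in% filter
    chars <- chars[keep]
  }
  dropped <- sum(!keep)
  if (length(chars) == 0L) stop("no symbols retained")
  s <- symbol_string(chars, alphabet = alphabet, m = m)
  attr(s, "dropped") <- dropped
  attr(s, "source") <- path
  attr(s, "filter") <- if (length(filter) == 1L) filter else "custom"
  s
}

#' Read a FASTA file as a symbol string
#'
#' Parses a (possibly multi-record, multi-line) FASTA file with
#' \pkg{Biostrings}.  When `record` is given only that record is used;
#' otherwise all records are concatenated in file order.  Sequences are
#' upper-cased; in nucleotide mode characters outside `{A, C, G, T}`
#' (ambiguity codes, `N`) are dropped and their count reported in a
#' message and in `attr(, "dropped")`.
#'
#' @param path Path to a FASTA file.
#' @param record Optional record id (the word before the first space in
#'   the header).
#' @param mode `"nucleotide"` (alphabet ACGT, `m = 4`) or `"protein"`
#'   (the 20 standard residues).
#' @return A [symbol_string()] with the declared alphabet of the mode.
#' @export
read_fasta <- function(path, record = NULL,
                       mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("invalid FASTA: ", conditionMessage(e)))
  if (length(set) == 0L) stop("invalid FASTA: no records")
  ids <- sub("\\s.*$", "", names(set))
  if (!is.null(record)) {
    hit <- which(ids == record)
    if (length(hit) == 0L) stop("record not found: ", record)
    set <- set[hit]
  }
  seq <- toupper(paste(as.character(set), collapse = ""))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  alph <- if (mode == "nucleotide") c("A", "C", "G", "T") else
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  keep <- chars %in% alph
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("read_fasta: dropped %d symbols outside the %s alphabet",
                    dropped, mode))
  }
  chars <- chars[keep]
  if (length(chars) == 0L) stop("no symbols retained")
  s <- symbol_string(chars, alphabet = alph)
  attr(s, "dropped") <- dropped
  attr(s, "source") <- path
  s
}
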