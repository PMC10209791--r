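# Character code table: per-character sub-glyph code systems.
#
# Each Chinese character carries four code strings:
#   * five_stroke — wubi keyboard code, 1-4 lowercase letters
#   * zheng      — Zheng root/structure code, 1-4 lowercase letters
#   * phonological — pinyin syllable with tone
#   * stroke_seq — ordered stroke types as digits 1-5 (horizontal, vertical,
#     left-falling, right-falling, turning)
# Characters absent from a table (digits, Latin letters, punctuation) map to
# a designated UNK record whose codes are empty, so every downstream feature
# channel is all-zero for them.

RE_LETTER_CODE <- "^[a-z]{1,4}$"
RE_STROKE_CODE <- "^[1-5]*$"

new_unk_record <- function() {
  tibble(
    char = NA_character_, five_stroke = "", zheng = "",
    phonological = "", stroke_seq = ""
  )
}

validate_code_row <- function(char, five_stroke, zheng, phonological, stroke_seq) {
  if (is.na(char) || nchar(char) != 1L) {
    return("`char` must be a single Unicode codepoint")
  }
  if (!grepl(RE_LETTER_CODE, five_stroke)) {
    return(sprintf("five_stroke %s does not match %s", dQuote(five_stroke), RE_LETTER_CODE))
  }
  if (!grepl(RE_LETTER_CODE, zheng)) {
    return(sprintf("zheng %s does not match %s", dQuote(zheng), RE_LETTER_CODE))
  }
  if (!grepl(RE_STROKE_CODE, stroke_seq) || nchar(stroke_seq) == 0L) {
    return(sprintf("stroke_seq %s must be a non-empty string over digits 1-5", dQuote(stroke_seq)))
  }
  NA_character_
}

#' Build a code table from a data frame
#'
#' @param entries A data frame with columns `char`, `five_stroke`, `zheng`,
#'   `phonological`, `stroke_seq` (one row per character).
#' @return A `code_table` object: the validated entries plus the UNK record
#'   returned for unknown characters.
#' @export
code_table <- function(entries) {
  entries <- as_tibble(entries)
  need <- c("char", "five_stroke", "zheng", "phonological", "stroke_seq")
  if (!all(need %in% names(entries))) {
    abort(paste0("code table needs columns: ", paste(need, collapse = ", ")))
  }
  entries <- entries[need]
  for (col in need) entries[[col]] <- as.character(entries[[col]])
  if (nrow(entries) > 0) {
    msgs <- purrr::pmap_chr(entries, validate_code_row)
    if (any(!is.na(msgs))) {
      i <- which(!is.na(msgs))[1]
      abort(sprintf("invalid code table row %d: %s", i, msgs[i]))
    }
    dup <- entries$char[duplicated(entries$char)]
    if (length(dup) > 0) {
      abort(sprintf("duplicate character(s) in code table: %s",
                    paste(unique(dup), collapse = " ")))
    }
  }
  structure(
    list(entries = entries, unk_record = new_unk_record()),
    class = "code_table"
  )
}

#' @export
print.code_table <- function(x, ...) {
  cat(sprintf("<code_table> %d characters\n", nrow(x$entries)))
  if (nrow(x$entries) > 0) print(head(x$entries, 6))
  invisible(x)
}

#' @export
length.code_table <- function(x) nrow(x$entries)

#' Read a character code table from a TSV file
#'
#' The file is UTF-8, tab-separated, five columns
#' `char  five_stroke  zheng  phonological  stroke_seq`; a header line is
#' optional and `#`-prefixed comment lines are ignored. Malformed rows are
#' rejected with a line-numbered error.
#'
#' @param path Path to the TSV file.
#' @return A [code_table()].
#' @export
#' @examples
#' tab <- read_code_table(mscner_file("code_table_reference.tsv"))
#' lookup_codes(tab, "心")  # heart
read_code_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("code table file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rows <- list()
  seen <- character(0)
  for (ln in keep) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (identical(tolower(fields[1]), "char")) next # header
    if (length(fields) != 5L) {
      abort(sprintf("line %d: expected 5 tab-separated columns, got %d", ln, length(fields)))
    }
    fields <- trimws(fields)
    msg <- validate_code_row(fields[1], fields[2], fields[3], fields[4], fields[5])
    if (!is.na(msg)) abort(sprintf("line %d: %s", ln, msg))
    if (fields[1] %in% seen) abort(sprintf("line %d: duplicate character %s", ln, dQuote(fields[1])))
    seen <- c(seen, fields[1])
    rows[[length(rows) + 1L]] <- fields
  }
  if (length(rows) == 0) {
    return(code_table(tibble(
      char = character(0), five_stroke = character(0), zheng = character(0),
      phonological = character(0), stroke_seq = character(0)
    )))
  }
  m <- do.call(rbind, rows)
  code_table(tibble(
    char = m[, 1], five_stroke = m[, 2], zheng = m[, 3],
    phonological = m[, 4], stroke_seq = m[, 5]
  ))
}

#' Look up one character's codes
#'
#' Total function: any character not in the table (including digits, Latin
#' letters and punctuation) returns the table's UNK record, whose codes are
#' empty strings.
#'
#' @param table A [code_table()].
#' @param char A single character.
#' @return One-row tibble with columns `char`, `five_stroke`, `zheng`,
#'   `phonological`, `stroke_seq`.
#' @export
lookup_codes <- function(table, char) {
  stopifnot(inherits(table, "code_table"))
  if (length(char) != 1L || is.na(char)) return(table$unk_record)
  i <- match(char, table$entries$char)
  if (is.na(i)) table$unk_record else table$entries[i, ]
}

#' Stroke-type count vector
#'
#' Collapses a stroke-sequence code into a 5-component vector counting each
#' stroke type: (horizontal, vertical, left-falling, right-falling, turning).
#' Components always sum to the code length.
#'
#' @param stroke_seq Digit string over `1`--`5` (empty string allowed, giving
#'   the zero vector).
#' @return Integer vector of length 5.
#' @export
#' @examples
#' stroke_count_vector("4544")  # heart: 3 right-falling + 1 turning
stroke_count_vector <- function(stroke_seq) {
  if (length(stroke_seq) != 1L || is.na(stroke_seq)) abort("`stroke_seq` must be a single string.")
  if (!grepl(RE_STROKE_CODE, stroke_seq)) {
    abort(sprintf("stroke_seq %s contains a digit outside 1-5", dQuote(stroke_seq)))
  }
  if (nchar(stroke_seq) == 0L) return(integer(5))
  d <- as.integer(chars_of(stroke_seq))
  tabulate(d, nbins = 5L)
}

#' One-hot encode a code string over an ordered alphabet
#'
#' Row `r` of the result is the indicator of symbol `r` of the code; rows
#' beyond the code length are all-zero, so the empty (UNK) code encodes as an
#' all-zero matrix. Codes longer than `max_len` are truncated with a warning.
#'
#' @param code Code to encode: a single string (split into characters) or a
#'   character vector of multi-letter symbols.
#' @param alphabet Ordered character vector of admissible symbols.
#' @param max_len Number of rows of the output.
#' @return A `max_len` x `length(alphabet)` binary matrix.
#' @export
#' @examples
#' one_hot_encode("kaqy", letters, 4)
one_hot_encode <- function(code, alphabet, max_len) {
  stopifnot(is.character(alphabet), length(alphabet) > 0, max_len >= 1)
  if (anyDuplicated(alphabet)) abort("`alphabet` has duplicate symbols.")
  syms <- if (length(code) == 1L && !is.na(code)) chars_of(code) else as.character(code)
  syms <- syms[!is.na(syms)]
  if (length(syms) > max_len) {
    warn(sprintf("code of length %d truncated to max_len = %d", length(syms), max_len))
    syms <- syms[seq_len(max_len)]
  }
  idx <- match(syms, alphabet)
  if (anyNA(idx)) {
    abort(sprintf("symbol(s) outside alphabet: %s",
                  paste(unique(syms[is.na(idx)]), collapse = " ")))
  }
  m <- matrix(0, nrow = max_len, ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  if (length(idx) > 0) m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode a one-hot matrix back to its symbol sequence
#'
#' Inverse of [one_hot_encode()] up to truncation.
#'
#' @param mat Binary matrix with column names giving the alphabet.
#' @return Character vector of symbols (empty for an all-zero matrix).
#' @export
one_hot_decode <- function(mat) {
  alphabet <- colnames(mat)
  out <- character(0)
  for (r in seq_len(nrow(mat))) {
    j <- which(mat[r, ] == 1)
    if (length(j) == 0) break
    out <- c(out, alphabet[j[1]])
  }
  out
}

#' Path to a bundled mscner data file
#'
#' @param ... File name components under the package's `extdata/` directory;
#'   empty to list available files.
#' @return File path(s).
#' @export
mscner_file <- function(...) {
  if (length(list(...)) == 0) {
    dir(system.file("extdata", package = "mscner"))
  } else {
    p <- system.file("extdata", ..., package = "mscner")
    if (p == "") abort(sprintf("no bundled file %s", file.path(...)))
    p
  }
}

#' Load the bundled code table
#'
#' Concatenates the reference table (six characters whose published
#' input-method codes are reproduced verbatim) with the synthetic table
#' covering the synthetic-corpus character set (well-formed but invented
#' codes, for offline testing).
#'
#' @param synthetic Include the synthetic rows (default `TRUE`).
#' @return A [code_table()].
#' @export
bundled_code_table <- function(synthetic = TRUE) {
  ref <- read_code_table(mscner_file("code_table_reference.tsv"))
  if (!synthetic) return(ref)
  syn <- read_code_table(mscner_file("code_table_synthetic.tsv"))
  code_table(dplyr::bind_rows(ref$entries, syn$entries))
}
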