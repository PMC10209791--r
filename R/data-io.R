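# CoNLL-style BIO corpus input/output, document chunking, corpus statistics.
#
# A corpus is a tidy tibble with one row per character:
#   doc_id (integer), pos (1-based position within the document),
#   char (single character), tag ("O", "B-X" or "I-X").
# Files are UTF-8, one "char<TAB>tag" per line, a blank line between
# documents. The tab separator is mandatory (space-delimited dialects are
# ambiguous with CJK text). Span coordinates elsewhere in the package are
# 0-based half-open.

RE_TAG <- "^(O|[BI]-[A-Za-z0-9_]+)$"

validate_corpus <- function(corpus) {
  corpus <- as_tibble(corpus)
  need <- c("doc_id", "pos", "char", "tag")
  if (!all(need %in% names(corpus))) {
    abort(paste0("corpus needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(corpus) > 0) {
    bad <- which(!grepl(RE_TAG, corpus$tag))
    if (length(bad) > 0) {
      abort(sprintf("invalid tag %s at row %d", dQuote(corpus$tag[bad[1]]), bad[1]))
    }
    if (any(nchar(corpus$char) != 1L)) abort("each `char` must be a single character")
  }
  corpus
}

#' Read a CoNLL-style BIO file
#'
#' @param path UTF-8 file, one `char<TAB>tag` per line, blank line between
#'   documents. Malformed lines raise a line-numbered error.
#' @return Corpus tibble with columns `doc_id`, `pos`, `char`, `tag`.
#' @export
read_bio <- function(path) {
  if (!file.exists(path)) abort(sprintf("BIO file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  doc_id <- integer(0); pos <- integer(0); ch <- character(0); tag <- character(0)
  cur_doc <- 1L; cur_pos <- 0L; any_in_doc <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) {
      if (any_in_doc) {
        cur_doc <- cur_doc + 1L; cur_pos <- 0L; any_in_doc <- FALSE
      }
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L) {
      abort(sprintf("line %d: expected `char<TAB>tag`, got %s", ln, dQuote(line)))
    }
    if (nchar(fields[1]) != 1L) {
      abort(sprintf("line %d: token %s is not a single character", ln, dQuote(fields[1])))
    }
    if (!grepl(RE_TAG, fields[2])) {
      abort(sprintf("line %d: invalid tag %s", ln, dQuote(fields[2])))
    }
    cur_pos <- cur_pos + 1L; any_in_doc <- TRUE
    doc_id <- c(doc_id, cur_doc); pos <- c(pos, cur_pos)
    ch <- c(ch, fields[1]); tag <- c(tag, fields[2])
  }
  tibble(doc_id = doc_id, pos = pos, char = ch, tag = tag)
}

#' Write a corpus to a CoNLL-style BIO file
#'
#' Inverse of [read_bio()]: `read_bio(write_bio(corpus, path))` round-trips
#' bit-exactly (document ids are positional).
#'
#' @param corpus Corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bio <- function(corpus, path) {
  corpus <- validate_corpus(corpus)
  blocks <- corpus |>
    group_by(.data$doc_id) |>
    summarise(block = paste(.data$char, .data$tag, sep = "\t", collapse = "\n"),
              .groups = "drop")
  writeLines(paste(blocks$block, collapse = "\n\n"), path, useBytes = FALSE)
  invisible(path)
}

#' Split long documents into chunks of at most `max_len` characters
#'
#' Chunk boundaries never split an entity: when the character after a
#' tentative boundary continues an entity (an `I-` tag), the boundary moves
#' left to the last `O`-tagged position before it. Concatenating the chunks
#' of a document restores it exactly. Documents already within `max_len`
#' come back unchanged (as chunk 1).
#'
#' @param corpus Corpus tibble (any number of documents).
#' @param max_len Maximum chunk length (default 510).
#' @return Corpus tibble with an added `chunk` column; `pos` is renumbered
#'   within each chunk.
#' @export
chunk_documents <- function(corpus, max_len = 510L) {
  corpus <- validate_corpus(corpus)
  out <- corpus |>
    group_by(.data$doc_id) |>
    group_modify(function(df, key) {
      n <- nrow(df)
      starts <- integer(0); ends <- integer(0)
      s <- 1L
      while (s <= n) {
        e <- min(s + max_len - 1L, n)
        if (e < n && grepl("^I-", df$tag[e + 1L])) {
          cand <- which(df$tag[s:e] == "O")
          if (length(cand) == 0L) {
            abort(sprintf("document %s: entity spanning more than max_len = %d characters cannot be chunked",
                          key$doc_id, max_len))
          }
          e <- s + max(cand) - 1L
        }
        starts <- c(starts, s); ends <- c(ends, e)
        s <- e + 1L
      }
      purrr::map2_dfr(seq_along(starts), seq_along(ends), function(k, ...) {
        piece <- df[starts[k]:ends[k], ]
        piece$chunk <- k
        piece$pos <- seq_len(nrow(piece))
        piece
      })
    }) |>
    ungroup()
  out[, c("doc_id", "chunk", "pos", "char", "tag")]
}

#' Per-category corpus statistics
#'
#' For each entity category, the train/test split ratio
#' `train / (train + test)` (rounded to 4 decimal places) and the category's
#' share of all entities (pooled over both splits), also as a percentage
#' rounded to 2 decimal places. A pooled `"All"` row is appended.
#'
#' @param counts Data frame with columns `category`, `train`, `test`
#'   (entity counts per split).
#' @return Tibble with columns `category`, `train`, `test`, `split_ratio`,
#'   `share`, `share_pct`.
#' @export
#' @examples
#' corpus_stats(data.frame(category = c("Disease", "Anatomy"),
#'                         train = c(4212, 8426), test = c(1323, 3094)))
corpus_stats <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("category", "train", "test") %in% names(counts)))
  if (any(counts$train < 0 | counts$test < 0)) abort("entity counts must be non-negative")
  grand <- sum(counts$train) + sum(counts$test)
  per <- counts |>
    mutate(
      split_ratio = round(.data$train / pmax(.data$train + .data$test, 1), 4),
      share = (.data$train + .data$test) / max(grand, 1),
      share_pct = round(100 * .data$share, 2)
    )
  total <- tibble(
    category = "All",
    train = sum(counts$train), test = sum(counts$test),
    split_ratio = round(sum(counts$train) / max(grand, 1), 4),
    share = 1, share_pct = 100
  )
  bind_rows(per, total)
}

#' Bundled entity-count tables
#'
#' Published per-category train/test entity counts for the two benchmark
#' corpora (Yidu-S4K and a self-annotated EMR set), bundled so corpus
#' statistics can be recomputed offline.
#'
#' @param dataset `"yidu_s4k"` or `"self_annotated"`.
#' @return Tibble with columns `category`, `train`, `test`.
#' @export
bundled_entity_counts <- function(dataset = c("yidu_s4k", "self_annotated")) {
  dataset <- match.arg(dataset)
  path <- mscner_file(sprintf("entity_counts_%s.tsv", dataset))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_tibble(df)
}
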