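# Entity-level evaluation: BIO span extraction, exact-match counting,
# precision / recall / F1 per category and micro-averaged.
#
# A predicted span counts as a true positive only when both boundaries and
# the category equal a gold span (no partial credit). Micro averaging pools
# TP/FP/FN over categories before applying the metric formulas:
#   precision = TP / (TP + FP)
#   recall    = TP / (TP + FN)
#   F1        = 2 * precision * recall / (precision + recall)
# with the zero-division guard P = R = F1 = 0 when a denominator is 0.

#' Extract entity spans from a BIO tag sequence
#'
#' Maximal `B-X (I-X)*` runs become spans of category `X`. An orphan `I-X`
#' (no preceding tag of the same category) starts a new span — the lenient
#' repair policy. Coordinates are 0-based half-open.
#'
#' @param tags Character vector over `O`, `B-X`, `I-X`.
#' @return Tibble with columns `start`, `end`, `category`.
#' @export
#' @examples
#' extract_entities(c("B-DIS", "I-DIS", "O", "B-ANA"))
extract_entities <- function(tags) {
  bad <- which(!grepl(RE_TAG, tags))
  if (length(bad) > 0) {
    abort(sprintf("unknown tag %s at position %d", dQuote(tags[bad[1]]), bad[1]))
  }
  starts <- integer(0); ends <- integer(0); cats <- character(0)
  cur_cat <- NA_character_; cur_start <- NA_integer_
  close_span <- function(upto) {
    if (!is.na(cur_cat)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, upto)
      cats <<- c(cats, cur_cat)
    }
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") {
      close_span(i - 1L); cur_cat <- NA_character_
    } else {
      kind <- substr(t, 1, 1)
      cat <- sub("^[BI]-", "", t)
      if (kind == "B" || is.na(cur_cat) || cat != cur_cat) {
        close_span(i - 1L)
        cur_cat <- cat; cur_start <- i - 1L
      }
    }
  }
  close_span(length(tags))
  tibble(start = starts, end = ends, category = cats)
}

#' Write non-overlapping spans as a BIO tag sequence
#'
#' Inverse of [extract_entities()] for valid span sets.
#'
#' @param spans Tibble with `start`, `end` (0-based half-open), `category`.
#' @param n Document length.
#' @return Character vector of `n` tags.
#' @export
spans_to_tags <- function(spans, n) {
  tags <- rep("O", n)
  if (nrow(spans) == 0) return(tags)
  spans <- dplyr::arrange(as_tibble(spans), .data$start)
  if (any(spans$start < 0 | spans$end > n | spans$start >= spans$end)) {
    abort("span coordinates out of range")
  }
  if (any(utils::head(spans$end, -1) > utils::tail(spans$start, -1))) {
    abort("spans overlap")
  }
  for (k in seq_len(nrow(spans))) {
    idx <- (spans$start[k] + 1L):spans$end[k]
    tags[idx] <- paste0("I-", spans$category[k])
    tags[idx[1]] <- paste0("B-", spans$category[k])
  }
  tags
}

#' Precision, recall and F1 from exact-match counts
#'
#' @param tp,fp,fn Non-negative counts of true positives, false positives
#'   and false negatives.
#' @return One-row tibble with `precision`, `recall`, `f1` in `[0, 1]`.
#' @export
prf1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  tibble(precision = p, recall = r, f1 = f1_score(p, r))
}

#' F1 as the harmonic mean of precision and recall
#'
#' Scale-agnostic: works on proportions or percentages. Returns 0 when
#' `precision + recall` is 0.
#'
#' @param precision,recall Numeric (same scale).
#' @return F1 on the same scale.
#' @export
#' @examples
#' f1_score(90.37, 88.22) # 89.28 to 2 d.p.
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

count_matches <- function(gold, pred) {
  # exact span-and-category matching within documents
  key <- function(df) paste(df$doc_id, df$start, df$end, df$category)
  gk <- key(gold); pk <- key(pred)
  tibble(
    category = unique(c(gold$category, pred$category))
  ) |>
    rowwise() |>
    mutate(
      tp = sum(pk %in% gk & pred$category == .data$category),
      fp = sum(!(pk %in% gk) & pred$category == .data$category),
      fn = sum(!(gk %in% pk) & gold$category == .data$category)
    ) |>
    ungroup()
}

#' Entity-level evaluation report
#'
#' Compares gold and predicted spans under exact boundary-and-category
#' matching, per category and micro-averaged over all categories (pooled
#' counts, reported as category `"All"`).
#'
#' @param gold,pred Tibbles with columns `doc_id`, `start`, `end`,
#'   `category` (0-based half-open spans). See [corpus_spans()] for
#'   building them from a BIO corpus.
#' @return A `ner_eval_report`: tibble with `category`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
evaluate_ner <- function(gold, pred) {
  gold <- as_tibble(gold); pred <- as_tibble(pred)
  need <- c("doc_id", "start", "end", "category")
  stopifnot(all(need %in% names(gold)), all(need %in% names(pred)))
  per <- count_matches(gold, pred) |> dplyr::arrange(.data$category)
  all_row <- tibble(category = "All", tp = sum(per$tp), fp = sum(per$fp),
                    fn = sum(per$fn))
  out <- bind_rows(per, all_row) |>
    rowwise() |>
    mutate(prf1(.data$tp, .data$fp, .data$fn)) |>
    ungroup()
  structure(out, class = c("ner_eval_report", class(out)))
}

#' Extract every document's spans from a BIO corpus
#'
#' @param corpus Corpus tibble (`doc_id`, `pos`, `char`, `tag`).
#' @return Tibble with `doc_id`, `start`, `end`, `category`.
#' @export
corpus_spans <- function(corpus) {
  corpus <- validate_corpus(corpus)
  corpus |>
    group_by(.data$doc_id) |>
    group_modify(function(df, key) extract_entities(df$tag[order(df$pos)])) |>
    ungroup()
}

#' @export
print.ner_eval_report <- function(x, ...) {
  cat("Entity-level evaluation (exact match), percent:\n")
  df <- as_tibble(x) |>
    mutate(across(c("precision", "recall", "f1"), ~ round(100 * .x, 2)))
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' Per-metric differences between two evaluation reports
#'
#' Deltas `a - b` on the percent scale, rounded to 2 decimal places, joined
#' by category (categories present in only one report get `NA`).
#'
#' @param a,b [evaluate_ner()] reports, or any tibbles with `category`,
#'   `precision`, `recall`, `f1` columns on the `[0, 1]` scale.
#' @return Tibble with `category`, `d_precision`, `d_recall`, `d_f1`.
#' @export
compare_reports <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  dplyr::full_join(a, b, by = "category", suffix = c("_a", "_b")) |>
    transmute(
      category = .data$category,
      d_precision = round(100 * (.data$precision_a - .data$precision_b), 2),
      d_recall = round(100 * (.data$recall_a - .data$recall_b), 2),
      d_f1 = round(100 * (.data$f1_a - .data$f1_b), 2)
    )
}

#' Write an evaluation report as TSV
#'
#' Category by precision/recall/F1, percent, 2 decimal places.
#'
#' @param report A `ner_eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  df <- as_tibble(report) |>
    mutate(across(c("precision", "recall", "f1"),
                  ~ sprintf("%.2f", 100 * .x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundled benchmark metric table
#'
#' Published precision/recall/F1 rows (percent) for reference models on the
#' two benchmark corpora, bundled so the metric arithmetic can be
#' cross-checked offline.
#'
#' @return Tibble with `dataset`, `model`, `precision`, `recall`, `f1`
#'   (percent; `NA` where a value was not published).
#' @export
bundled_benchmarks <- function() {
  df <- utils::read.delim(mscner_file("benchmark_metrics.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  as_tibble(df)
}
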