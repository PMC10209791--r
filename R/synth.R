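# Deterministic synthetic EMR-like corpus generator.
#
# Stands in for clinical corpora that cannot be redistributed: documents are
# template sentences over a closed set of ~66 Chinese characters (all with
# bundled codes and glyph bitmaps, so every feature channel is populated
# offline), interleaving O-tagged connective runs with entity mentions drawn
# from per-category dictionaries. Entity surface forms are 2-6 characters,
# so B->I transitions are exercised. Category frequencies default to the
# published per-category entity shares of a large self-annotated EMR set
# (strongly imbalanced: Instrument ~1.5%). Generation is deterministic
# given the seed. A controlled label-corruption operator reproduces the
# standard annotation-error taxonomy (category flips, boundary shifts,
# missing annotations) for robustness experiments.

SYNTH_CATEGORIES <- c("Disease", "Symptoms", "Anatomy", "Examination",
                      "Instrument", "Medicine", "Operation")

#' Default per-category entity dictionaries
#'
#' Multi-character surface strings (2-6 characters) over the closed
#' synthetic character set.
#'
#' @return Named list of character vectors, one per category.
#' @export
synth_dictionaries <- function() {
  list(
    Disease = c("肺癌", "肝炎", "胃疡", "脑瘤",
                "肾炎", "骨癌", "肺胃炎",
                "肝脑瘤疸"),
    Symptoms = c("呕吐", "肿胀", "晕痛", "咳热",
                 "呕吐晕", "肿胀痛",
                 "咳痛热晕"),
    Anatomy = c("心肺", "肝胃", "脑骨", "手骨",
                "心肝肺", "胃肾", "肺肝胃肾"),
    Examination = c("查验", "电超", "影超", "检验",
                    "电影查", "检查",
                    "影电超验"),
    Instrument = c("针管", "刀镜", "仪器",
                   "镜仪器", "刀针管",
                   "仪器镜管"),
    Medicine = c("药素", "霉素", "胶片", "药液",
                 "霉素片", "胶液",
                 "霉胶素液"),
    Operation = c("切除", "缝术", "引流",
                  "切缝术", "除术", "引流术",
                  "缝引流术")
  )
}

SYNTH_CONNECTIVES <- c(
  "患", "者", "今", "日", "出", "现", "于",
  "部", "行", "后", "给", "予", "无", "明",
  "显", "好", "转", "及", "伴", "有"
)

#' The closed synthetic character set
#'
#' Every character that can occur in generated corpora (entity dictionary
#' characters plus connectives). All of them carry bundled codes and glyph
#' bitmaps.
#'
#' @return Character vector of single characters.
#' @export
synth_charset <- function() {
  sort(unique(c(unlist(strsplit(unlist(synth_dictionaries()), "")),
                SYNTH_CONNECTIVES)))
}

# published per-category entity shares of the self-annotated EMR benchmark
default_weights <- function() {
  counts <- bundled_entity_counts("self_annotated")
  w <- (counts$train + counts$test) / sum(counts$train + counts$test)
  stats::setNames(w, counts$category)[SYNTH_CATEGORIES]
}

#' Configuration of the synthetic corpus generator
#'
#' @param seed Integer seed (full determinism).
#' @param n_documents Number of documents (one sentence each).
#' @param categories Entity categories to emit.
#' @param weights Category sampling weights (non-negative, at least one
#'   positive); default: the published per-category entity shares of the
#'   self-annotated benchmark, renormalized over `categories`.
#' @param entities_per_doc Inclusive range of entity mentions per document.
#' @param connective_len Inclusive range of O-tagged connective run lengths.
#' @param split Train fraction of documents.
#' @param dictionaries Per-category surface-form dictionaries.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_documents = 200L,
                         categories = SYNTH_CATEGORIES, weights = NULL,
                         entities_per_doc = c(1L, 3L),
                         connective_len = c(2L, 5L), split = 0.7,
                         dictionaries = synth_dictionaries()) {
  missing_dict <- setdiff(categories, names(dictionaries))
  if (length(missing_dict) > 0) {
    abort(paste0("no dictionary for: ", paste(missing_dict, collapse = ", ")))
  }
  if (is.null(weights)) {
    w <- default_weights()
    w[is.na(w)] <- mean(w, na.rm = TRUE) # categories outside the benchmark set
    weights <- w[categories] / sum(w[categories])
  }
  weights <- stats::setNames(as.numeric(weights), categories)
  if (anyNA(weights) || any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with at least one positive")
  }
  if (any(vapply(dictionaries[categories], length, integer(1)) == 0)) {
    abort("empty dictionary")
  }
  structure(list(
    seed = as.integer(seed), n_documents = as.integer(n_documents),
    categories = categories, weights = weights / sum(weights),
    entities_per_doc = as.integer(entities_per_doc),
    connective_len = as.integer(connective_len), split = split,
    dictionaries = dictionaries[categories]
  ), class = "synth_config")
}

synth_one_doc <- function(config) {
  n_ent <- sample(config$entities_per_doc[1]:config$entities_per_doc[2], 1)
  conn <- function() {
    k <- sample(config$connective_len[1]:config$connective_len[2], 1)
    sample(SYNTH_CONNECTIVES, k, replace = TRUE)
  }
  chars <- conn(); tags <- rep("O", length(chars))
  for (e in seq_len(n_ent)) {
    cat <- sample(config$categories, 1, prob = config$weights)
    surf <- chars_of(sample(config$dictionaries[[cat]], 1))
    chars <- c(chars, surf)
    tags <- c(tags, paste0("B-", cat), rep(paste0("I-", cat), length(surf) - 1L))
    cc <- conn()
    chars <- c(chars, cc); tags <- c(tags, rep("O", length(cc)))
  }
  list(chars = chars, tags = tags)
}

#' Generate a synthetic BIO corpus
#'
#' Deterministic given `config$seed`: the same configuration always yields
#' byte-identical corpora. Every emitted entity's surface string comes from
#' its category dictionary, tags are BIO-consistent with the gold spans,
#' and the train fraction is respected to the rounding of one document.
#'
#' @param config A [synth_config()].
#' @return List with `train` and `test` corpus tibbles (documents
#'   renumbered within each split) and `spans`, the gold spans of both
#'   splits (columns `split`, `doc_id`, `start`, `end`, `category`).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  docs <- with_seed(config$seed, {
    lapply(seq_len(config$n_documents), function(i) synth_one_doc(config))
  })
  n_train <- round(config$n_documents * config$split)
  build <- function(ix) {
    purrr::imap_dfr(docs[ix], function(d, k) {
      tibble(doc_id = as.integer(k), pos = seq_along(d$chars),
             char = d$chars, tag = d$tags)
    })
  }
  train <- build(seq_len(n_train))
  test <- if (n_train < config$n_documents) {
    build((n_train + 1L):config$n_documents)
  } else {
    tibble(doc_id = integer(0), pos = integer(0), char = character(0), tag = character(0))
  }
  spans <- bind_rows(
    if (nrow(train) > 0) mutate(corpus_spans(train), split = "train"),
    if (nrow(test) > 0) mutate(corpus_spans(test), split = "test")
  )
  list(train = train, test = test, spans = spans)
}

#' Corrupt a fraction of gold spans (annotation-error simulator)
#'
#' Applies exactly `floor(rate * span count)` corruptions, each a category
#' flip, a boundary shift, or a deletion (mode drawn uniformly from
#' `modes`), mirroring the usual annotation-error taxonomy: inconsistent
#' category assignment, inconsistent boundaries, missing annotation.
#' Boundary shifts shrink the span start by one character (or extend the
#' end when the span is a single character and room exists; otherwise the
#' span is deleted).
#'
#' @param corpus Corpus tibble.
#' @param rate Corruption rate in `[0, 1]`.
#' @param modes Subset of `c("flip", "shift", "delete")`.
#' @param seed Integer seed.
#' @return List with `corpus` (corrupted) and `log` (one row per
#'   corruption: `doc_id`, `start`, `end`, `category`, `mode`,
#'   `new_start`, `new_end`, `new_category`).
#' @export
inject_noise <- function(corpus, rate, modes = c("flip", "shift", "delete"),
                         seed = 1L) {
  corpus <- validate_corpus(corpus)
  stopifnot(rate >= 0, rate <= 1)
  modes <- match.arg(modes, several.ok = TRUE)
  spans <- corpus_spans(corpus)
  n_corrupt <- floor(rate * nrow(spans))
  empty_log <- tibble(doc_id = integer(0), start = integer(0), end = integer(0),
                      category = character(0), mode = character(0),
                      new_start = integer(0), new_end = integer(0),
                      new_category = character(0))
  if (n_corrupt == 0) return(list(corpus = corpus, log = empty_log))
  all_cats <- unique(spans$category)
  res <- with_seed(seed, {
    pick <- sample.int(nrow(spans), n_corrupt)
    log_rows <- vector("list", n_corrupt)
    by_doc <- split(spans, spans$doc_id)
    changed <- lapply(by_doc, function(df) df)
    for (j in seq_along(pick)) {
      sp <- spans[pick[j], ]
      mode <- sample(modes, 1)
      did <- as.character(sp$doc_id)
      df <- changed[[did]]
      row <- which(df$start == sp$start & df$end == sp$end &
                     df$category == sp$category)[1]
      new_start <- NA_integer_; new_end <- NA_integer_; new_cat <- NA_character_
      doc_len <- sum(corpus$doc_id == sp$doc_id)
      if (mode == "flip" && length(all_cats) > 1) {
        new_cat <- sample(setdiff(all_cats, sp$category), 1)
        df$category[row] <- new_cat
        new_start <- sp$start; new_end <- sp$end
      } else if (mode == "shift") {
        if (sp$end - sp$start >= 2) {
          new_start <- sp$start + 1L; new_end <- sp$end
        } else if (sp$end < doc_len &&
                   !any(df$start == sp$end & seq_len(nrow(df)) != row)) {
          new_start <- sp$start; new_end <- sp$end + 1L
        }
        if (!is.na(new_start)) {
          df$start[row] <- new_start; df$end[row] <- new_end
          new_cat <- sp$category
        } else {
          mode <- "delete"
        }
      } else if (mode == "flip") {
        mode <- "delete" # single-category corpus: flip degenerates
      }
      if (mode == "delete") {
        df <- df[-row, ]
        new_start <- NA_integer_; new_end <- NA_integer_; new_cat <- NA_character_
      }
      changed[[did]] <- df
      log_rows[[j]] <- tibble(doc_id = sp$doc_id, start = sp$start,
                              end = sp$end, category = sp$category,
                              mode = mode, new_start = new_start,
                              new_end = new_end, new_category = new_cat)
    }
    list(changed = changed, log = bind_rows(log_rows))
  })
  out <- corpus |>
    group_by(.data$doc_id) |>
    group_modify(function(df, key) {
      sp <- res$changed[[as.character(key$doc_id)]]
      if (is.null(sp)) sp <- tibble(start = integer(0), end = integer(0),
                                    category = character(0))
      df$tag <- spans_to_tags(sp, nrow(df))
      df
    }) |>
    ungroup()
  list(corpus = out[, c("doc_id", "pos", "char", "tag")], log = res$log)
}
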