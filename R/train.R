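# Training loop (AdamW on the CRF negative log-likelihood), prediction and
# model-level evaluation.

zero_like <- function(p) {
  if (is.numeric(p)) return(p * 0)
  if (!is.list(p)) abort("non-numeric leaf in parameter tree")
  lapply(p, zero_like)
}

add_grads <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  for (nm in names(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
  a
}

scale_grads <- function(a, s) {
  if (is.numeric(a)) return(a * s)
  lapply(a, scale_grads, s = s)
}

adamw_init <- function(params) list(m = zero_like(params), v = zero_like(params), t = 0L)

adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.numeric(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      p <- p - lr * (mh / (sqrt(vh) + eps) + weight_decay * p)
      return(list(p = p, m = m, v = v))
    }
    out_p <- p; out_m <- m; out_v <- v
    for (nm in names(p)) {
      r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

effective_transitions <- function(model) {
  if (model$config$bio_constraints) {
    bio_constrain(model$params$trans, model$meta$tag_names)
  } else {
    model$params$trans
  }
}

lstm_cell <- function(p, model) {
  c(p, list(hidden = model$config$hidden, input_dim = model$meta$input_dim))
}

# Effective fusion weights: trainable softmax weights under dynamic fusion,
# or a fixed one-hot on the top backbone layer when it is disabled (the
# conventional "top layer only" use of a contextual encoder).
model_fusion_weights <- function(model) {
  if (!model$config$channels[["context"]]) return(NULL)
  if (model$config$dynamic_fusion) {
    structure(list(raw = model$params$fusion_raw), class = "fusion_weights")
  } else {
    L <- length(model$params$fusion_raw)
    c(numeric(L - 1L), 1)
  }
}

# docs: list of list(chars, y, n); stacks: per-doc layer stacks (or NULL).
# Returns loss (mean NLL per document) and, when compute_grads, gradients
# structured like model$params.
forward_backward_batch <- function(model, docs, stacks, training = TRUE,
                                   compute_grads = TRUE) {
  cfg <- model$config
  ch <- cfg$channels
  B <- length(docs)
  w_ctx <- unname(model$meta$widths["context"])
  has_char <- any(ch[CHANNEL_NAMES != "context"])
  uchars <- unique(unlist(lapply(docs, `[[`, "chars")))
  cf <- if (has_char) char_feature_matrix(model, uchars, keep_cache = compute_grads) else NULL
  fw <- model_fusion_weights(model)
  trans <- effective_transitions(model)
  Xs <- vector("list", B)
  ctx_caches <- vector("list", B)
  masksX <- vector("list", B)
  for (b in seq_len(B)) {
    d <- docs[[b]]
    parts <- NULL
    if (ch[["context"]]) {
      fr <- fusion_fwd_cache(stacks[[b]], fw, model$params$proj)
      ctx_caches[[b]] <- fr$cache
      parts <- fr$out
    }
    if (has_char) {
      feats <- cf$mat[match(d$chars, uchars), , drop = FALSE]
      parts <- if (is.null(parts)) feats else cbind(parts, feats)
    }
    if (training && cfg$dropout > 0) {
      m <- matrix((runif(length(parts)) >= cfg$dropout) / (1 - cfg$dropout),
                  nrow(parts), ncol(parts))
      masksX[[b]] <- m
      parts <- parts * m
    }
    Xs[[b]] <- parts
  }
  run <- bilstm_fwd_batch(Xs, lstm_cell(model$params$lstm_f, model),
                          lstm_cell(model$params$lstm_b, model))
  H <- run$H
  masksH <- vector("list", B)
  if (training && cfg$dropout > 0) {
    for (b in seq_len(B)) {
      m <- matrix((runif(length(H[[b]])) >= cfg$dropout) / (1 - cfg$dropout),
                  nrow(H[[b]]), ncol(H[[b]]))
      masksH[[b]] <- m
      H[[b]] <- H[[b]] * m
    }
  }
  We <- model$params$emit$W; be <- model$params$emit$b
  loss <- 0
  if (!compute_grads) {
    for (b in seq_len(B)) {
      E <- sweep(H[[b]] %*% t(We), 2, be, "+")
      loss <- loss + log_partition(E, trans) - sequence_score(E, trans, docs[[b]]$y)
    }
    return(list(loss = loss / B))
  }
  g <- zero_like(model$params)
  dH <- vector("list", B)
  for (b in seq_len(B)) {
    E <- sweep(H[[b]] %*% t(We), 2, be, "+")
    cg <- crf_nll_grad(E, trans, docs[[b]]$y)
    loss <- loss + cg$nll
    g$trans <- g$trans + cg$d_transitions
    g$emit$W <- g$emit$W + crossprod(cg$d_emissions, H[[b]])
    g$emit$b <- g$emit$b + colSums(cg$d_emissions)
    dHb <- cg$d_emissions %*% We
    if (!is.null(masksH[[b]])) dHb <- dHb * masksH[[b]]
    dH[[b]] <- dHb
  }
  back <- bilstm_bwd_batch(dH, run$cache, lstm_cell(model$params$lstm_f, model),
                           lstm_cell(model$params$lstm_b, model))
  g$lstm_f <- add_grads(g$lstm_f, back$grads_fwd)
  g$lstm_b <- add_grads(g$lstm_b, back$grads_bwd)
  dCharMat <- if (has_char) matrix(0, length(uchars), ncol(cf$mat)) else NULL
  for (b in seq_len(B)) {
    dX <- back$dX[[b]]
    if (!is.null(masksX[[b]])) dX <- dX * masksX[[b]]
    if (ch[["context"]]) {
      fb <- fusion_bwd(dX[, seq_len(w_ctx), drop = FALSE], ctx_caches[[b]])
      if (cfg$dynamic_fusion) g$fusion_raw <- g$fusion_raw + fb$draw
      g$proj$W <- g$proj$W + fb$dW
      g$proj$b <- g$proj$b + fb$db
    }
    if (has_char) {
      dFeat <- dX[, (w_ctx + 1):ncol(dX), drop = FALSE]
      idx <- match(docs[[b]]$chars, uchars)
      acc <- rowsum(dFeat, group = idx)
      rows <- as.integer(rownames(acc))
      dCharMat[rows, ] <- dCharMat[rows, , drop = FALSE] + acc
    }
  }
  if (has_char) {
    # column ranges of the char-feature matrix (context excluded)
    w <- model$meta$widths[setdiff(CHANNEL_NAMES, "context")]
    offs <- cumsum(c(0, w))
    rng <- stats::setNames(lapply(seq_along(w), function(i) {
      if (w[i] == 0) integer(0) else (offs[i] + 1):offs[i + 1]
    }), names(w))
    sc_cnn_dim <- model$meta$spec_code$dense_out
    cc <- cf$caches
    if (ch[["five_stroke"]]) {
      r <- code_cnn_bwd_batch(dCharMat[, rng$five_stroke, drop = FALSE], cc$fc,
                              cnn_obj(model$params$cnn_fc, model, "code", 26L))
      g$cnn_fc <- r$grads
    }
    if (ch[["zheng"]]) {
      r <- code_cnn_bwd_batch(dCharMat[, rng$zheng, drop = FALSE], cc$zc,
                              cnn_obj(model$params$cnn_zc, model, "code", 26L))
      g$cnn_zc <- r$grads
    }
    if (ch[["phonological"]]) {
      r <- code_cnn_bwd_batch(dCharMat[, rng$phonological, drop = FALSE], cc$pc,
                              cnn_obj(model$params$cnn_pc, model, "code",
                                      length(model$meta$pinyin_alpha)))
      g$cnn_pc <- r$grads
    }
    if (ch[["stroke"]]) {
      dsc <- dCharMat[, rng$stroke[seq_len(sc_cnn_dim)], drop = FALSE]
      r <- code_cnn_bwd_batch(dsc, cc$sc,
                              cnn_obj(model$params$cnn_sc, model, "stroke", 5L))
      g$cnn_sc <- r$grads
    }
    if (ch[["image"]]) {
      r <- image_cnn_bwd_batch(dCharMat[, rng$image, drop = FALSE], cc$img,
                               img_obj(model$params$cnn_img, model))
      g$cnn_img <- r$grads
    }
  }
  list(loss = loss / B, grads = scale_grads(g, 1 / B))
}

corpus_to_docs <- function(corpus, tag_names, max_len) {
  corpus <- validate_corpus(corpus)
  if (nrow(corpus) == 0) abort("corpus is empty")
  corpus <- chunk_documents(corpus, max_len)
  key <- paste(corpus$doc_id, corpus$chunk, sep = ".")
  split_idx <- split(seq_len(nrow(corpus)), factor(key, levels = unique(key)))
  lapply(split_idx, function(ix) {
    df <- corpus[ix, ]
    df <- df[order(df$pos), ]
    y <- match(df$tag, tag_names)
    if (anyNA(y)) {
      abort(sprintf("tag %s outside the model's schema (%s)",
                    dQuote(df$tag[which(is.na(y))[1]]),
                    paste(tag_names, collapse = " ")))
    }
    list(chars = df$char, y = y, n = nrow(df),
         doc_id = df$doc_id[1], chunk = df$chunk[1])
  })
}

doc_stacks <- function(model, docs) {
  if (!model$config$channels[["context"]]) return(vector("list", length(docs)))
  lapply(docs, function(d) backbone_encode(d$chars, model$backbone))
}

#' Fit the multisemantic NER model
#'
#' Trains every parameter group (dynamic-fusion weights and projection, the
#' four code extractors, the image extractor, BiLSTM, emission projection
#' and CRF transitions; the backbone itself stays frozen) by AdamW on the
#' CRF negative log-likelihood. Dropout is applied to the concatenated
#' BiLSTM input and to the hidden states before emission projection.
#' Deterministic given `config$seed`. Documents longer than
#' `config$max_len` are chunked at entity-safe boundaries first.
#'
#' @param corpus Training corpus tibble (`doc_id`, `pos`, `char`, `tag`).
#' @param config A [ner_config()].
#' @param categories Entity categories; default: those present in `corpus`.
#' @param code_table,bitmaps Feature resources (bundled defaults).
#' @param dev_corpus Optional held-out corpus: enables per-epoch dev loss /
#'   micro-F1 logging and early stopping with `config$patience`.
#' @param verbose Print one line per epoch.
#' @return A fitted `ner_model`; `$log` holds the `ner_training_log` tibble
#'   (epoch, loss, dev_loss, dev_f1, train_f1 where computed).
#' @export
ner_fit <- function(corpus, config = ner_config("desk"), categories = NULL,
                    code_table = bundled_code_table(),
                    bitmaps = bundled_glyph_bitmaps(),
                    dev_corpus = NULL, verbose = FALSE) {
  corpus <- validate_corpus(corpus)
  if (nrow(corpus) == 0) abort("corpus is empty")
  if (is.null(categories)) {
    categories <- unique(sub("^[BI]-", "", grep("^[BI]-", corpus$tag, value = TRUE)))
    if (length(categories) == 0) abort("corpus has no entity tags; supply `categories`")
  }
  model <- ner_model(config, categories, code_table, bitmaps)
  docs <- corpus_to_docs(corpus, model$meta$tag_names, config$max_len)
  dev_docs <- if (!is.null(dev_corpus)) {
    corpus_to_docs(dev_corpus, model$meta$tag_names, config$max_len)
  } else NULL
  set.seed(config$seed)
  stacks <- doc_stacks(model, docs)
  dev_stacks <- if (!is.null(dev_docs)) doc_stacks(model, dev_docs) else NULL
  opt <- adamw_init(model$params)
  log_rows <- list()
  best_dev <- Inf; wait <- 0L
  n_docs <- length(docs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_docs)
    ep_loss <- 0; n_batch <- 0L
    for (s in seq(1, n_docs, by = config$batch_size)) {
      ix <- ord[s:min(s + config$batch_size - 1L, n_docs)]
      fb <- forward_backward_batch(model, docs[ix], stacks[ix], training = TRUE)
      step <- adamw_step(model$params, fb$grads, opt, config$learning_rate,
                         config$weight_decay)
      model$params <- step$params
      opt <- step$state
      ep_loss <- ep_loss + fb$loss; n_batch <- n_batch + 1L
    }
    row <- tibble(epoch = epoch, loss = ep_loss / n_batch,
                  dev_loss = NA_real_, dev_f1 = NA_real_, train_f1 = NA_real_)
    if (!is.null(dev_docs)) {
      row$dev_loss <- forward_backward_batch(model, dev_docs, dev_stacks,
                                             training = FALSE,
                                             compute_grads = FALSE)$loss
      row$dev_f1 <- micro_f1_docs(model, dev_docs, dev_stacks)
    }
    stop_now <- FALSE
    if (!is.null(config$f1_target) && epoch %% config$f1_every == 0L) {
      row$train_f1 <- micro_f1_docs(model, docs, stacks)
      if (row$train_f1 >= config$f1_target) stop_now <- TRUE
    }
    log_rows[[epoch]] <- row
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f%s%s\n", epoch, row$loss,
                  if (!is.na(row$dev_f1)) sprintf("  dev_f1 %.4f", row$dev_f1) else "",
                  if (!is.na(row$train_f1)) sprintf("  train_f1 %.4f", row$train_f1) else ""))
    }
    if (!is.null(dev_docs)) {
      if (row$dev_loss < best_dev - 1e-6) {
        best_dev <- row$dev_loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) stop_now <- TRUE
      }
    }
    if (stop_now) break
  }
  model$log <- structure(bind_rows(log_rows), class = c("ner_training_log", class(tibble())))
  model$fitted <- TRUE
  model
}

decode_docs <- function(model, docs, stacks) {
  trans <- effective_transitions(model)
  ch <- model$config$channels
  has_char <- any(ch[CHANNEL_NAMES != "context"])
  uchars <- unique(unlist(lapply(docs, `[[`, "chars")))
  cf <- if (has_char) char_feature_matrix(model, uchars) else NULL
  fw <- model_fusion_weights(model)
  Xs <- lapply(seq_along(docs), function(b) {
    parts <- NULL
    if (ch[["context"]]) parts <- fusion_fwd_cache(stacks[[b]], fw, model$params$proj)$out
    if (has_char) {
      feats <- cf$mat[match(docs[[b]]$chars, uchars), , drop = FALSE]
      parts <- if (is.null(parts)) feats else cbind(parts, feats)
    }
    parts
  })
  run <- bilstm_fwd_batch(Xs, lstm_cell(model$params$lstm_f, model),
                          lstm_cell(model$params$lstm_b, model))
  lapply(seq_along(docs), function(b) {
    E <- sweep(run$H[[b]] %*% t(model$params$emit$W), 2, model$params$emit$b, "+")
    viterbi_decode(E, trans)$tags
  })
}

micro_f1_docs <- function(model, docs, stacks) {
  pred_tags <- decode_docs(model, docs, stacks)
  gold <- list(); pred <- list()
  for (b in seq_along(docs)) {
    gold[[b]] <- extract_entities(model$meta$tag_names[docs[[b]]$y]) |>
      mutate(doc_id = b)
    pred[[b]] <- extract_entities(model$meta$tag_names[pred_tags[[b]]]) |>
      mutate(doc_id = b)
  }
  rep <- evaluate_ner(bind_rows(gold), bind_rows(pred))
  rep$f1[rep$category == "All"]
}

#' Predict BIO tags for new text
#'
#' @param object A fitted [ner_fit()] model.
#' @param newdata A corpus tibble (`doc_id`, `pos`, `char`; a `tag` column
#'   is ignored for prediction) or a character vector of document strings.
#' @param ... Unused.
#' @return Corpus tibble with a `pred_tag` column of Viterbi-decoded tags.
#' @export
predict.ner_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    newdata <- purrr::imap_dfr(newdata, function(s, i) {
      ch <- chars_of(s)
      tibble(doc_id = i, pos = seq_along(ch), char = ch, tag = "O")
    })
  }
  corpus <- as_tibble(newdata)
  if (!"tag" %in% names(corpus)) corpus$tag <- "O"
  docs <- corpus_to_docs(corpus, object$meta$tag_names, object$config$max_len)
  stacks <- doc_stacks(object, docs)
  tags <- decode_docs(object, docs, stacks)
  out <- purrr::imap_dfr(docs, function(d, k) {
    tibble(doc_id = d$doc_id, chunk = d$chunk, pos = seq_len(d$n),
           char = d$chars, pred_tag = object$meta$tag_names[tags[[as.integer(k)]]])
  })
  # restore original in-document positions (chunks are consecutive)
  out |>
    group_by(.data$doc_id) |>
    mutate(pos = dplyr::row_number()) |>
    ungroup() |>
    select("doc_id", "pos", "char", "pred_tag")
}

#' Evaluate a fitted model on a tagged corpus
#'
#' Predicts tags for `corpus` and scores them against its gold tags with
#' entity-level exact matching.
#'
#' @param corpus Gold-tagged corpus tibble.
#' @param model A fitted `ner_model`.
#' @return A `ner_eval_report`.
#' @export
ner_evaluate <- function(corpus, model) {
  corpus <- validate_corpus(corpus)
  pred <- predict(model, corpus)
  pred$tag <- pred$pred_tag
  evaluate_ner(corpus_spans(corpus), corpus_spans(pred))
}

# ---- broom-style methods -------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted NER model
#'
#' One row per learned CRF transition (including START/STOP boundaries),
#' plus the softmax-normalized fusion weight of every backbone layer.
#'
#' @param x A `ner_model`.
#' @param ... Unused.
#' @return Tibble with `component`, `from`, `to`, `estimate`.
#' @exportS3Method generics::tidy
tidy.ner_model <- function(x, ...) {
  tags <- c(x$meta$tag_names, "START", "STOP")
  Z <- effective_transitions(x)
  trans <- tidyr::expand_grid(from = tags, to = tags) |>
    mutate(component = "transition",
           estimate = as.vector(t(Z))[match(paste(.data$from, .data$to),
                                            paste(rep(tags, each = length(tags)),
                                                  rep(tags, length(tags))))])
  out <- trans[, c("component", "from", "to", "estimate")]
  if (x$config$channels[["context"]]) {
    a <- fusion_alpha(model_fusion_weights(x))
    out <- bind_rows(out, tibble(component = "fusion_weight",
                                 from = paste0("layer", seq_along(a)),
                                 to = NA_character_, estimate = a))
  }
  out
}

#' Glance at a fitted NER model
#'
#' @param x A `ner_model`.
#' @param ... Unused.
#' @return One-row tibble: parameter count, epochs run, final training
#'   loss, last dev loss/F1 (NA without a dev split), enabled channels.
#' @exportS3Method generics::glance
glance.ner_model <- function(x, ...) {
  lg <- x$log
  tibble(
    n_parameters = n_parameters(x),
    epochs = if (is.null(lg)) 0L else nrow(lg),
    final_loss = if (is.null(lg)) NA_real_ else lg$loss[nrow(lg)],
    dev_loss = if (is.null(lg)) NA_real_ else lg$dev_loss[nrow(lg)],
    dev_f1 = if (is.null(lg)) NA_real_ else lg$dev_f1[nrow(lg)],
    channels = paste(names(which(x$config$channels)), collapse = "+")
  )
}

#' @exportS3Method generics::tidy
tidy.ner_eval_report <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.ner_eval_report <- function(x, ...) {
  as_tibble(x) |> dplyr::filter(.data$category == "All") |>
    select("tp", "fp", "fn", "precision", "recall", "f1")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training log
#'
#' Training loss per epoch, with dev loss and dev micro-F1 overlaid when a
#' dev split was supplied.
#'
#' @param object A `ner_training_log` (the `$log` of a fitted model).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ner_training_log <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(cols = c("loss", "dev_loss", "dev_f1", "train_f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Per-category precision/recall/F1 bars (percent).
#'
#' @param object A `ner_eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ner_eval_report <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(cols = c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = 100 * .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}
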