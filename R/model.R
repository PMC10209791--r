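# End-to-end model: multisemantic featurization -> BiLSTM -> CRF.
#
# Per character, six feature channels are concatenated in fixed order
#   (context, five_stroke, zheng, phonological, stroke, image)
# into v_input, encoded by a bidirectional LSTM, projected to per-tag
# emission scores and decoded by the linear-chain CRF. Training minimizes
# the CRF negative log-likelihood with AdamW; the contextual backbone is
# frozen (its fusion weights and projection train), the feature extractors,
# BiLSTM, emission projection and transition matrix all train. Any channel
# can be ablated: disabled channels contribute a zero-width slice.

CHANNEL_NAMES <- c("context", "five_stroke", "zheng", "phonological",
                   "stroke", "image")

#' Training and model configuration
#'
#' The `"paper"` profile carries the reference hyperparameters (dropout 0.5,
#' AdamW, learning rate 1e-4, batch 32, BiLSTM hidden 768, max length 510,
#' contextual width 768, image feature 128). The `"desk"` profile is the
#' package's scaled-down configuration for from-scratch training on small
#' synthetic corpora (stand-in backbone of 2 layers x width 32, hidden 64,
#' projection 32, learning rate 1e-3, dropout 0.1, batch 16): a random-init
#' model this small needs a larger step size and less regularization than a
#' large pretrained backbone being fine-tuned.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param ... Overrides for any field of the profile.
#' @return A `ner_config` list.
#' @export
ner_config <- function(profile = c("paper", "desk"), ...) {
  profile <- match.arg(profile)
  base <- list(
    hidden = 768L, proj_dim = 768L,
    backbone = list(type = "standin", layers = 12L, width = 768L, seed = 1L),
    learning_rate = 1e-4, batch_size = 32L, dropout = 0.5, max_len = 510L,
    epochs = 50L, patience = 5L, weight_decay = 0.01, seed = 42L,
    channels = stats::setNames(rep(TRUE, 6L), CHANNEL_NAMES),
    dynamic_fusion = TRUE,
    stroke_counts = FALSE, bio_constraints = FALSE,
    code_max_len = 4L, stroke_max_len = 24L,
    f1_target = NULL, f1_every = 5L
  )
  if (profile == "desk") {
    base$hidden <- 64L; base$proj_dim <- 32L
    base$backbone <- list(type = "standin", layers = 2L, width = 32L, seed = 1L)
    base$learning_rate <- 1e-3; base$dropout <- 0.1; base$batch_size <- 16L
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(base))
  if (length(bad) > 0) abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  if (!is.null(dots$channels)) {
    ch <- stats::setNames(rep(TRUE, 6L), CHANNEL_NAMES)
    if (is.null(names(dots$channels))) abort("`channels` must be named")
    bad <- setdiff(names(dots$channels), CHANNEL_NAMES)
    if (length(bad) > 0) abort(paste0("unknown channel(s): ", paste(bad, collapse = ", ")))
    ch[names(dots$channels)] <- dots$channels
    base$channels <- ch
  }
  stopifnot(base$learning_rate > 0, base$batch_size >= 1, base$dropout >= 0,
            base$dropout < 1, base$max_len >= 1, base$hidden >= 1)
  structure(base, class = "ner_config")
}

#' Concatenate per-position feature channels
#'
#' Channels are bound column-wise in the fixed order context, five_stroke,
#' zheng, phonological, stroke, image; a `NULL` channel (ablated)
#' contributes a zero-width slice. All supplied channels must agree on the
#' number of positions.
#'
#' @param context,five_stroke,zheng,phonological,stroke,image `n x w`
#'   matrices (or `NULL`).
#' @return `n x sum(w)` matrix with a `channel_offsets` attribute naming
#'   each slice's column range.
#' @export
concat_features <- function(context = NULL, five_stroke = NULL, zheng = NULL,
                            phonological = NULL, stroke = NULL, image = NULL) {
  chans <- list(context = context, five_stroke = five_stroke, zheng = zheng,
                phonological = phonological, stroke = stroke, image = image)
  chans <- chans[!vapply(chans, is.null, logical(1))]
  if (length(chans) == 0) abort("all channels are NULL")
  ns <- vapply(chans, nrow, integer(1))
  if (length(unique(ns)) != 1) abort("channels disagree on the number of positions")
  out <- do.call(cbind, chans)
  offs <- cumsum(c(0, vapply(chans, ncol, integer(1))))
  attr(out, "channel_offsets") <-
    stats::setNames(lapply(seq_along(chans), function(i) (offs[i] + 1):offs[i + 1]),
                    names(chans))
  out
}

tag_vocabulary <- function(categories) {
  categories <- sort(unique(categories))
  c("O", as.vector(rbind(paste0("B-", categories), paste0("I-", categories))))
}

#' Initialize an untrained NER model
#'
#' @param config A [ner_config()].
#' @param categories Entity categories the tag vocabulary covers.
#' @param code_table A [code_table()]; default the bundled table.
#' @param bitmaps Glyph bitmaps; default the bundled synthetic archive.
#' @return A `ner_model` object (parameters, frozen backbone, caches).
#' @export
ner_model <- function(config, categories, code_table = bundled_code_table(),
                      bitmaps = bundled_glyph_bitmaps()) {
  stopifnot(inherits(config, "ner_config"), length(categories) >= 1)
  tag_names <- tag_vocabulary(categories)
  K <- length(tag_names)
  ch <- config$channels
  spec_code <- conv_stack_spec("code")
  spec_img <- conv_stack_spec("image")
  bk <- config$backbone
  backbone <- standin_backbone(bk$layers, bk$width, bk$seed, config$max_len)
  seed <- config$seed
  params <- list()
  meta <- list(tag_names = tag_names, categories = sort(unique(categories)),
               spec_code = spec_code, spec_img = spec_img,
               pinyin_alpha = pinyin_alphabet())
  if (ch[["context"]]) {
    params$fusion_raw <- numeric(bk$layers)
    params$proj <- with_seed(seed + 1, list(
      W = init_mat(config$proj_dim, bk$width, fan_in = bk$width),
      b = numeric(config$proj_dim)
    ))
  }
  wfields <- c("W1", "b1", "W2", "b2", "Wd", "bd") # numeric leaves only
  if (ch[["five_stroke"]]) {
    params$cnn_fc <- code_cnn_init(26L, config$code_max_len, spec_code, seed + 2)[wfields]
  }
  if (ch[["zheng"]]) {
    params$cnn_zc <- code_cnn_init(26L, config$code_max_len, spec_code, seed + 3)[wfields]
  }
  if (ch[["phonological"]]) {
    params$cnn_pc <- code_cnn_init(length(meta$pinyin_alpha),
                                   config$code_max_len, spec_code, seed + 4)[wfields]
  }
  if (ch[["stroke"]]) {
    params$cnn_sc <- code_cnn_init(5L, config$stroke_max_len, spec_code, seed + 5)[wfields]
  }
  if (ch[["image"]]) {
    params$cnn_img <- image_cnn_init(GLYPH_SIZE, spec_img, seed + 6)[wfields]
  }
  widths <- c(
    context = if (ch[["context"]]) config$proj_dim else 0L,
    five_stroke = if (ch[["five_stroke"]]) spec_code$dense_out else 0L,
    zheng = if (ch[["zheng"]]) spec_code$dense_out else 0L,
    phonological = if (ch[["phonological"]]) spec_code$dense_out else 0L,
    stroke = if (ch[["stroke"]]) spec_code$dense_out + if (config$stroke_counts) 5L else 0L else 0L,
    image = if (ch[["image"]]) spec_img$dense_out else 0L
  )
  D <- sum(widths)
  if (D == 0L) abort("all feature channels are disabled")
  params$lstm_f <- lstm_init(D, config$hidden, seed + 7)[c("Wx", "Wh", "b")]
  params$lstm_b <- lstm_init(D, config$hidden, seed + 8)[c("Wx", "Wh", "b")]
  params$emit <- with_seed(seed + 9, list(
    W = init_mat(K, 2L * config$hidden, fan_in = 2L * config$hidden),
    b = numeric(K)
  ))
  params$trans <- matrix(0, K + 2L, K + 2L)
  meta$widths <- widths
  meta$input_dim <- D
  structure(list(
    config = config, params = params, meta = meta, backbone = backbone,
    code_table = code_table, bitmaps = bitmaps,
    char_cache = new.env(parent = emptyenv()),
    log = NULL, fitted = FALSE
  ), class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  on_ch <- names(which(x$config$channels))
  cat(sprintf("<ner_model> %d tags (%s)\n", length(x$meta$tag_names),
              paste(x$meta$categories, collapse = ", ")))
  cat(sprintf("  channels: %s | input %d -> BiLSTM hidden %d -> CRF\n",
              paste(on_ch, collapse = "+"), x$meta$input_dim, x$config$hidden))
  cat(sprintf("  %s | %d trainable parameters\n",
              if (x$fitted) "fitted" else "untrained", n_parameters(x)))
  invisible(x)
}

n_parameters <- function(model) {
  cnt <- 0L
  walk_leaves <- function(p) {
    if (is.numeric(p)) cnt <<- cnt + length(p)
    else if (is.list(p)) for (q in p) walk_leaves(q)
  }
  walk_leaves(model$params)
  cnt
}

# --- per-character raw inputs (one-hots + glyph), cached ------------------

char_inputs <- function(model, char) {
  cache <- model$char_cache
  if (!is.null(cache[[char]])) return(cache[[char]])
  rec <- lookup_codes(model$code_table, char)
  cml <- model$config$code_max_len
  fc <- if (nzchar(rec$five_stroke)) one_hot_encode(rec$five_stroke, letters, cml) else
    matrix(0, cml, 26L)
  zc <- if (nzchar(rec$zheng)) one_hot_encode(rec$zheng, letters, cml) else
    matrix(0, cml, 26L)
  psym <- if (nzchar(rec$phonological)) pinyin_symbols(rec$phonological) else character(0)
  pc <- one_hot_encode(psym, model$meta$pinyin_alpha, cml)
  sml <- model$config$stroke_max_len
  sc <- one_hot_encode(rec$stroke_seq, as.character(1:5), sml)
  counts <- stroke_count_vector(rec$stroke_seq)
  glyph <- if (!is.null(model$bitmaps[[char]])) model$bitmaps[[char]]$pixels else
    matrix(0, GLYPH_SIZE, GLYPH_SIZE)
  out <- list(fc = fc, zc = zc, pc = pc, sc = sc, counts = counts, glyph = glyph)
  cache[[char]] <- out
  out
}

# Feature matrix for a set of unique characters. All characters run through
# each extractor as one stacked batch; `caches` holds one batched forward
# cache per channel for backprop. Returns uchar x width matrix + caches.
char_feature_matrix <- function(model, uchars, keep_cache = FALSE) {
  ch <- model$config$channels
  p <- model$params
  N <- length(uchars)
  inputs <- lapply(uchars, function(u) char_inputs(model, u))
  parts <- list()
  caches <- list()
  run_code <- function(field, obj) {
    X <- do.call(rbind, lapply(inputs, `[[`, field))
    code_cnn_fwd_batch(X, obj)
  }
  if (ch[["five_stroke"]]) {
    r <- run_code("fc", cnn_obj(p$cnn_fc, model, "code", 26L))
    parts$five_stroke <- r$out; caches$fc <- r$cache
  }
  if (ch[["zheng"]]) {
    r <- run_code("zc", cnn_obj(p$cnn_zc, model, "code", 26L))
    parts$zheng <- r$out; caches$zc <- r$cache
  }
  if (ch[["phonological"]]) {
    r <- run_code("pc", cnn_obj(p$cnn_pc, model, "code",
                                length(model$meta$pinyin_alpha)))
    parts$phonological <- r$out; caches$pc <- r$cache
  }
  if (ch[["stroke"]]) {
    r <- run_code("sc", cnn_obj(p$cnn_sc, model, "stroke", 5L))
    out <- r$out
    if (model$config$stroke_counts) {
      out <- cbind(out, do.call(rbind, lapply(inputs, `[[`, "counts")))
    }
    parts$stroke <- out; caches$sc <- r$cache
  }
  if (ch[["image"]]) {
    X <- matrix(unlist(lapply(inputs, function(i) as.vector(i$glyph))), ncol = 1L)
    r <- image_cnn_fwd_batch(X, img_obj(p$cnn_img, model))
    parts$image <- r$out; caches$img <- r$cache
  }
  list(mat = do.call(cbind, unname(parts)),
       caches = if (keep_cache) caches else NULL)
}

cnn_obj <- function(p, model, kind, in_channels) {
  in_len <- if (kind == "stroke") model$config$stroke_max_len else model$config$code_max_len
  structure(c(p, list(spec = model$meta$spec_code, in_len = in_len,
                      in_channels = in_channels)),
            class = "code_cnn_params")
}

img_obj <- function(p, model) {
  structure(c(p, list(spec = model$meta$spec_img, in_size = GLYPH_SIZE)),
            class = "image_cnn_params")
}
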