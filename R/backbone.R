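# Contextual encoder: pluggable transformer backbone + dynamic layer fusion.
#
# The per-character contextual channel weights the representation emitted by
# every transformer layer of the backbone with a learned non-negative weight
# vector (softmax-normalized, so the weights sum to 1), sums the layers per
# position, and projects the sum with a dense map. Rather than using only
# the top layer, low/middle/high layers (surface, syntactic, semantic
# information) all contribute.
#
# The backbone itself is external and frozen here. Two handles exist:
#   * standin_backbone() — a small deterministic random-weight encoder used
#     by all tests and offline runs; per-character embeddings are seeded from
#     the codepoint, and each layer mixes every position with its neighbors
#     through a tanh map, so representations are context-dependent.
#   * a user-supplied encoder function (e.g. an adapter over a pretrained
#     whole-word-masking model) with the same signature; never required.

#' Create the stand-in contextual backbone
#'
#' Deterministic given `(layers, width, seed)`: weights are drawn once under
#' the seed, and character embeddings are derived from codepoints, so the
#' same text always encodes to the same layer stack.
#'
#' @param layers Number of transformer-like layers (default 12).
#' @param width Representation width per position (default 768).
#' @param seed Integer seed.
#' @param max_len Longest admissible input (default 510 characters).
#' @return A `standin_backbone` handle usable with [backbone_encode()].
#' @export
standin_backbone <- function(layers = 12L, width = 768L, seed = 0L,
                             max_len = 510L) {
  stopifnot(layers >= 1, width >= 1)
  mats <- with_seed(seed, {
    lapply(seq_len(layers), function(c) {
      list(
        A = matrix(rnorm(width * width, sd = 1 / sqrt(width)), width, width),
        B = matrix(rnorm(width * width, sd = 0.5 / sqrt(width)), width, width),
        C = matrix(rnorm(width * width, sd = 0.5 / sqrt(width)), width, width),
        b = rnorm(width, sd = 0.1)
      )
    })
  })
  structure(list(layers = as.integer(layers), width = as.integer(width),
                 seed = as.integer(seed), max_len = as.integer(max_len),
                 mats = mats),
            class = "standin_backbone")
}

#' @export
print.standin_backbone <- function(x, ...) {
  cat(sprintf("<standin_backbone> %d layers, width %d, seed %d\n",
              x$layers, x$width, x$seed))
  invisible(x)
}

standin_embed <- function(chars, width, seed) {
  E <- matrix(0, length(chars), width)
  for (i in seq_along(chars)) {
    cp <- utf8ToInt(chars[i])
    E[i, ] <- with_seed((seed * 1000003 + cp) %% 2147483647, rnorm(width))
  }
  E / sqrt(width)
}

#' Encode text into a per-layer representation stack
#'
#' @param text A single string or a character vector of single characters;
#'   must be non-empty and at most `max_len` characters.
#' @param backbone A [standin_backbone()] or a function
#'   `function(chars) -> list of n x width matrices` wrapping an external
#'   pretrained model (its adapter must return character-aligned rows).
#' @return A `layer_stack`: list of `layers` matrices, each `n x width`, one
#'   row per input character.
#' @export
backbone_encode <- function(text, backbone) {
  chars <- if (length(text) == 1L) chars_of(text) else as.character(text)
  if (length(chars) == 0L) abort("cannot encode an empty character sequence")
  if (is.function(backbone)) {
    stack <- backbone(chars)
  } else {
    stopifnot(inherits(backbone, "standin_backbone"))
    if (length(chars) > backbone$max_len) {
      abort(sprintf("sequence of %d characters exceeds max_len = %d",
                    length(chars), backbone$max_len))
    }
    h <- standin_embed(chars, backbone$width, backbone$seed)
    stack <- vector("list", backbone$layers)
    for (c in seq_len(backbone$layers)) {
      m <- backbone$mats[[c]]
      h <- tanh(h %*% m$A + shift_rows(h, 1) %*% m$B +
                  shift_rows(h, -1) %*% m$C +
                  matrix(m$b, nrow(h), length(m$b), byrow = TRUE))
      stack[[c]] <- h
    }
  }
  dims <- vapply(stack, dim, integer(2))
  if (any(dims[1, ] != length(chars)) || any(dims[2, ] != dims[2, 1])) {
    abort("backbone returned layers with inconsistent shapes")
  }
  structure(stack, class = "layer_stack", chars = chars)
}

#' Trainable fusion weights over backbone layers
#'
#' Stored unconstrained; [dynamic_fusion()] softmax-normalizes them each
#' forward pass, so the effective weights are non-negative and sum to 1.
#' The initial raw value 0 for every layer gives uniform effective weights.
#'
#' @param layers Number of layers, or a numeric vector of raw weights.
#' @return A `fusion_weights` object.
#' @export
fusion_weights <- function(layers) {
  raw <- if (length(layers) == 1L && is.numeric(layers) && layers >= 1 &&
             layers == as.integer(layers)) {
    numeric(as.integer(layers))
  } else {
    as.numeric(layers)
  }
  structure(list(raw = raw), class = "fusion_weights")
}

#' Effective (normalized) fusion weights
#'
#' @param weights A [fusion_weights()] object or a plain numeric vector
#'   (returned unchanged).
#' @return Non-negative numeric vector summing to 1 (for `fusion_weights`).
#' @export
fusion_alpha <- function(weights) {
  if (inherits(weights, "fusion_weights")) softmax(weights$raw) else as.numeric(weights)
}

#' Fuse a layer stack into per-position contextual vectors
#'
#' Per position `i`, the output is `projection(sum_c alpha_c * h_c(i))`:
#' a learned convex combination of every layer's representation, then a
#' dense projection. A one-hot `alpha` with an identity projection returns
#' the selected layer verbatim; a uniform `alpha` returns the per-position
#' layer mean.
#'
#' @param stack A `layer_stack` from [backbone_encode()].
#' @param weights A [fusion_weights()] object (softmax-normalized) or a
#'   plain numeric weight vector used as-is; length must equal the number
#'   of layers.
#' @param projection `NULL` for the identity, or a list `list(W, b)` with
#'   `W` a `d_out x width` matrix and `b` a length-`d_out` vector.
#' @return Matrix `n x d_out` of fused contextual vectors.
#' @export
dynamic_fusion <- function(stack, weights, projection = NULL) {
  fusion_fwd_cache(stack, weights, projection)$out
}

fusion_fwd_cache <- function(stack, weights, projection = NULL) {
  stopifnot(inherits(stack, "layer_stack") || is.list(stack))
  alpha <- fusion_alpha(weights)
  L <- length(stack)
  if (length(alpha) != L) {
    abort(sprintf("%d fusion weights for %d layers", length(alpha), L))
  }
  S <- alpha[1] * stack[[1]]
  if (L > 1) for (c in 2:L) S <- S + alpha[c] * stack[[c]]
  out <- if (is.null(projection)) S else {
    sweep(S %*% t(projection$W), 2, projection$b, "+")
  }
  list(out = out, cache = list(stack = stack, alpha = alpha, S = S,
                               weights = weights, projection = projection))
}

# Backward pass: gradients for the raw fusion weights (through softmax when
# `weights` is a fusion_weights object) and the projection; the backbone is
# frozen, so no gradient flows into the stack.
fusion_bwd <- function(dout, cache) {
  prj <- cache$projection
  if (is.null(prj)) {
    dS <- dout
    dW <- NULL; db <- NULL
  } else {
    dS <- dout %*% prj$W
    dW <- crossprod(dout, cache$S)
    db <- colSums(dout)
  }
  L <- length(cache$stack)
  dalpha <- vapply(seq_len(L), function(c) sum(dS * cache$stack[[c]]), numeric(1))
  draw <- if (inherits(cache$weights, "fusion_weights")) {
    a <- cache$alpha
    a * (dalpha - sum(dalpha * a)) # softmax Jacobian
  } else {
    dalpha
  }
  list(draw = draw, dW = dW, db = db)
}
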