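# Trainable convolutional feature extractors.
#
# Two stacks, both "two convolutions, kernel 3, rectifier, each followed by
# window-2 max pooling, then a dense layer":
#   * code stack (1D): runs along the positions of a one-hot code matrix with
#     the alphabet as input channels; 32 channels per convolution; dense
#     output 32. Produces the per-character code vectors (5-stroke, Zheng,
#     phonological, stroke channels).
#   * image stack (2D): runs over the 14x14 glyph raster; 8 then 32 channels;
#     dense output 128. Spatial sizes 14 -> 7 -> 3 (odd lengths floor).
# Convolutions use "same" zero padding so pooling never empties the grid.

#' Describe a convolutional feature-extractor stack
#'
#' @param kind `"code"` (1D over code positions, 32-dim output) or `"image"`
#'   (2D over the glyph raster, 128-dim output).
#' @return A `conv_stack_spec`: kernel size, per-layer channels, pooling
#'   window and dense output width.
#' @export
conv_stack_spec <- function(kind = c("code", "image")) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    code = list(kind = "code", kernel = 3L, channels = c(32L, 32L),
                pool = 2L, dense_out = 32L),
    image = list(kind = "image", kernel = 3L, channels = c(8L, 32L),
                 pool = 2L, dense_out = 128L)
  )
  structure(spec, class = "conv_stack_spec")
}

#' @export
print.conv_stack_spec <- function(x, ...) {
  cat(sprintf("<conv_stack_spec> %s: conv(k=%d, ch=%d) relu pool(%d) conv(k=%d, ch=%d) relu pool(%d) dense(%d)\n",
              x$kind, x$kernel, x$channels[1], x$pool,
              x$kernel, x$channels[2], x$pool, x$dense_out))
  invisible(x)
}

#' Initialize parameters of a code (1D) feature extractor
#'
#' @param alphabet_size Number of input channels (symbols of the code
#'   alphabet).
#' @param max_len Number of code positions (rows of the one-hot matrix).
#' @param spec A `"code"` [conv_stack_spec()].
#' @param seed Integer seed for the fan-in-scaled uniform initialization.
#' @return Parameter list (weights, biases, shapes), class `code_cnn_params`.
#' @export
code_cnn_init <- function(alphabet_size, max_len, spec = conv_stack_spec("code"),
                          seed = 0L) {
  stopifnot(inherits(spec, "conv_stack_spec"), spec$kind == "code")
  L2 <- max_len %/% 2L
  L4 <- L2 %/% 2L
  if (L4 < 1L) abort(sprintf("max_len = %d leaves no positions after two window-2 poolings", max_len))
  ch <- spec$channels
  with_seed(seed, {
    structure(list(
      spec = spec, in_len = as.integer(max_len), in_channels = as.integer(alphabet_size),
      W1 = init_mat(3L * alphabet_size, ch[1], fan_in = 3L * alphabet_size),
      b1 = numeric(ch[1]),
      W2 = init_mat(3L * ch[1], ch[2], fan_in = 3L * ch[1]),
      b2 = numeric(ch[2]),
      Wd = init_mat(spec$dense_out, L4 * ch[2], fan_in = L4 * ch[2]),
      bd = numeric(spec$dense_out)
    ), class = "code_cnn_params")
  })
}

# Batched forward over N stacked one-hot blocks: X ((N*L) x alphabet).
code_cnn_fwd_batch <- function(X, params) {
  L <- params$in_len
  if (nrow(X) %% L != 0 || ncol(X) != params$in_channels) {
    abort(sprintf("one-hot batch %dx%d does not match extractor input %dx%d",
                  nrow(X), ncol(X), L, params$in_channels))
  }
  c1 <- conv1d_fwd(X, params$W1, params$b1, L)
  r1 <- relu_fwd(c1$out)
  p1 <- pool1d_fwd(r1$out, L)
  L2 <- L %/% 2L
  c2 <- conv1d_fwd(p1$out, params$W2, params$b2, L2)
  r2 <- relu_fwd(c2$out)
  p2 <- pool1d_fwd(r2$out, L2)
  d <- dense_fwd(p2$out, params$Wd, params$bd, L2 %/% 2L)
  list(out = d$out, cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
                                 p2 = p2, d = d))
}

# dout: N x dense_out. Returns weight grads and the input gradient.
code_cnn_bwd_batch <- function(dout, cache, params) {
  dd <- dense_bwd(dout, cache$d$cache)
  dr2 <- pool1d_bwd(dd$dX, cache$p2$cache)
  dc2 <- relu_bwd(dr2, cache$r2$cache)
  g2 <- conv1d_bwd(dc2, cache$c2$cache)
  dr1 <- pool1d_bwd(g2$dX, cache$p1$cache)
  dc1 <- relu_bwd(dr1, cache$r1$cache)
  g1 <- conv1d_bwd(dc1, cache$c1$cache)
  list(grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                    Wd = dd$dW, bd = dd$db),
       dX = g1$dX)
}

code_cnn_fwd_cache <- function(one_hot, params) {
  X <- as.matrix(one_hot)
  if (nrow(X) != params$in_len) {
    abort(sprintf("one-hot shape %dx%d does not match extractor input %dx%d",
                  nrow(X), ncol(X), params$in_len, params$in_channels))
  }
  r <- code_cnn_fwd_batch(X, params)
  list(out = as.vector(r$out), cache = r$cache)
}

#' Forward pass of the code (1D) feature extractor
#'
#' Deterministic given fixed parameters; an all-zero one-hot input (the UNK
#' code) yields the bias-determined constant vector.
#'
#' @param one_hot Binary matrix from [one_hot_encode()] with the shape the
#'   parameters were initialized for.
#' @param params From [code_cnn_init()].
#' @return Numeric feature vector of length `params$spec$dense_out` (32).
#' @export
code_cnn_forward <- function(one_hot, params) {
  code_cnn_fwd_cache(one_hot, params)$out
}

#' Initialize parameters of the image (2D) feature extractor
#'
#' @param size Glyph side length (default 14).
#' @param spec An `"image"` [conv_stack_spec()].
#' @param seed Integer seed.
#' @return Parameter list, class `image_cnn_params`.
#' @export
image_cnn_init <- function(size = GLYPH_SIZE, spec = conv_stack_spec("image"),
                           seed = 0L) {
  stopifnot(inherits(spec, "conv_stack_spec"), spec$kind == "image")
  s2 <- size %/% 2L
  s4 <- s2 %/% 2L
  if (s4 < 1L) abort("glyph too small for two window-2 poolings")
  ch <- spec$channels
  with_seed(seed, {
    structure(list(
      spec = spec, in_size = as.integer(size),
      W1 = init_mat(9L, ch[1], fan_in = 9L),
      b1 = numeric(ch[1]),
      W2 = init_mat(9L * ch[1], ch[2], fan_in = 9L * ch[1]),
      b2 = numeric(ch[2]),
      Wd = init_mat(spec$dense_out, s4 * s4 * ch[2], fan_in = s4 * s4 * ch[2]),
      bd = numeric(spec$dense_out)
    ), class = "image_cnn_params")
  })
}

# Batched forward over N stacked glyphs: X ((N*size^2) x 1), each block a
# column-major flattened size x size raster.
image_cnn_fwd_batch <- function(X, params) {
  s <- params$in_size
  c1 <- conv2d_fwd(X, params$W1, params$b1, s, s)
  r1 <- relu_fwd(c1$out)
  p1 <- pool2d_fwd(r1$out, s, s)
  s2 <- s %/% 2L
  c2 <- conv2d_fwd(p1$out, params$W2, params$b2, s2, s2)
  r2 <- relu_fwd(c2$out)
  p2 <- pool2d_fwd(r2$out, s2, s2)
  s4 <- s2 %/% 2L
  d <- dense_fwd(p2$out, params$Wd, params$bd, s4 * s4)
  list(out = d$out, cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
                                 p2 = p2, d = d))
}

image_cnn_bwd_batch <- function(dout, cache, params) {
  dd <- dense_bwd(dout, cache$d$cache)
  dr2 <- pool2d_bwd(dd$dX, cache$p2$cache)
  dc2 <- relu_bwd(dr2, cache$r2$cache)
  g2 <- conv2d_bwd(dc2, cache$c2$cache)
  dr1 <- pool2d_bwd(g2$dX, cache$p1$cache)
  dc1 <- relu_bwd(dr1, cache$r1$cache)
  g1 <- conv2d_bwd(dc1, cache$c1$cache)
  list(grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                    Wd = dd$dW, bd = dd$db),
       dX = g1$dX)
}

image_cnn_fwd_cache <- function(image, params) {
  px <- if (inherits(image, "glyph_image")) image$pixels else as.matrix(image)
  if (!all(dim(px) == c(params$in_size, params$in_size))) {
    abort(sprintf("image must be %dx%d", params$in_size, params$in_size))
  }
  r <- image_cnn_fwd_batch(matrix(as.vector(px), ncol = 1L), params)
  list(out = as.vector(r$out), cache = r$cache)
}

#' Forward pass of the image (2D) feature extractor
#'
#' Pipeline: conv(3x3, 8 channels), rectifier, 2x2 max pool, conv(3x3, 32
#' channels), rectifier, 2x2 max pool, dense to 128. Spatial sizes
#' 14 -> 7 -> 3 under "same" padding with flooring pools.
#'
#' @param image A [glyph_image()] or a binary matrix of the configured size.
#' @param params From [image_cnn_init()].
#' @return Numeric feature vector of length 128 (by default).
#' @export
image_cnn_forward <- function(image, params) {
  image_cnn_fwd_cache(image, params)$out
}

# single-input backward wrappers (dout: vector of length dense_out)
code_cnn_bwd <- function(dout, cache, params) {
  code_cnn_bwd_batch(matrix(dout, nrow = 1L), cache, params)
}

image_cnn_bwd <- function(dout, cache, params) {
  image_cnn_bwd_batch(matrix(dout, nrow = 1L), cache, params)
}
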