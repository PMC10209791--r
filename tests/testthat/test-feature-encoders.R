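test_that("code extractor yields fixed-width 32-dim vectors, deterministically", {
  p <- code_cnn_init(26L, 4L, seed = 2)
  for (code in c("kaqy", "g", "", "abcd")) {
    v <- code_cnn_forward(one_hot_encode(code, letters, 4), p)
    expect_length(v, 32L)
  }
  m <- one_hot_encode("rtgh", letters, 4)
  expect_identical(code_cnn_forward(m, p), code_cnn_forward(m, p))
  expect_error(code_cnn_forward(matrix(0, 3, 26), p), "does not match")
})

test_that("all-zero input and all-zero parameters give all-zero output", {
  p <- code_cnn_init(26L, 4L, seed = 2)
  for (nm in c("W1", "b1", "W2", "b2", "Wd", "bd")) p[[nm]][] <- 0
  expect_equal(code_cnn_forward(matrix(0, 4, 26), p), rep(0, 32))

  ip <- image_cnn_init(seed = 2)
  for (nm in c("W1", "b1", "W2", "b2", "Wd", "bd")) ip[[nm]][] <- 0
  expect_equal(image_cnn_forward(matrix(0, 14, 14), ip), rep(0, 128))
})

test_that("image extractor is 128-dim with spatial sizes 14 -> 7 -> 3", {
  ip <- image_cnn_init(seed = 4)
  g <- bundled_glyph_bitmaps()[["心"]]
  v <- image_cnn_forward(g, ip)
  expect_length(v, 128L)
  r <- mscner:::image_cnn_fwd_cache(g, ip)
  expect_equal(nrow(r$cache$p1$out), 7L * 7L) # after first pool
  expect_equal(nrow(r$cache$p2$out), 3L * 3L) # after second pool (floor)
  expect_equal(ncol(r$cache$c1$out), 8L)
  expect_equal(ncol(r$cache$c2$out), 32L)
  expect_error(image_cnn_forward(matrix(0, 13, 14), ip), "14x14")
})

test_that("conv stack specs pin the reference architecture", {
  sc <- conv_stack_spec("code")
  expect_equal(sc$kernel, 3L)
  expect_equal(sc$pool, 2L)
  expect_equal(sc$dense_out, 32L)
  si <- conv_stack_spec("image")
  expect_equal(si$channels, c(8L, 32L))
  expect_equal(si$dense_out, 128L)
})

test_that("analytic gradients match numeric gradients on a small input", {
  set.seed(6)
  # 3x3 one-hot-style toy input through a small code stack
  p <- code_cnn_init(3L, 4L, seed = 3)
  X <- matrix(runif(12), 4, 3) # continuous input avoids pooling ties
  wvec <- rnorm(32)
  r <- mscner:::code_cnn_fwd_cache(X, p)
  bk <- mscner:::code_cnn_bwd(wvec, r$cache, p)
  for (nm in c("W1", "b1", "W2", "b2", "Wd", "bd")) {
    f <- function(v) {
      pp <- p; pp[[nm]][] <- v
      sum(mscner:::code_cnn_fwd_cache(X, pp)$out * wvec)
    }
    expect_grad_match(f, p[[nm]], bk$grads[[nm]], k = 12, tol = 1e-4)
  }

  ip <- image_cnn_init(seed = 5)
  img <- matrix(runif(196), 14, 14)
  wv <- rnorm(128)
  ri <- mscner:::image_cnn_fwd_cache(img, ip)
  bki <- mscner:::image_cnn_bwd(wv, ri$cache, ip)
  for (nm in c("W1", "b1", "W2", "b2", "Wd", "bd")) {
    f <- function(v) {
      pp <- ip; pp[[nm]][] <- v
      sum(mscner:::image_cnn_fwd_cache(img, pp)$out * wv)
    }
    expect_grad_match(f, ip[[nm]], bki$grads[[nm]], k = 12, tol = 1e-4)
  }
})

test_that("batched forward equals per-input forward", {
  p <- code_cnn_init(26L, 4L, seed = 9)
  codes <- c("kaqy", "rtgh", "", "abc")
  single <- t(vapply(codes, function(cd) {
    code_cnn_forward(one_hot_encode(cd, letters, 4), p)
  }, numeric(32)))
  X <- do.call(rbind, lapply(codes, one_hot_encode, alphabet = letters, max_len = 4))
  batch <- mscner:::code_cnn_fwd_batch(X, p)$out
  expect_equal(unname(batch), unname(single), tolerance = 1e-12)

  ip <- image_cnn_init(seed = 9)
  bm <- bundled_glyph_bitmaps()
  chars <- c("心", "手", "肿")
  singles <- t(vapply(chars, function(ch) image_cnn_forward(bm[[ch]], ip),
                      numeric(128)))
  Xi <- matrix(unlist(lapply(chars, function(ch) as.vector(bm[[ch]]$pixels))),
               ncol = 1)
  batchi <- mscner:::image_cnn_fwd_batch(Xi, ip)$out
  expect_equal(unname(batchi), unname(singles), tolerance = 1e-12)
})

test_that("batch order does not change a single example's features", {
  ip <- image_cnn_init(seed = 1)
  bm <- bundled_glyph_bitmaps()
  orderings <- list(c("心", "手", "呕"), c("呕", "心", "手"))
  outs <- lapply(orderings, function(ord) {
    X <- matrix(unlist(lapply(ord, function(ch) as.vector(bm[[ch]]$pixels))), ncol = 1)
    out <- mscner:::image_cnn_fwd_batch(X, ip)$out
    out[match("心", ord), ]
  })
  expect_equal(outs[[1]], outs[[2]])
})
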