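small_cfg <- function(...) {
  ner_config("desk", hidden = 16L, proj_dim = 8L,
             backbone = list(type = "standin", layers = 2L, width = 8L, seed = 1L),
             batch_size = 8L, ...)
}

small_corpus <- function(n = 16, seed = 5) {
  synth_generate(synth_config(seed = seed, n_documents = n,
                              categories = c("Disease", "Anatomy"),
                              weights = c(0.6, 0.4), split = 1))$train
}

test_that("the reference configuration profile carries the standard defaults", {
  cfg <- ner_config("paper")
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$hidden, 768L)
  expect_equal(cfg$proj_dim, 768L)
  expect_equal(cfg$max_len, 510L)
  expect_equal(cfg$backbone$layers, 12L)
  expect_true(all(cfg$channels))
  expect_error(ner_config("desk", nonsense = 1), "unknown config field")
  expect_error(ner_config("desk", channels = c(bogus = FALSE)), "unknown channel")
})

test_that("concatenation preserves channel order, widths and positions", {
  n <- 3
  mats <- list(context = matrix(1, n, 768), five_stroke = matrix(2, n, 32),
               zheng = matrix(3, n, 32), phonological = matrix(4, n, 32),
               stroke = matrix(5, n, 32), image = matrix(6, n, 128))
  out <- do.call(concat_features, mats)
  expect_equal(dim(out), c(n, 1024L)) # 768 + 4*32 + 128
  offs <- attr(out, "channel_offsets")
  expect_equal(names(offs), c("context", "five_stroke", "zheng",
                              "phonological", "stroke", "image"))
  expect_true(all(out[, offs$zheng] == 3))
  expect_true(all(out[, offs$image] == 6))
  # an all-zero channel keeps its slice all-zero
  mats$stroke <- matrix(0, n, 32)
  out2 <- do.call(concat_features, mats)
  expect_true(all(out2[, offs$stroke] == 0))
  # ablated channel contributes zero width
  out3 <- concat_features(five_stroke = mats$five_stroke, image = mats$image)
  expect_equal(ncol(out3), 160L)
  expect_error(concat_features(), "NULL")
  expect_error(concat_features(context = matrix(1, 2, 3),
                               image = matrix(1, 3, 3)), "disagree")
})

test_that("bilstm output is [forward; backward] of width 2 x hidden", {
  cf <- lstm_init(6L, 768L, seed = 1)
  cb <- lstm_init(6L, 768L, seed = 2)
  H <- bilstm_encode(matrix(rnorm(18), 3, 6), cf, cb)
  expect_equal(dim(H), c(3L, 1536L))

  # all-zero parameters give all-zero states
  cz <- lstm_init(4L, 5L, seed = 1)
  for (nm in c("Wx", "Wh", "b")) cz[[nm]][] <- 0
  expect_equal(bilstm_encode(matrix(rnorm(12), 3, 4), cz, cz),
               matrix(0, 3, 10))

  expect_error(bilstm_encode(matrix(0, 0, 4), cz, cz), "empty")
  expect_error(bilstm_encode(matrix(0, 3, 7), cz, cz), "input_dim")
})

test_that("backward pass equals the reversed forward pass on reversed input", {
  cf <- lstm_init(5L, 4L, seed = 3)
  cb <- lstm_init(5L, 4L, seed = 4)
  x <- matrix(rnorm(35), 7, 5)
  H <- bilstm_encode(x, cf, cb)
  rev_run <- mscner:::lstm_fwd_batch(mscner:::pad_batch(list(x[7:1, ]))$Xs, cb)$Hs
  h_rev <- do.call(rbind, lapply(rev_run, function(m) m[1, ]))
  expect_equal(H[, 5:8], h_rev[7:1, ], tolerance = 1e-12)
})

test_that("training reduces the loss and is seed-deterministic", {
  corpus <- small_corpus(16)
  cfg <- small_cfg(epochs = 6L)
  m1 <- ner_fit(corpus, cfg)
  expect_equal(nrow(m1$log), 6L)
  # loss strictly decreases over the first epochs on easy synthetic data
  expect_true(all(diff(m1$log$loss[1:5]) < 0))
  m2 <- ner_fit(corpus, cfg)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$params$trans, m2$params$trans)
})

test_that("empty corpora and out-of-schema tags are rejected", {
  empty <- tibble::tibble(doc_id = integer(0), pos = integer(0),
                          char = character(0), tag = character(0))
  expect_error(ner_fit(empty, small_cfg()), "empty")
  corpus <- small_corpus(4)
  expect_error(ner_fit(corpus, small_cfg(), categories = "Medicine"), "schema")
})

test_that("channel ablation trains and shrinks the input width", {
  corpus <- small_corpus(8)
  cfg <- small_cfg(epochs = 1L,
                   channels = c(image = FALSE, phonological = FALSE))
  m <- ner_fit(corpus, cfg)
  expect_equal(m$meta$input_dim, 8L + 3L * 32L)
  expect_false(any(is.na(m$log$loss)))
  # emissions-only configuration (context channel alone) also trains
  cfg2 <- small_cfg(epochs = 1L, dynamic_fusion = FALSE,
                    channels = c(five_stroke = FALSE, zheng = FALSE,
                                 phonological = FALSE, stroke = FALSE,
                                 image = FALSE))
  m2 <- ner_fit(corpus, cfg2)
  expect_equal(m2$meta$input_dim, 8L)
})

test_that("prediction emits schema tags aligned with the input", {
  corpus <- small_corpus(10)
  m <- ner_fit(corpus, small_cfg(epochs = 2L))
  pred <- predict(m, corpus)
  expect_equal(nrow(pred), nrow(corpus))
  expect_true(all(pred$pred_tag %in% m$meta$tag_names))
  expect_equal(pred$char, corpus$char)
  # strings predict too
  pred2 <- predict(m, "患者肺癌切除")
  expect_equal(nchar(paste(pred2$char, collapse = "")), 6L)
  # evaluating gold against itself gives perfect scores
  rep <- evaluate_ner(corpus_spans(corpus), corpus_spans(corpus))
  expect_true(all(rep$f1 == 1))
})

test_that("dev split drives early stopping and logged dev metrics", {
  gen <- synth_generate(synth_config(seed = 8, n_documents = 20,
                                     categories = c("Disease", "Anatomy"),
                                     weights = c(0.6, 0.4), split = 0.7))
  m <- ner_fit(gen$train, small_cfg(epochs = 3L, patience = 2L),
               dev_corpus = gen$test)
  expect_true(all(!is.na(m$log$dev_loss)))
  expect_true(all(m$log$dev_f1 >= 0 & m$log$dev_f1 <= 1))
})

test_that("tidy/glance/autoplot expose model internals", {
  corpus <- small_corpus(6)
  m <- ner_fit(corpus, small_cfg(epochs = 2L))
  td <- generics::tidy(m)
  expect_true(all(c("transition", "fusion_weight") %in% td$component))
  a <- td$estimate[td$component == "fusion_weight"]
  expect_equal(sum(a), 1)
  gl <- generics::glance(m)
  expect_equal(gl$epochs, 2L)
  expect_gt(gl$n_parameters, 1000)
  p <- ggplot2::autoplot(m$log)
  expect_s3_class(p, "ggplot")
})
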