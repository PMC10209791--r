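test_that("read_bio parses documents and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".bio")
  writeLines(c("头\tB-ANA", "痛\tI-ANA"), f)
  corpus <- read_bio(f)
  expect_equal(nrow(corpus), 2L)
  expect_equal(unique(corpus$doc_id), 1L)
  sp <- corpus_spans(corpus)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$category, "ANA")

  writeLines(character(0), f)
  expect_equal(nrow(read_bio(f)), 0L)

  writeLines(c("头\tB-ANA", "no-tab-here"), f)
  expect_error(read_bio(f), "line 2")

  writeLines(c("头\tB-ANA", "痛\tBAD"), f)
  expect_error(read_bio(f), "line 2")
})

test_that("write/read round-trips generated corpora bit-exactly", {
  gen <- demo_corpus()
  f <- withr::local_tempfile(fileext = ".bio")
  write_bio(gen$train, f)
  back <- read_bio(f)
  expect_identical(as.data.frame(back), as.data.frame(gen$train))
  # and the file itself round-trips byte-exactly
  f2 <- withr::local_tempfile(fileext = ".bio")
  write_bio(back, f2)
  expect_identical(readLines(f, encoding = "UTF-8"), readLines(f2, encoding = "UTF-8"))
})

test_that("chunking respects max_len and never splits an entity", {
  # 1200-char entity-free document: ceiling split into 3 chunks
  doc <- tibble::tibble(doc_id = 1L, pos = 1:1200,
                        char = rep("患", 1200), tag = "O")
  ch <- chunk_documents(doc, 510L)
  expect_equal(unique(ch$chunk), 1:3)
  expect_true(all(table(ch$chunk) <= 510))
  expect_equal(paste(ch$char, collapse = ""), paste(doc$char, collapse = ""))

  # short document comes back unchanged
  short <- tibble::tibble(doc_id = 1L, pos = 1:5, char = rep("心", 5), tag = "O")
  expect_equal(chunk_documents(short, 510L)$pos, 1:5)

  # entity straddling the tentative boundary: break moves left to last O
  n <- 30L
  tags <- rep("O", n)
  tags[14:18] <- c("B-DIS", rep("I-DIS", 4)) # crosses position 15
  doc2 <- tibble::tibble(doc_id = 1L, pos = 1:n, char = rep("肺", n), tag = tags)
  ch2 <- chunk_documents(doc2, 15L)
  expect_equal(max(ch2$pos[ch2$chunk == 1]), 13L) # last O before the entity
  # concatenation restores the document and its spans
  expect_equal(ch2$tag, tags)
  orig_spans <- corpus_spans(doc2)
  glued <- ch2 |> dplyr::group_by(doc_id) |>
    dplyr::mutate(pos = dplyr::row_number()) |> dplyr::ungroup()
  expect_equal(corpus_spans(glued[, c("doc_id", "pos", "char", "tag")]), orig_spans)

  # a single entity longer than max_len cannot be chunked
  tags3 <- c("B-DIS", rep("I-DIS", 19))
  doc3 <- tibble::tibble(doc_id = 1L, pos = 1:20, char = rep("肺", 20), tag = tags3)
  expect_error(chunk_documents(doc3, 10L), "cannot be chunked")
})

test_that("corpus_stats reproduces the published split ratios and shares", {
  yidu <- corpus_stats(bundled_entity_counts("yidu_s4k"))
  expect_equal(yidu$split_ratio[yidu$category == "Disease"], 0.7610)
  expect_equal(yidu$split_ratio[yidu$category == "Medicine"], 0.7898)
  expect_equal(yidu$split_ratio[yidu$category == "All"], 0.7463)
  expect_equal(yidu$train[yidu$category == "All"], 17653)
  expect_equal(yidu$test[yidu$category == "All"], 6002)

  self <- corpus_stats(bundled_entity_counts("self_annotated"))
  expect_equal(self$share_pct[self$category == "Instrument"], 1.52)

  # single category with empty test split
  one <- corpus_stats(data.frame(category = "X", train = 10, test = 0))
  expect_equal(one$split_ratio[one$category == "X"], 1.0)
  # shares sum to 1 over categories
  expect_equal(sum(self$share[self$category != "All"]), 1)
})
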