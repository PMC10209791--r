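test_that("bundled reference table returns the published codes", {
  tab <- bundled_code_table(synthetic = FALSE)
  expect_equal(length(tab), 6L)

  ou <- lookup_codes(tab, "呕") # 呕
  expect_equal(ou$five_stroke, "kaqy")
  expect_equal(ou$zheng, "jhos")

  shou <- lookup_codes(tab, "手") # 手
  expect_equal(shou$five_stroke, "rtgh")
  expect_equal(shou$stroke_seq, "3112")

  xin <- lookup_codes(tab, "心") # 心
  expect_equal(xin$stroke_seq, "4544")

  zhong <- lookup_codes(tab, "肿") # 肿
  expect_equal(zhong$five_stroke, "ekhh")
  expect_equal(zhong$phonological, "zhǒng")
})

test_that("lookup is total: unknown characters return the UNK record", {
  tab <- tiny_code_table()
  for (ch in c("A", "7", "?", "龟")) {
    rec <- lookup_codes(tab, ch)
    expect_equal(rec$five_stroke, "")
    expect_equal(rec$stroke_seq, "")
  }
})

test_that("reading rejects malformed rows with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("一\tg\ta\tyi1\t1", "二\tBAD!\tbd\ter4\t11"), f)
  expect_error(read_code_table(f), "line 2")

  writeLines(c("一\tg\ta\tyi1\t1", "一\tfg\tbd\ter4\t11"), f)
  expect_error(read_code_table(f), "duplicate")

  writeLines(c("一\tg\ta\tyi1\t196"), f)
  expect_error(read_code_table(f), "line 1")

  expect_error(read_code_table(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("empty file yields a table where every lookup is UNK", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  tab <- read_code_table(f)
  expect_equal(length(tab), 0L)
  expect_equal(lookup_codes(tab, "心")$five_stroke, "")
})

test_that("stroke_count_vector counts each stroke type", {
  expect_equal(stroke_count_vector("4544"), c(0L, 0L, 0L, 3L, 1L))
  expect_equal(stroke_count_vector("251121"), c(3L, 2L, 0L, 0L, 1L))
  expect_equal(stroke_count_vector(""), integer(5))
  expect_error(stroke_count_vector("126"), "1-5")
  # components always sum to the code length
  set.seed(4)
  for (i in 1:20) {
    s <- paste(sample(1:5, sample(0:12, 1), replace = TRUE), collapse = "")
    expect_equal(sum(stroke_count_vector(s)), nchar(s))
  }
})

test_that("one_hot_encode places single indicators per row", {
  m <- one_hot_encode("a", letters, 4)
  expect_equal(dim(m), c(4L, 26L))
  expect_equal(unname(m[1, 1]), 1)
  expect_equal(sum(m), 1)

  expect_equal(sum(one_hot_encode("", letters, 4)), 0)

  m2 <- one_hot_encode("kaqy", letters, 4)
  expect_equal(unname(rowSums(m2)), c(1, 1, 1, 1))
  expect_equal(which(m2[1, ] == 1), c(k = 11L))
  expect_equal(unname(apply(m2, 1, which.max)), match(c("k", "a", "q", "y"), letters))

  expect_error(one_hot_encode("a1", letters, 4), "outside alphabet")
  expect_warning(one_hot_encode("abcde", letters, 4), "truncated")
})

test_that("one-hot round-trips the (possibly truncated) code string", {
  tab <- bundled_code_table()
  set.seed(7)
  for (ch in sample(tab$entries$char, 12)) {
    code <- lookup_codes(tab, ch)$five_stroke
    m <- one_hot_encode(code, letters, 4)
    expect_equal(paste(one_hot_decode(m), collapse = ""),
                 substr(code, 1, 4))
  }
  # row sums <= 1 and total = min(len, max_len)
  m <- suppressWarnings(one_hot_encode("12345123", as.character(1:5), 6))
  expect_true(all(rowSums(m) <= 1))
  expect_equal(sum(m), 6)
})

test_that("pinyin decomposition normalizes tones and splits syllables", {
  expect_equal(parse_pinyin("zhǒng"), list(initial = "zh", final = "ong", tone = "3"))
  expect_equal(parse_pinyin("ǒu"), list(initial = "", final = "ou", tone = "3"))
  expect_equal(parse_pinyin("xīn"), list(initial = "x", final = "in", tone = "1"))
  expect_equal(parse_pinyin("ma3"), list(initial = "m", final = "a", tone = "3"))
  expect_equal(parse_pinyin("er"), list(initial = "", final = "er", tone = "0"))
  expect_true(is.na(parse_pinyin("xyzzy")$final))
  # symbols always lie in the alphabet
  alpha <- pinyin_alphabet()
  for (s in c("zhàng", "tù", "shǒu", "lv4")) {
    expect_true(all(mscner:::pinyin_symbols(s) %in% alpha))
  }
})
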