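test_that("sequence_score matches hand-computed arithmetic", {
  # n = 1, K = 2, all-zero scores: both tags score 0
  E0 <- matrix(0, 1, 2); Z0 <- matrix(0, 4, 4)
  expect_equal(sequence_score(E0, Z0, 1L), 0)
  expect_equal(sequence_score(E0, Z0, 2L), 0)

  # n = 2 hand-set: emissions [[1,0],[0,2]], all transitions 0.5
  E <- matrix(c(1, 0, 0, 2), 2, 2, byrow = TRUE)
  Z <- matrix(0.5, 4, 4)
  expect_equal(sequence_score(E, Z, c(1L, 2L)), 4.5)

  # adding c to every emission adds n*c to every sequence score
  set.seed(3)
  E <- matrix(rnorm(6), 3, 2); Z <- matrix(rnorm(16), 4, 4)
  for (y in list(c(1L, 1L, 2L), c(2L, 2L, 2L))) {
    expect_equal(sequence_score(E + 1.7, Z, y),
                 sequence_score(E, Z, y) + 3 * 1.7)
  }
})

test_that("log_partition has its closed forms on zero scores", {
  expect_equal(log_partition(matrix(0, 1, 2), matrix(0, 4, 4)), log(2))
  expect_equal(log_partition(matrix(0, 2, 2), matrix(0, 4, 4)), log(4))
})

test_that("probabilities normalize and shift-invariance holds", {
  E0 <- matrix(0, 1, 2); Z0 <- matrix(0, 4, 4)
  expect_equal(sequence_probability(E0, Z0, 1L), 0.5)

  set.seed(11)
  for (case in 1:5) {
    n <- sample(1:3, 1); K <- sample(2:3, 1)
    E <- matrix(rnorm(n * K), n, K)
    Z <- matrix(rnorm((K + 2)^2), K + 2, K + 2)
    enum <- crf_enumerate(E, Z)
    expect_equal(sum(enum$prob), 1, tolerance = 1e-12)
    # the Viterbi sequence attains the maximal probability
    vit <- viterbi_decode(E, Z)
    expect_equal(sequence_probability(E, Z, vit$tags), max(enum$prob))
    # adding a constant to all scores leaves probabilities unchanged
    y <- enum$tags[[3]]
    expect_equal(sequence_probability(E + 2.3, Z, y),
                 sequence_probability(E, Z, y))
  }
})

test_that("forward recursion and Viterbi match exhaustive enumeration", {
  for (s in 1:40) {
    inst <- random_crf(s)
    lz_oracle <- enum_log_partition(inst$E, inst$Z)
    expect_equal(log_partition(inst$E, inst$Z), lz_oracle, tolerance = 1e-8)
    vit <- viterbi_decode(inst$E, inst$Z)
    enum <- crf_enumerate(inst$E, inst$Z)
    expect_equal(vit$score, max(enum$score), tolerance = 1e-10)
    expect_equal(sequence_score(inst$E, inst$Z, vit$tags), vit$score)
  }
})

test_that("marginals equal the gradient of log-partition and the enumeration", {
  set.seed(23)
  inst <- random_crf(23)
  fb <- crf_forward_backward(inst$E, inst$Z)
  enum <- crf_enumerate(inst$E, inst$Z)
  marg_true <- matrix(0, inst$n, inst$K)
  for (r in seq_len(nrow(enum))) {
    y <- enum$tags[[r]]
    for (i in seq_len(inst$n)) {
      marg_true[i, y[i]] <- marg_true[i, y[i]] + enum$prob[r]
    }
  }
  expect_equal(fb$marginals, marg_true, tolerance = 1e-8)
  # d logZ / d emission[i, t] = marginal[i, t] (numeric check)
  f <- function(v) { EE <- inst$E; EE[] <- v; log_partition(EE, inst$Z) }
  idx <- seq_len(min(6, length(inst$E)))
  ng <- num_grad_at(f, as.vector(inst$E), idx)
  expect_equal(ng, as.vector(fb$marginals)[idx], tolerance = 1e-5)
})

test_that("ties backtrack to the lowest tag index", {
  # all-zero scores: every sequence ties; decoder must pick tag 1 throughout
  vit <- viterbi_decode(matrix(0, 3, 3), matrix(0, 5, 5))
  expect_equal(vit$tags, c(1L, 1L, 1L))
  # zero transitions: per-position argmax of emissions
  E <- matrix(c(0, 2, 1, 3, 5, 4), 2, 3, byrow = TRUE)
  expect_equal(viterbi_decode(E, matrix(0, 5, 5))$tags, c(2L, 2L))
})

test_that("BIO hard constraints forbid invalid transitions in decodes", {
  tags <- c("O", "B-DIS", "I-DIS", "B-ANA", "I-ANA")
  K <- length(tags)
  set.seed(31)
  for (rep in 1:10) {
    Z <- bio_constrain(matrix(rnorm((K + 2)^2), K + 2, K + 2), tags)
    E <- matrix(rnorm(6 * K), 6, K)
    y <- viterbi_decode(E, Z)$tags
    lab <- tags[y]
    for (i in seq_along(lab)) {
      if (grepl("^I-", lab[i])) {
        prev <- if (i == 1) "O" else lab[i - 1]
        expect_true(grepl("^[BI]-", prev) &&
                      sub("^[BI]-", "", prev) == sub("^I-", "", lab[i]))
      }
    }
  }
})
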