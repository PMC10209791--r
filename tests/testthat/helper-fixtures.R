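# Shared fixtures and oracles, built in code.

# tiny in-memory code table
tiny_code_table <- function() {
  code_table(tibble::tibble(
    char = c("一", "二", "三"),
    five_stroke = c("g", "fg", "dg"),
    zheng = c("a", "bd", "cd"),
    phonological = c("yi1", "er4", "san1"),
    stroke_seq = c("1", "11", "111")
  ))
}

# numeric gradient at a random coordinate subset
num_grad_at <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

expect_grad_match <- function(f, x, analytic, k = 20, tol = 1e-4) {
  idx <- sample(length(x), min(k, length(x)))
  ng <- num_grad_at(f, as.vector(x), idx)
  ag <- as.vector(analytic)[idx]
  expect_lt(max(abs(ng - ag)) / max(1e-6, max(abs(ng))), tol)
}

# independent log-partition oracle: explicit sum over all K^n sequences
enum_log_partition <- function(emissions, transitions) {
  n <- nrow(emissions); K <- ncol(emissions)
  S <- K + 1L; E <- K + 2L
  all_y <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  scores <- apply(all_y, 1, function(y) {
    from <- c(S, y[-n])
    sum(transitions[cbind(from, y)]) + transitions[y[n], E] +
      sum(emissions[cbind(seq_len(n), y)])
  })
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

# random small CRF instance
random_crf <- function(seed, n_max = 4, k_max = 4) {
  set.seed(seed)
  n <- sample(1:n_max, 1); K <- sample(2:k_max, 1)
  list(E = matrix(rnorm(n * K), n, K),
       Z = matrix(rnorm((K + 2)^2), K + 2, K + 2),
       n = n, K = K)
}

# small ready-made corpus for io tests
demo_corpus <- function() {
  gen <- synth_generate(synth_config(seed = 5, n_documents = 12,
                                     categories = c("Disease", "Anatomy"),
                                     weights = c(0.5, 0.5), split = 0.75))
  gen
}
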