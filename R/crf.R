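# Linear-chain conditional random field output layer.
#
# A tag sequence y for an n-character input is scored as
#   s(X, y) = sum_i ( Z[y_i, y_{i+1}] + P[i+1, y_{i+1}] )
# over the chain extended with START and STOP boundary states, where Z is
# the (K+2)x(K+2) transition matrix and P the n x K emission matrix. The
# sequence probability is exp(s) normalized over all K^n candidate
# sequences; the partition function is computed exactly by the forward
# recursion in O(n K^2) (log-space with log-sum-exp stabilization), and the
# best sequence by the Viterbi dynamic program. Hard BIO constraints can be
# imposed by setting forbidden transitions to -Inf.
#
# Index convention: tags are 1..K; START = K+1, STOP = K+2.

crf_check <- function(emissions, transitions, tags = NULL) {
  emissions <- as.matrix(emissions)
  K <- ncol(emissions)
  if (nrow(emissions) < 1L) abort("need at least one position")
  if (!all(dim(transitions) == c(K + 2L, K + 2L))) {
    abort(sprintf("transitions must be %dx%d for %d tags", K + 2L, K + 2L, K))
  }
  if (!is.null(tags)) {
    tags <- as.integer(tags)
    if (length(tags) != nrow(emissions)) abort("tag sequence length != number of positions")
    if (any(tags < 1L | tags > K)) abort("tag index outside 1..K")
  }
  list(P = emissions, Z = transitions, K = K, n = nrow(emissions), y = tags)
}

colLSE <- function(M) {
  m <- apply(M, 2, max)
  out <- m + log(colSums(exp(sweep(M, 2, m, "-"))))
  out[!is.finite(m)] <- m[!is.finite(m)] # all -Inf column
  out
}

#' Score one tag sequence under a linear-chain CRF
#'
#' Includes the START -> y_1 and y_n -> STOP boundary terms.
#'
#' @param emissions `n x K` matrix of per-position tag scores.
#' @param transitions `(K+2) x (K+2)` transition matrix (rows = from,
#'   columns = to; START = K+1, STOP = K+2).
#' @param y Integer tag sequence in `1..K`, length `n`.
#' @return The sequence score (a real number).
#' @export
sequence_score <- function(emissions, transitions, y) {
  x <- crf_check(emissions, transitions, y)
  S <- x$K + 1L; E <- x$K + 2L
  from <- c(S, x$y[-x$n])
  sum(x$Z[cbind(from, x$y)]) + x$Z[x$y[x$n], E] +
    sum(x$P[cbind(seq_len(x$n), x$y)])
}

#' Log partition function of a linear-chain CRF
#'
#' `log` of the sum of `exp(sequence_score)` over all `K^n` tag sequences,
#' computed exactly by the forward recursion in `O(n K^2)`.
#'
#' @inheritParams sequence_score
#' @return The log partition value.
#' @export
log_partition <- function(emissions, transitions) {
  x <- crf_check(emissions, transitions)
  S <- x$K + 1L; E <- x$K + 2L
  ZKK <- x$Z[seq_len(x$K), seq_len(x$K), drop = FALSE]
  f <- x$Z[S, seq_len(x$K)] + x$P[1, ]
  if (x$n > 1) for (i in 2:x$n) {
    f <- colLSE(f + ZKK) + x$P[i, ]
  }
  logsumexp(f + x$Z[seq_len(x$K), E])
}

#' Probability of a tag sequence
#'
#' `exp(sequence_score - log_partition)`; over all candidate sequences the
#' probabilities sum to 1, and adding a constant to every score leaves them
#' unchanged.
#'
#' @inheritParams sequence_score
#' @return Probability in `[0, 1]`.
#' @export
sequence_probability <- function(emissions, transitions, y) {
  exp(sequence_score(emissions, transitions, y) -
        log_partition(emissions, transitions))
}

#' Viterbi decoding
#'
#' Returns an argmax of [sequence_score()]; ties are broken toward the
#' lowest tag index at each backtracking step.
#'
#' @inheritParams sequence_score
#' @return List with `tags` (integer sequence) and `score`.
#' @export
viterbi_decode <- function(emissions, transitions) {
  x <- crf_check(emissions, transitions)
  K <- x$K; S <- K + 1L; E <- K + 2L
  ZKK <- x$Z[seq_len(K), seq_len(K), drop = FALSE]
  delta <- x$Z[S, seq_len(K)] + x$P[1, ]
  back <- matrix(0L, x$n, K)
  if (x$n > 1) for (i in 2:x$n) {
    M <- delta + ZKK # M[a, b]: best score ending in b via a
    arg <- apply(M, 2, which.max)
    delta <- M[cbind(arg, seq_len(K))] + x$P[i, ]
    back[i, ] <- arg
  }
  fin <- delta + x$Z[seq_len(K), E]
  tags <- integer(x$n)
  tags[x$n] <- which.max(fin)
  if (x$n > 1) for (i in x$n:2) tags[i - 1L] <- back[i, tags[i]]
  list(tags = tags, score = max(fin))
}

#' Forward-backward pass: partition, marginals and expected counts
#'
#' @inheritParams sequence_score
#' @return List with `log_z`, `marginals` (`n x K` posterior tag
#'   probabilities) and `expected_transitions` (`(K+2) x (K+2)` expected
#'   transition counts under the model, including boundary transitions).
#' @export
crf_forward_backward <- function(emissions, transitions) {
  x <- crf_check(emissions, transitions)
  K <- x$K; n <- x$n; S <- K + 1L; E <- K + 2L
  ZKK <- x$Z[seq_len(K), seq_len(K), drop = FALSE]
  Fm <- matrix(-Inf, n, K)
  Fm[1, ] <- x$Z[S, seq_len(K)] + x$P[1, ]
  if (n > 1) for (i in 2:n) Fm[i, ] <- colLSE(Fm[i - 1, ] + ZKK) + x$P[i, ]
  log_z <- logsumexp(Fm[n, ] + x$Z[seq_len(K), E])
  Bm <- matrix(-Inf, n, K)
  Bm[n, ] <- x$Z[seq_len(K), E]
  if (n > 1) for (i in (n - 1):1) {
    # rows of ZKK are "from": b_i[a] = lse_b(Z[a,b] + P[i+1,b] + B[i+1,b])
    Bm[i, ] <- colLSE(t(ZKK) + x$P[i + 1, ] + Bm[i + 1, ])
  }
  marg <- exp(Fm + Bm - log_z)
  et <- matrix(0, K + 2L, K + 2L)
  if (n > 1) for (i in 1:(n - 1)) {
    lp <- outer(Fm[i, ], x$P[i + 1, ] + Bm[i + 1, ], "+") + ZKK - log_z
    et[seq_len(K), seq_len(K)] <- et[seq_len(K), seq_len(K)] + exp(lp)
  }
  et[S, seq_len(K)] <- marg[1, ]
  et[seq_len(K), E] <- marg[n, ]
  list(log_z = log_z, marginals = marg, expected_transitions = et)
}

# Negative log-likelihood of y and its gradients w.r.t. emissions and
# transitions (observed minus expected counts, negated).
crf_nll_grad <- function(emissions, transitions, y) {
  x <- crf_check(emissions, transitions, y)
  fb <- crf_forward_backward(emissions, transitions)
  s <- sequence_score(emissions, transitions, y)
  K <- x$K; n <- x$n; S <- K + 1L; E <- K + 2L
  obs_e <- matrix(0, n, K)
  obs_e[cbind(seq_len(n), x$y)] <- 1
  obs_t <- matrix(0, K + 2L, K + 2L)
  from <- c(S, x$y[-n])
  for (i in seq_len(n)) obs_t[from[i], x$y[i]] <- obs_t[from[i], x$y[i]] + 1
  obs_t[x$y[n], E] <- obs_t[x$y[n], E] + 1
  dT <- fb$expected_transitions - obs_t
  dT[!is.finite(transitions)] <- 0 # hard-forbidden entries stay fixed
  list(nll = fb$log_z - s,
       d_emissions = fb$marginals - obs_e,
       d_transitions = dT)
}

#' Enumerate all tag sequences (brute-force oracle)
#'
#' Exhaustive enumeration of the `K^n` candidate sequences with their scores
#' and probabilities. Intended as an independent cross-check of
#' [log_partition()], [sequence_probability()] and [viterbi_decode()] on
#' small instances; refuses instances with more than `limit` sequences.
#'
#' @inheritParams sequence_score
#' @param limit Maximum number of sequences to enumerate.
#' @return Tibble with list-column `tags`, `score`, `prob`, sorted by
#'   decreasing score.
#' @export
crf_enumerate <- function(emissions, transitions, limit = 1e5) {
  x <- crf_check(emissions, transitions)
  if (x$K^x$n > limit) abort(sprintf("K^n = %g exceeds limit %g", x$K^x$n, limit))
  grids <- rep(list(seq_len(x$K)), x$n)
  all_y <- as.matrix(expand.grid(grids))
  scores <- apply(all_y, 1, function(y) sequence_score(emissions, transitions, y))
  lz <- logsumexp(scores)
  out <- tibble(
    tags = lapply(seq_len(nrow(all_y)), function(i) unname(all_y[i, ])),
    score = scores,
    prob = exp(scores - lz)
  )
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' Transition matrix with hard BIO constraints
#'
#' Sets `-Inf` on transitions a BIO scheme forbids: `O -> I-X`,
#' `I-X -> I-Y` and `B-X -> I-Y` for `X != Y`, and `START -> I-X`.
#'
#' @param transitions Finite `(K+2) x (K+2)` matrix.
#' @param tag_names Character vector of the K tag names (`"O"`, `"B-X"`,
#'   `"I-X"`) in column order of the emissions.
#' @return The constrained transition matrix.
#' @export
bio_constrain <- function(transitions, tag_names) {
  K <- length(tag_names)
  stopifnot(all(dim(transitions) == c(K + 2L, K + 2L)))
  cat_of <- function(t) ifelse(grepl("^[BI]-", t), sub("^[BI]-", "", t), NA_character_)
  is_i <- grepl("^I-", tag_names)
  for (b in which(is_i)) {
    cb <- cat_of(tag_names[b])
    for (a in seq_len(K)) {
      ok <- grepl("^[BI]-", tag_names[a]) && identical(cat_of(tag_names[a]), cb)
      if (!ok) transitions[a, b] <- -Inf
    }
    transitions[K + 1L, b] <- -Inf # START -> I-X
  }
  transitions
}
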