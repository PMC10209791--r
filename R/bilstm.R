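# Bidirectional LSTM encoder.
#
# A forward LSTM memorizes the preceding text, a backward LSTM the
# following text; per position the two hidden states are concatenated
# (h = [h_forward; h_backward], width 2 x hidden) so both directions of
# context are available to the decoder. The backward direction is computed
# by running the forward machinery on each sequence reversed within its own
# length, then un-reversing the outputs — which also handles variable
# sequence lengths in a padded batch: padded steps sit after all real steps
# and receive zero upstream gradient, so they contribute nothing.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize one LSTM cell
#'
#' Gate order inside the stacked weight matrices is (input, forget, output,
#' candidate); the forget-gate bias starts at 1.
#'
#' @param input_dim Input width per position.
#' @param hidden Hidden state width.
#' @param seed Integer seed for fan-in-scaled uniform initialization.
#' @return Parameter list `list(Wx, Wh, b, hidden, input_dim)`.
#' @export
lstm_init <- function(input_dim, hidden, seed = 0L) {
  with_seed(seed, {
    b <- numeric(4L * hidden)
    b[(hidden + 1L):(2L * hidden)] <- 1 # forget gate open at init
    list(
      Wx = init_mat(input_dim, 4L * hidden, fan_in = input_dim),
      Wh = init_mat(hidden, 4L * hidden, fan_in = hidden),
      b = b,
      hidden = as.integer(hidden), input_dim = as.integer(input_dim)
    )
  })
}

# Xs: list over time of B x D matrices. Returns Hs (list of B x H) + cache.
# The input projection X %*% Wx is batched over all timesteps up front; only
# the recurrent product stays inside the time loop.
lstm_fwd_batch <- function(Xs, params) {
  H <- params$hidden
  B <- nrow(Xs[[1]])
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  Tmax <- length(Xs)
  Hs <- vector("list", Tmax)
  cache <- vector("list", Tmax)
  idx_i <- 1:H; idx_f <- (H + 1):(2 * H)
  idx_o <- (2 * H + 1):(3 * H); idx_g <- (3 * H + 1):(4 * H)
  Xall <- do.call(rbind, Xs) # (Tmax*B) x D, time-major blocks
  preX <- sweep(Xall %*% params$Wx, 2, params$b, "+")
  for (t in seq_len(Tmax)) {
    rows <- ((t - 1) * B + 1):(t * B)
    pre <- preX[rows, , drop = FALSE] + h %*% params$Wh
    gi <- sigmoid(pre[, idx_i, drop = FALSE])
    gf <- sigmoid(pre[, idx_f, drop = FALSE])
    go <- sigmoid(pre[, idx_o, drop = FALSE])
    gg <- tanh(pre[, idx_g, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    h_new <- go * tc
    cache[[t]] <- list(h_prev = h, c_prev = cc,
                       gi = gi, gf = gf, go = go, gg = gg, tc = tc)
    h <- h_new
    cc <- c_new
    Hs[[t]] <- h
  }
  list(Hs = Hs, cache = cache, Xall = Xall, B = B)
}

# dHs: list over time of B x H upstream gradients; run: output of
# lstm_fwd_batch. Weight/input gradients are batched over timesteps; only
# the recurrent gradient propagation stays in the loop.
lstm_bwd_batch <- function(dHs, run, params) {
  cache <- run$cache
  H <- params$hidden
  Tmax <- length(dHs)
  B <- nrow(dHs[[1]])
  tWh <- t(params$Wh)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  dpre_all <- matrix(0, Tmax * B, 4L * H)
  h_prev_all <- matrix(0, Tmax * B, H)
  for (t in rev(seq_len(Tmax))) {
    cc <- cache[[t]]
    dh <- dHs[[t]] + dh_next
    dc <- dc_next + dh * cc$go * (1 - cc$tc^2)
    dgo <- dh * cc$tc * cc$go * (1 - cc$go)
    dgf <- dc * cc$c_prev * cc$gf * (1 - cc$gf)
    dgi <- dc * cc$gg * cc$gi * (1 - cc$gi)
    dgg <- dc * cc$gi * (1 - cc$gg^2)
    dpre <- cbind(dgi, dgf, dgo, dgg)
    rows <- ((t - 1) * B + 1):(t * B)
    dpre_all[rows, ] <- dpre
    h_prev_all[rows, ] <- cc$h_prev
    dh_next <- dpre %*% tWh
    dc_next <- dc * cc$gf
  }
  dXall <- dpre_all %*% t(params$Wx)
  dXs <- lapply(seq_len(Tmax), function(t) {
    dXall[((t - 1) * B + 1):(t * B), , drop = FALSE]
  })
  list(dXs = dXs,
       grads = list(Wx = crossprod(run$Xall, dpre_all),
                    Wh = crossprod(h_prev_all, dpre_all),
                    b = colSums(dpre_all)))
}

# Build padded time-major batch from a list of n_i x D sequences.
# reverse = TRUE reverses each sequence within its own length first.
pad_batch <- function(seqs, reverse = FALSE) {
  lens <- vapply(seqs, nrow, integer(1))
  Tmax <- max(lens)
  D <- ncol(seqs[[1]])
  B <- length(seqs)
  Xs <- lapply(seq_len(Tmax), function(t) matrix(0, B, D))
  for (b in seq_len(B)) {
    s <- seqs[[b]]
    if (reverse) s <- s[rev(seq_len(lens[b])), , drop = FALSE]
    for (t in seq_len(lens[b])) Xs[[t]][b, ] <- s[t, ]
  }
  list(Xs = Xs, lens = lens)
}

# Inverse of pad_batch for per-time outputs: collect sequence b's rows.
unpad_batch <- function(Hs, lens, reverse = FALSE) {
  lapply(seq_along(lens), function(b) {
    out <- do.call(rbind, lapply(seq_len(lens[b]), function(t) Hs[[t]][b, ]))
    if (reverse) out[rev(seq_len(lens[b])), , drop = FALSE] else out
  })
}

# Full bidirectional pass over a batch of sequences.
# seqs: list of n_i x D matrices. Returns per-sequence n_i x 2H matrices.
bilstm_fwd_batch <- function(seqs, fwd_params, bwd_params) {
  pf <- pad_batch(seqs, reverse = FALSE)
  pb <- pad_batch(seqs, reverse = TRUE)
  runf <- lstm_fwd_batch(pf$Xs, fwd_params)
  runb <- lstm_fwd_batch(pb$Xs, bwd_params)
  Hf <- unpad_batch(runf$Hs, pf$lens, reverse = FALSE)
  Hb <- unpad_batch(runb$Hs, pb$lens, reverse = TRUE)
  H <- lapply(seq_along(seqs), function(b) cbind(Hf[[b]], Hb[[b]]))
  list(H = H, cache = list(runf = runf, runb = runb, lens = pf$lens,
                           B = length(seqs), D = ncol(seqs[[1]])))
}

# dH: list of per-sequence n_i x 2H gradients.
bilstm_bwd_batch <- function(dH, cache, fwd_params, bwd_params) {
  H <- fwd_params$hidden
  lens <- cache$lens
  Tmax <- max(lens)
  B <- cache$B
  dHf <- lapply(seq_len(Tmax), function(t) matrix(0, B, H))
  dHb <- lapply(seq_len(Tmax), function(t) matrix(0, B, H))
  for (b in seq_len(B)) {
    g <- dH[[b]]
    for (t in seq_len(lens[b])) {
      dHf[[t]][b, ] <- g[t, 1:H]
      # backward direction ran on the reversed sequence: position t of the
      # original is step len - t + 1 of the reversed run
      dHb[[lens[b] - t + 1L]][b, ] <- g[t, (H + 1):(2 * H)]
    }
  }
  backf <- lstm_bwd_batch(dHf, cache$runf, fwd_params)
  backb <- lstm_bwd_batch(dHb, cache$runb, bwd_params)
  dX <- lapply(seq_len(B), function(b) {
    out <- matrix(0, lens[b], cache$D)
    for (t in seq_len(lens[b])) {
      out[t, ] <- backf$dXs[[t]][b, ] + backb$dXs[[lens[b] - t + 1L]][b, ]
    }
    out
  })
  list(dX = dX, grads_fwd = backf$grads, grads_bwd = backb$grads)
}

#' Encode one sequence with a bidirectional LSTM
#'
#' @param inputs `n x D` matrix: one concatenated feature vector per
#'   position (must be non-empty).
#' @param fwd_params,bwd_params Cell parameters from [lstm_init()] for the
#'   left-to-right and right-to-left passes.
#' @return `n x (2 * hidden)` matrix; columns `1:hidden` are the forward
#'   hidden states, the rest the backward ones.
#' @export
bilstm_encode <- function(inputs, fwd_params, bwd_params) {
  inputs <- as.matrix(inputs)
  if (nrow(inputs) == 0L) abort("cannot encode an empty sequence")
  if (ncol(inputs) != fwd_params$input_dim) {
    abort(sprintf("input width %d does not match cell input_dim %d",
                  ncol(inputs), fwd_params$input_dim))
  }
  bilstm_fwd_batch(list(inputs), fwd_params, bwd_params)$H[[1]]
}
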