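# Low-level differentiable ops: 1D/2D convolution ("same" zero padding,
# kernel 3), window-2 max pooling (floor on odd lengths), dense layers and
# rectifier.
#
# All ops are block-batched: a batch of N equally-shaped inputs is one tall
# matrix of N stacked blocks (rows = positions of one input, column-major
# for 2D grids; columns = channels). Convolution weights are stored
# flattened — kernel-offset blocks stacked along the input-channel
# dimension (offsets -1, 0, +1 along positions for 1D; row-major over the
# 3x3 window for 2D) — so a convolution is a single matrix product per
# batch. Each *_fwd returns the output plus the cache its *_bwd needs.

# whole-matrix row shift (zero fill): rows moved down by k (k = +1: row i
# holds old row i-1)
shift_rows <- function(X, k) shift_blocks(X, k, nrow(X))

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(dout, cache) dout * cache

# shift within each length-L block: out[row] = X[row - k] (k = +1 reads the
# previous position), zeroed where the source crosses a block boundary
shift_blocks <- function(X, k, L) {
  if (k == 0L) return(X)
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  if (k > 0) {
    out[(k + 1):n, ] <- X[1:(n - k), , drop = FALSE]
    out[rep(seq_len(L), n %/% L) <= k, ] <- 0
  } else {
    out[1:(n + k), ] <- X[(1 - k):n, , drop = FALSE]
    out[rep(seq_len(L), n %/% L) > L + k, ] <- 0
  }
  out
}

conv1d_fwd <- function(X, W, b, L) {
  # X: (N*L) x C_in blocks; W: (3*C_in) x C_out; b: C_out
  Xcat <- cbind(shift_blocks(X, 1L, L), X, shift_blocks(X, -1L, L))
  out <- sweep(Xcat %*% W, 2, b, "+")
  list(out = out, cache = list(Xcat = Xcat, W = W, C_in = ncol(X), L = L))
}

conv1d_bwd <- function(dout, cache) {
  dW <- crossprod(cache$Xcat, dout)
  db <- colSums(dout)
  dXcat <- dout %*% t(cache$W)
  C <- cache$C_in; L <- cache$L
  dX <- shift_blocks(dXcat[, 1:C, drop = FALSE], -1L, L) +
    dXcat[, (C + 1):(2 * C), drop = FALSE] +
    shift_blocks(dXcat[, (2 * C + 1):(3 * C), drop = FALSE], 1L, L)
  list(dW = dW, db = db, dX = dX)
}

# paired indices for window-2 pooling over length-L blocks of an N-block
# batch (odd lengths drop the trailing element)
pool1d_idx <- function(n_rows, L) {
  L2 <- L %/% 2L
  if (L2 < 1L) abort("pooling would empty the sequence")
  N <- n_rows %/% L
  base <- (rep(seq_len(N), each = L2) - 1L) * L
  list(a = base + rep(2L * seq_len(L2) - 1L, N),
       b = base + rep(2L * seq_len(L2), N),
       L_out = L2)
}

pool1d_fwd <- function(X, L) {
  ix <- pool1d_idx(nrow(X), L)
  a <- X[ix$a, , drop = FALSE]
  b <- X[ix$b, , drop = FALSE]
  mask <- a >= b # ties to the earlier position
  list(out = pmax(a, b),
       cache = list(mask = mask, ix = ix, n_in = nrow(X)))
}

pool1d_bwd <- function(dout, cache) {
  dX <- matrix(0, cache$n_in, ncol(dout))
  dX[cache$ix$a, ] <- dout * cache$mask
  dX[cache$ix$b, ] <- dout * (1 - cache$mask)
  dX
}

# dense over flattened blocks: P ((N*L) x C) -> (N x L*C), position fastest
flatten_blocks <- function(P, L, C) {
  N <- nrow(P) %/% L
  t(matrix(aperm(array(P, c(L, N, C)), c(1, 3, 2)), L * C, N))
}

unflatten_blocks <- function(dflat, L, C) {
  N <- nrow(dflat)
  matrix(aperm(array(t(dflat), c(L, C, N)), c(1, 3, 2)), N * L, C)
}

dense_fwd <- function(P, W, b, L) {
  # P: (N*L) x C blocks; W: d_out x (L*C); b: d_out. Output N x d_out.
  C <- ncol(P)
  flat <- flatten_blocks(P, L, C)
  list(out = sweep(flat %*% t(W), 2, b, "+"),
       cache = list(flat = flat, W = W, L = L, C = C))
}

dense_bwd <- function(dout, cache) {
  list(dW = crossprod(dout, cache$flat),
       db = colSums(dout),
       dX = unflatten_blocks(dout %*% cache$W, cache$L, cache$C))
}

# ---- 2D ops on column-major H x W grids stored as (N*H*W) x C blocks -----

# row-major over the window: (dr, dc) in (-1,-1), (-1,0), ..., (1,1)
.offsets3x3 <- as.matrix(expand.grid(dc = -1:1, dr = -1:1))[, c("dr", "dc")]

# per-offset within-block shift amount and validity mask for an H x W grid
grid_shift_spec <- function(H, W) {
  lapply(seq_len(9L), function(k) {
    dr <- .offsets3x3[k, 1]; dc <- .offsets3x3[k, 2]
    rr <- rep(seq_len(H), W); cc <- rep(seq_len(W), each = H)
    list(s = dr + dc * H,
         keep = (rr + dr >= 1) & (rr + dr <= H) & (cc + dc >= 1) & (cc + dc <= W))
  })
}

# out[row] = X[row + s] within blocks, zero where `keep` is FALSE
grid_shift <- function(X, s, keep, block) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  if (s > 0) {
    out[1:(n - s), ] <- X[(s + 1):n, , drop = FALSE]
  } else if (s < 0) {
    out[(1 - s):n, ] <- X[1:(n + s), , drop = FALSE]
  } else {
    out <- X
  }
  out[!rep(keep, n %/% block), ] <- 0
  out
}

conv2d_fwd <- function(X, W, b, H, Wd) {
  # X: (N*H*Wd) x C_in blocks (column-major grids); W: (9*C_in) x C_out
  spec <- grid_shift_spec(H, Wd)
  block <- H * Wd
  P <- do.call(cbind, lapply(spec, function(o) grid_shift(X, o$s, o$keep, block)))
  out <- sweep(P %*% W, 2, b, "+")
  list(out = out, cache = list(P = P, W = W, C_in = ncol(X), spec = spec,
                               block = block))
}

conv2d_bwd <- function(dout, cache) {
  dW <- crossprod(cache$P, dout)
  db <- colSums(dout)
  dP <- dout %*% t(cache$W)
  C <- cache$C_in
  n <- nrow(dP)
  dX <- matrix(0, n, C)
  for (k in seq_len(9L)) {
    o <- cache$spec[[k]]
    blk <- dP[, ((k - 1) * C + 1):(k * C), drop = FALSE]
    blk[!rep(o$keep, n %/% cache$block), ] <- 0
    # adjoint of "read from row + s" is "add at row + s"
    if (o$s > 0) {
      dX[(o$s + 1):n, ] <- dX[(o$s + 1):n, , drop = FALSE] + blk[1:(n - o$s), , drop = FALSE]
    } else if (o$s < 0) {
      dX[1:(n + o$s), ] <- dX[1:(n + o$s), , drop = FALSE] + blk[(1 - o$s):n, , drop = FALSE]
    } else {
      dX <- dX + blk
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# 2x2/stride-2 pooling over column-major H x W grids (floor on odd sides)
pool2d_idx <- function(n_rows, H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  if (Ho < 1L || Wo < 1L) abort("pooling would empty the spatial grid")
  N <- n_rows %/% (H * W)
  ro <- rep(seq_len(Ho), Wo); co <- rep(seq_len(Wo), each = Ho)
  b11 <- (2L * ro - 2L) + (2L * co - 2L) * H + 1L
  b21 <- b11 + 1L
  b12 <- b11 + H
  b22 <- b12 + 1L
  off <- (rep(seq_len(N), each = Ho * Wo) - 1L) * (H * W)
  list(i11 = off + rep(b11, N), i21 = off + rep(b21, N),
       i12 = off + rep(b12, N), i22 = off + rep(b22, N),
       H_out = Ho, W_out = Wo)
}

pool2d_fwd <- function(X, H, W) {
  ix <- pool2d_idx(nrow(X), H, W)
  a11 <- X[ix$i11, , drop = FALSE]; a21 <- X[ix$i21, , drop = FALSE]
  a12 <- X[ix$i12, , drop = FALSE]; a22 <- X[ix$i22, , drop = FALSE]
  m <- pmax(a11, a21, a12, a22)
  w11 <- a11 == m
  w21 <- (a21 == m) & !w11
  w12 <- (a12 == m) & !(w11 | w21)
  w22 <- (a22 == m) & !(w11 | w21 | w12)
  list(out = m, cache = list(w = list(w11, w21, w12, w22), ix = ix,
                             n_in = nrow(X)))
}

pool2d_bwd <- function(dout, cache) {
  dX <- matrix(0, cache$n_in, ncol(dout))
  ix <- cache$ix
  dX[ix$i11, ] <- dout * cache$w[[1]]
  dX[ix$i21, ] <- dout * cache$w[[2]]
  dX[ix$i12, ] <- dout * cache$w[[3]]
  dX[ix$i22, ] <- dout * cache$w[[4]]
  dX
}
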