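#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 imap walk
#' @importFrom stats runif rnorm setNames
#' @importFrom utils head tail
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# split a UTF-8 string into single characters
chars_of <- function(text) {
  if (length(text) != 1L || is.na(text)) abort("`text` must be a single string.")
  if (nchar(text) == 0L) return(character(0))
  strsplit(text, "", fixed = FALSE)[[1]]
}

# Deterministic local RNG: run `expr` under a temporary seed without
# disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# fan-in scaled uniform init
init_mat <- function(nrow, ncol, fan_in = ncol) {
  r <- sqrt(1 / max(1, fan_in))
  matrix(runif(nrow * ncol, -r, r), nrow, ncol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
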