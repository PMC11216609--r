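# Internal numerical and RNG helpers.

# Seed the RNG for the remainder of the calling function, restoring the
# caller-visible RNG state when that function exits.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  invisible(NULL)
}

# One master seed fans out into named sub-streams (simulate/init/train/...)
# so stages are independently reproducible. Result stays below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483587)
}

# Row-wise numerically stable softmax of a matrix.
softmax_rows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(!is.finite(x))) stop("non-finite scores passed to softmax")
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Backprop through row-wise softmax: given y = softmax_rows(x) and dL/dy,
# return dL/dx = y * (dy - rowSums(dy * y)).
softmax_rows_grad <- function(y, dy) {
  y * (dy - rowSums(dy * y))
}

# Exhaustive best one-to-one topic matching (maximizing total similarity).
# K is small in all supported uses; above the exhaustive limit fall back to
# a greedy assignment.
best_assignment <- function(sim, exhaustive_limit = 8L) {
  K <- nrow(sim)
  stopifnot(ncol(sim) == K)
  if (K <= exhaustive_limit) {
    perms <- permutations_of(K)
    scores <- vapply(perms, function(p) sum(sim[cbind(seq_len(K), p)]), numeric(1))
    perms[[which.max(scores)]]
  } else {
    assign <- integer(K)
    taken <- rep(FALSE, K)
    ord <- order(apply(sim, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(ifelse(taken, -Inf, sim[i, ]))
      assign[i] <- j
      taken[j] <- TRUE
    }
    assign
  }
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Slice a T x A x B array at time t without losing dimensions.
slice_mat <- function(arr, t, nr, nc) matrix(arr[t, , ], nr, nc)
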