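# Amortized inference network (theta encoder) and the label classifier head.
# Both are small fully connected networks trained jointly with the model by
# analytic backpropagation; no external autodiff framework is involved.

# Glorot-style initialization of a dense layer weight matrix (out x in).
init_layer <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

# Encoder mapping (normalized BOW, eta_t) -> (mu, sigma) of q(theta_d).
# Two ReLU hidden layers; sigma through softplus so it is strictly positive.
init_encoder <- function(V, K, hidden = c(256L, 256L), use_eta = TRUE,
                         seed = 1L) {
  rng <- local_rng(seed)
  D <- V + if (use_eta) K else 0L
  list(W1 = init_layer(hidden[1], D), b1 = numeric(hidden[1]),
       W2 = init_layer(hidden[2], hidden[1]), b2 = numeric(hidden[2]),
       Wm = init_layer(K, hidden[2]), bm = numeric(K),
       Ws = init_layer(K, hidden[2]), bs = numeric(K),
       hidden = as.integer(hidden), use_eta = use_eta, V = V, K = K)
}

SIGMA_FLOOR <- 1e-6

# Forward pass. inp is B x D. drop_masks: NULL (evaluation) or a list of two
# 0/(1/(1-p)) matrices applied after the ReLUs (inverted dropout).
enc_forward <- function(inp, enc, drop_masks = NULL) {
  A1 <- sweep(inp %*% t(enc$W1), 2, enc$b1, `+`)
  H1 <- relu(A1)
  if (!is.null(drop_masks)) H1 <- H1 * drop_masks[[1]]
  A2 <- sweep(H1 %*% t(enc$W2), 2, enc$b2, `+`)
  H2 <- relu(A2)
  if (!is.null(drop_masks)) H2 <- H2 * drop_masks[[2]]
  s <- sweep(H2 %*% t(enc$Ws), 2, enc$bs, `+`)
  list(inp = inp, A1 = A1, H1 = H1, A2 = A2, H2 = H2, s = s,
       mu = sweep(H2 %*% t(enc$Wm), 2, enc$bm, `+`),
       sigma = softplus(s) + SIGMA_FLOOR,
       drop_masks = drop_masks)
}

# Backward pass: gradients of the loss w.r.t. encoder parameters and input.
enc_backward <- function(cache, enc, dmu, dsigma) {
  ds <- dsigma * sigmoid(cache$s)
  dH2 <- dmu %*% enc$Wm + ds %*% enc$Ws
  if (!is.null(cache$drop_masks)) dH2 <- dH2 * cache$drop_masks[[2]]
  dA2 <- dH2 * (cache$A2 > 0)
  dH1 <- dA2 %*% enc$W2
  if (!is.null(cache$drop_masks)) dH1 <- dH1 * cache$drop_masks[[1]]
  dA1 <- dH1 * (cache$A1 > 0)
  list(W1 = crossprod(dA1, cache$inp), b1 = colSums(dA1),
       W2 = crossprod(dA2, cache$H1), b2 = colSums(dA2),
       Wm = crossprod(dmu, cache$H2), bm = colSums(dmu),
       Ws = crossprod(ds, cache$H2), bs = colSums(ds),
       dinp = dA1 %*% enc$W1)
}

# Classifier head F: topic proportions -> label scores (one hidden layer).
init_classifier <- function(K, M, hidden = 64L, seed = 1L) {
  rng <- local_rng(seed)
  list(Wc1 = init_layer(hidden, K), bc1 = numeric(hidden),
       Wc2 = init_layer(M, hidden), bc2 = numeric(M),
       K = K, M = M, hidden = as.integer(hidden))
}

clf_forward <- function(theta, clf) {
  A <- sweep(theta %*% t(clf$Wc1), 2, clf$bc1, `+`)
  Z <- relu(A)
  O <- sweep(Z %*% t(clf$Wc2), 2, clf$bc2, `+`)
  list(theta = theta, A = A, Z = Z, O = O, P = softmax_rows(O))
}

# Mean cross-entropy of the head on a batch, with gradients w.r.t. the head
# parameters and the input proportions.
clf_backward <- function(cache, clf, labels) {
  B <- nrow(cache$P)
  Y <- matrix(0, B, clf$M)
  Y[cbind(seq_len(B), labels)] <- 1
  dO <- (cache$P - Y) / B
  dZ <- dO %*% clf$Wc2
  dA <- dZ * (cache$A > 0)
  list(Wc1 = crossprod(dA, cache$theta), bc1 = colSums(dA),
       Wc2 = crossprod(dO, cache$Z), bc2 = colSums(dO),
       dtheta = dA %*% clf$Wc1)
}
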