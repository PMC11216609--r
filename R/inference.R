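LOG_FLOOR <- 1e-10

#' KL divergence between diagonal Gaussians
#'
#' Closed form `sum_k [ log(sp_k/sq_k) + (sq_k^2 + (mq_k - mp_k)^2) /
#' (2 sp_k^2) - 1/2 ]`, non-negative and zero exactly when the two
#' distributions coincide. Vector arguments are recycled elementwise.
#'
#' @param mu_q,sigma_q mean and standard deviation of the variational
#'   Gaussian.
#' @param mu_p,sigma_p mean and standard deviation of the prior Gaussian.
#' @return non-negative scalar.
#' @export
kl_diag_gaussians <- function(mu_q, sigma_q, mu_p, sigma_p) {
  if (any(sigma_q <= 0) || any(sigma_p <= 0)) stop("sigma must be positive")
  sum(log(sigma_p / sigma_q) + (sigma_q^2 + (mu_q - mu_p)^2) / (2 * sigma_p^2) - 0.5)
}

# Row-wise KL of per-document q = N(mu_d, diag sigma_d^2) against the slice
# prior N(eta_t, eps^2 I); returns per-document values and gradients.
kl_rows <- function(mu, sigma, eta_t, eps_prior) {
  dev <- sweep(mu, 2, eta_t)
  kl <- rowSums(log(eps_prior / sigma) + (sigma^2 + dev^2) / (2 * eps_prior^2) - 0.5)
  list(kl = kl,
       dmu = dev / eps_prior^2,
       dsigma = -1 / sigma + sigma / eps_prior^2,
       deta = -colSums(dev) / eps_prior^2)
}

# Core single-draw ELBO machinery shared by training, evaluation and the
# gradient tests. Given variational (mu, sigma), one standard-normal draw
# per document, the batch counts and the slice's beta and prior mean,
# computes the reconstruction term, the KL term, and analytic gradients.
elbo_core <- function(mu, sigma, eps_draw, X, beta_t, eta_t, eps_prior,
                      floor = LOG_FLOOR, want_grad = TRUE) {
  r <- mu + sigma * eps_draw
  theta <- softmax_rows(r)
  m <- theta %*% beta_t
  recon <- sum(X * log(m + floor))
  klr <- kl_rows(mu, sigma, eta_t, eps_prior)
  out <- list(recon = recon, kl = sum(klr$kl), elbo = recon - sum(klr$kl),
              theta = theta)
  if (want_grad) {
    G <- X / (m + floor)                       # B x V
    dtheta <- G %*% t(beta_t)                  # d recon / d theta
    out$dtheta_recon <- dtheta
    out$dbeta_recon <- crossprod(theta, G)     # K x V, d recon / d beta
    dr <- softmax_rows_grad(theta, dtheta)
    out$delbo_dmu <- dr - klr$dmu
    out$delbo_dsigma <- dr * eps_draw - klr$dsigma
    out$delbo_deta <- klr$deta * (-1)          # d elbo / d eta = -dKL/deta
    out$kl_dmu <- klr$dmu; out$kl_dsigma <- klr$dsigma; out$kl_deta <- klr$deta
  }
  out
}

#' Variational posterior of a document's topic proportions
#'
#' Runs the amortized encoder on one document (or a matrix of documents) and
#' draws reparameterized samples `softmax(mu + sigma * eps)` from the
#' logistic-normal posterior. With `sigma` forced to zero all samples equal
#' `softmax(mu)`.
#'
#' @param counts length-V count vector, or B x V matrix of counts.
#' @param encoder encoder state from a fitted model.
#' @param eta_t length-K prior mean of the document's slice.
#' @param n_samples number of posterior draws.
#' @param seed integer seed for the draws.
#' @return list with `mu`, `sigma` (B x K) and `samples`
#'   (B x K x n_samples array of simplex rows).
#' @export
infer_theta <- function(counts, encoder, eta_t, n_samples = 1L, seed = 1L) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("empty document: cannot infer topic proportions")
  if (n_samples < 1) stop("n_samples must be at least 1")
  inp <- counts / tot
  if (encoder$use_eta)
    inp <- cbind(inp, matrix(eta_t, nrow(inp), encoder$K, byrow = TRUE))
  fw <- enc_forward(inp, encoder)
  B <- nrow(inp); K <- encoder$K
  rng <- local_rng(seed)
  samples <- array(0, dim = c(B, K, n_samples))
  for (s in seq_len(n_samples)) {
    epsd <- matrix(stats::rnorm(B * K), B, K)
    samples[, , s] <- softmax_rows(fw$mu + fw$sigma * epsd)
  }
  list(mu = fw$mu, sigma = fw$sigma, samples = samples)
}

#' Evidence lower bound of a batch of same-slice documents
#'
#' Monte-Carlo estimate of the per-batch ELBO: the reconstruction term
#' `sum_d sum_w count * log(sum_k theta_k beta^t_{k,w})` averaged over
#' `n_mc` reparameterized posterior samples, minus the closed-form KL of
#' `q(theta_d)` against the slice prior `N(eta_t, eps^2 I)` on the
#' pre-softmax variable. `scale` rescales the batch to an unbiased full-data
#' estimate (`N_t / batch size`).
#'
#' @param counts B x V matrix (or sparse matrix) of word counts, all from
#'   slice `t`.
#' @param t slice index.
#' @param params a [tm_params()] object (provides beta and eta for the
#'   slice).
#' @param encoder amortized encoder state.
#' @param n_mc number of Monte-Carlo samples.
#' @param seed seed for the draws.
#' @param scale multiplicative rescaling of both terms.
#' @return list with `elbo`, `recon`, `kl` (scaled) and `theta` (the last
#'   draw's proportions).
#' @export
elbo_batch <- function(counts, t, params, encoder, n_mc = 1L, seed = 1L,
                       scale = 1) {
  if (t < 1 || t > params$T) stop("slice without prior mean: t = ", t)
  counts <- as.matrix(counts)
  if (n_mc < 1) stop("n_mc must be at least 1")
  eta_t <- params$eta[t, ]
  beta_t <- compute_beta(slice_mat(params$alpha, t, params$K, params$L), params$rho)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("empty document in batch")
  inp <- counts / tot
  if (encoder$use_eta)
    inp <- cbind(inp, matrix(eta_t, nrow(inp), encoder$K, byrow = TRUE))
  fw <- enc_forward(inp, encoder)
  rng <- local_rng(seed)
  recon <- 0; theta <- NULL
  for (s in seq_len(n_mc)) {
    epsd <- matrix(stats::rnorm(nrow(counts) * params$K), nrow(counts), params$K)
    core <- elbo_core(fw$mu, fw$sigma, epsd, counts, beta_t, eta_t,
                      params$eps, want_grad = FALSE)
    recon <- recon + core$recon / n_mc
    theta <- core$theta
  }
  kl <- sum(kl_rows(fw$mu, fw$sigma, eta_t, params$eps)$kl)
  list(elbo = scale * (recon - kl), recon = scale * recon, kl = scale * kl,
       theta = theta)
}

#' Random-walk prior penalty of the temporal trajectories
#'
#' Negative log-density (up to additive constants) of the Gaussian
#' random-walk priors on the topic embeddings and the topic-proportion prior
#' means: `sum_{t>=2} ||alpha_t - alpha_{t-1}||^2 / (2 gamma^2) +
#' ||alpha_1||^2 / 2` plus the analogous `eta` terms with scale `delta`.
#' Constant-zero trajectories give 0; the penalty treats `alpha` and `eta`
#' as MAP-estimated parameters.
#'
#' @param params a [tm_params()] object.
#' @return non-negative scalar.
#' @export
dynamics_penalty <- function(params) {
  a <- params$alpha; e <- params$eta
  pen <- sum(slice_mat(a, 1, params$K, params$L)^2) / 2 + sum(e[1, ]^2) / 2
  if (params$T > 1) for (t in 2:params$T) {
    pen <- pen + sum((a[t, , ] - a[t - 1, , ])^2) / (2 * params$gamma^2)
    pen <- pen + sum((e[t, ] - e[t - 1, ])^2) / (2 * params$delta^2)
  }
  pen
}

# Gradients of dynamics_penalty w.r.t. alpha (array) and eta (matrix).
dynamics_penalty_grad <- function(alpha, eta, delta, gamma) {
  T_ <- dim(alpha)[1]
  ga <- array(0, dim = dim(alpha)); ge <- matrix(0, nrow(eta), ncol(eta))
  ga[1, , ] <- alpha[1, , ]
  ge[1, ] <- eta[1, ]
  if (T_ > 1) for (t in 2:T_) {
    da <- (alpha[t, , ] - alpha[t - 1, , ]) / gamma^2
    ga[t, , ] <- ga[t, , ] + da
    ga[t - 1, , ] <- ga[t - 1, , ] - da
    de <- (eta[t, ] - eta[t - 1, ]) / delta^2
    ge[t, ] <- ge[t, ] + de
    ge[t - 1, ] <- ge[t - 1, ] - de
  }
  list(alpha = ga, eta = ge)
}
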