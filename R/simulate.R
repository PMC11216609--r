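#' Model parameters of the time-aware embedded topic model
#'
#' Container for the generative parameters: the word-embedding table `rho`
#' (L x V), per-slice topic embeddings `alpha` (T x K x L array), per-slice
#' prior means of the topic proportions `eta` (T x K), and the three noise
#' scales — `eps` (standard deviation of the logistic-normal topic-proportion
#' prior around `eta_t`), `delta` (standard deviation of the `eta` random
#' walk) and `gamma` (standard deviation of the topic-embedding random walk).
#'
#' @param rho numeric L x V matrix of word embeddings (columns = words).
#' @param alpha numeric T x K x L array of topic embeddings.
#' @param eta numeric T x K matrix of prior means.
#' @param eps,delta,gamma positive noise scales.
#' @param vocabulary optional character vector of length V.
#' @return object of class `tm_params`.
#' @export
tm_params <- function(rho, alpha, eta, eps = 0.01, delta = 0.01, gamma = 0.01,
                      vocabulary = NULL) {
  stopifnot(is.matrix(rho), length(dim(alpha)) == 3, is.matrix(eta),
            eps > 0, delta >= 0, gamma >= 0)
  L <- nrow(rho); V <- ncol(rho)
  T_ <- dim(alpha)[1]; K <- dim(alpha)[2]
  if (K < 1) stop("K must be at least 1")
  if (dim(alpha)[3] != L) stop("alpha embedding dimension does not match rho")
  if (nrow(eta) != T_ || ncol(eta) != K) stop("eta shape inconsistent with alpha")
  if (!all(is.finite(rho)) || !all(is.finite(alpha)) || !all(is.finite(eta)))
    stop("non-finite model parameters")
  if (!is.null(vocabulary)) stopifnot(length(vocabulary) == V)
  structure(list(rho = rho, alpha = alpha, eta = eta, eps = eps, delta = delta,
                 gamma = gamma, K = K, L = L, T = T_, V = V,
                 vocabulary = vocabulary),
            class = "tm_params")
}

#' @export
print.tm_params <- function(x, ...) {
  cat(sprintf("<tm_params> K=%d topics, V=%d words, L=%d dims, T=%d slices (eps=%g delta=%g gamma=%g)\n",
              x$K, x$V, x$L, x$T, x$eps, x$delta, x$gamma))
  invisible(x)
}

#' Topic-word distributions from embeddings
#'
#' For one time slice, computes the K x V row-stochastic matrix
#' `beta = softmax(alpha %*% rho)` (softmax over words, row by row): each
#' word's generative probability under a topic grows with the inner product
#' of its embedding and the topic embedding. Numerically stabilized by
#' max-subtraction, so rows sum to 1 to machine precision and every entry is
#' strictly positive.
#'
#' @param alpha_t K x L matrix of topic embeddings at one slice.
#' @param rho L x V word-embedding matrix.
#' @return K x V row-stochastic matrix.
#' @export
compute_beta <- function(alpha_t, rho) {
  if (is.null(dim(alpha_t))) alpha_t <- matrix(alpha_t, nrow = 1)
  stopifnot(ncol(alpha_t) == nrow(rho))
  if (!all(is.finite(alpha_t)) || !all(is.finite(rho)))
    stop("non-finite embeddings")
  softmax_rows(alpha_t %*% rho)
}

# beta for every slice: T x K x V array.
compute_beta_all <- function(params) {
  out <- array(0, dim = c(params$T, params$K, params$V))
  for (t in seq_len(params$T))
    out[t, , ] <- compute_beta(slice_mat(params$alpha, t, params$K, params$L), params$rho)
  out
}

#' Simulate random-walk trajectories for topic embeddings and prior means
#'
#' Draws the latent temporal structure of the model: slice 1 of each
#' trajectory from a standard Gaussian, and every later slice as the previous
#' slice plus Gaussian noise (`gamma` for topic embeddings, `delta` for the
#' topic-proportion prior means). With zero noise the trajectories are
#' constant over time.
#'
#' @param K,L,T_ number of topics, embedding dimension, number of slices.
#' @param delta,gamma non-negative random-walk standard deviations.
#' @param seed integer seed.
#' @return list with `alpha` (T x K x L array) and `eta` (T x K matrix).
#' @export
sample_dynamics <- function(K, L, T_, delta = 0.01, gamma = 0.01, seed = 1L) {
  stopifnot(delta >= 0, gamma >= 0, K >= 1, L >= 1, T_ >= 1)
  rng <- local_rng(seed)
  alpha <- array(0, dim = c(T_, K, L))
  alpha[1, , ] <- matrix(stats::rnorm(K * L), K, L)
  if (T_ > 1) for (t in 2:T_)
    alpha[t, , ] <- alpha[t - 1, , ] + gamma * matrix(stats::rnorm(K * L), K, L)
  eta <- matrix(0, T_, K)
  eta[1, ] <- stats::rnorm(K)
  if (T_ > 1) for (t in 2:T_)
    eta[t, ] <- eta[t - 1, ] + delta * stats::rnorm(K)
  list(alpha = alpha, eta = eta)
}

#' Marginal word distribution of a document
#'
#' Mixture distribution over the vocabulary obtained by marginalizing the
#' per-token topic assignment: `p(w) = sum_k theta_k * beta[k, w]`.
#'
#' @param theta_d length-K topic proportion on the simplex.
#' @param beta_t K x V row-stochastic topic-word matrix.
#' @return length-V probability vector.
#' @export
marginal_word_prob <- function(theta_d, beta_t) {
  stopifnot(length(theta_d) == nrow(beta_t))
  if (abs(sum(theta_d) - 1) > 1e-6 || any(theta_d < 0))
    stop("theta is not on the probability simplex")
  as.numeric(theta_d %*% beta_t)
}

#' Simulate a labeled time-sliced corpus from the generative model
#'
#' Samples documents slice by slice: for each document a topic proportion
#' `theta = softmax(N(eta_t, eps^2 I))` (logistic-normal), then per token a
#' topic `z ~ Cat(theta)` and a word `w ~ Cat(beta_z^t)`. Labels are attached
#' by `label_mechanism`; the default draws a fixed `M x K` Gaussian map `W`
#' once and labels each document `argmax(W %*% theta)`, so labels are
#' predictable from the topic proportions. All latent draws (true
#' parameters, theta, per-token z, labels, the label map) are recorded in the
#' returned `truth` for recovery testing.
#'
#' @param params a [tm_params()] object.
#' @param docs_per_slice integer vector of length T.
#' @param tokens_per_doc integer token count per document, or a function
#'   `(n_docs) -> integer vector` of document lengths.
#' @param n_labels number of label categories for the default mechanism.
#' @param label_mechanism `"argmax"` (deterministic) or `"softmax"` (a
#'   categorical draw from `softmax(W %*% theta / label_temp)`).
#' @param label_temp temperature for the `"softmax"` mechanism.
#' @param seed integer seed.
#' @return list with `corpus` (a [tm_corpus][new_tm_corpus]) and `truth`
#'   (class `tm_truth`: `params`, `theta`, `z`, `labels`, `label_map`,
#'   `mechanism`).
#' @export
sample_corpus <- function(params, docs_per_slice, tokens_per_doc = 60L,
                          n_labels = 5L,
                          label_mechanism = c("argmax", "softmax"),
                          label_temp = 0.5, seed = 1L) {
  label_mechanism <- match.arg(label_mechanism)
  stopifnot(length(docs_per_slice) == params$T)
  len_fun <- if (is.function(tokens_per_doc)) tokens_per_doc else {
    if (tokens_per_doc < 1) stop("tokens_per_doc must be at least 1")
    function(n) rep.int(as.integer(tokens_per_doc), n)
  }
  rng <- local_rng(seed)
  K <- params$K; V <- params$V
  label_map <- matrix(stats::rnorm(n_labels * K), n_labels, K)

  n_total <- sum(docs_per_slice)
  theta_all <- matrix(0, n_total, K)
  z_all <- vector("list", n_total)
  slice_all <- integer(n_total)
  lab_all <- integer(n_total)
  trip_i <- vector("list", n_total)
  trip_j <- vector("list", n_total)
  d <- 0L
  for (t in seq_len(params$T)) {
    if (docs_per_slice[t] == 0) next
    beta_t <- compute_beta(slice_mat(params$alpha, t, params$K, params$L), params$rho)
    lens <- len_fun(docs_per_slice[t])
    if (any(lens < 1)) stop("tokens_per_doc must be at least 1")
    for (j in seq_len(docs_per_slice[t])) {
      d <- d + 1L
      u <- params$eta[t, ] + params$eps * stats::rnorm(K)
      theta <- drop(softmax_rows(matrix(u, 1)))
      z <- sample.int(K, lens[j], replace = TRUE, prob = theta)
      w <- integer(lens[j])
      for (k in unique(z)) {
        sel <- z == k
        w[sel] <- sample.int(V, sum(sel), replace = TRUE, prob = beta_t[k, ])
      }
      theta_all[d, ] <- theta
      z_all[[d]] <- z
      slice_all[d] <- t
      trip_i[[d]] <- rep.int(d, lens[j])
      trip_j[[d]] <- w
      score <- drop(label_map %*% theta)
      lab_all[d] <- if (label_mechanism == "argmax") which.max(score) else
        sample.int(n_labels, 1, prob = drop(softmax_rows(matrix(score / label_temp, 1))))
    }
  }
  counts <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j), x = 1,
                                 dims = c(n_total, V))
  vocab <- if (!is.null(params$vocabulary)) params$vocabulary else
    sprintf("w%04d", seq_len(V))
  docs <- tibble::tibble(doc_id = sprintf("sim%06d", seq_len(n_total)),
                         slice = slice_all,
                         year = slice_all - 1L + 2000L,
                         label = lab_all)
  corpus <- new_tm_corpus(counts, docs, vocab,
                          label_names = sprintf("IC%02d", seq_len(n_labels)),
                          years = 2000L:(2000L + params$T - 1L))
  truth <- structure(list(params = params, theta = theta_all, z = z_all,
                          labels = lab_all, label_map = label_map,
                          mechanism = label_mechanism, seed = seed),
                     class = "tm_truth")
  list(corpus = corpus, truth = truth)
}

#' Random model parameters for simulation studies
#'
#' Convenience constructor drawing `rho` from a Gaussian and the temporal
#' trajectories from [sample_dynamics()].
#'
#' @param K,V,L,T_ dimensions.
#' @param eps,delta,gamma noise scales (defaults follow the model's standard
#'   setting of 0.01 for all three).
#' @param rho_sd standard deviation of word-embedding entries.
#' @param seed integer seed.
#' @return a [tm_params()] object.
#' @export
random_params <- function(K, V, L, T_, eps = 0.01, delta = 0.01, gamma = 0.01,
                          rho_sd = 1, seed = 1L) {
  rng <- local_rng(seed)
  rho <- matrix(stats::rnorm(L * V, sd = rho_sd), L, V)
  dyn <- sample_dynamics(K, L, T_, delta = delta, gamma = gamma,
                         seed = derive_seed(seed, "dynamics"))
  tm_params(rho, dyn$alpha, dyn$eta, eps = eps, delta = delta, gamma = gamma)
}
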