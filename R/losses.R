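#' Topic-diversity loss
#'
#' Sum over time slices and over unordered distinct topic pairs of the
#' Euclidean distance between topic embeddings,
#' `sum_t sum_{i<j} ||alpha_i^t - alpha_j^t||`. Training *rewards* this
#' quantity (it enters the minimized objective with a negative sign, see
#' [total_objective()]), pushing topic embeddings apart within every slice.
#' Zero exactly when all topics of a slice coincide; invariant under a joint
#' translation of all topic embeddings of a slice.
#'
#' @param alpha T x K x L array of topic embeddings (a plain K x L matrix is
#'   treated as a single slice).
#' @param distance distance between embedding rows; only `"euclidean"` is
#'   built in.
#' @return non-negative scalar.
#' @export
topic_diversity_loss <- function(alpha, distance = "euclidean") {
  if (length(dim(alpha)) == 2) alpha <- array(alpha, dim = c(1, dim(alpha)))
  stopifnot(distance == "euclidean")
  K <- dim(alpha)[2]
  if (K < 2) {
    warning("topic-diversity loss undefined for K < 2; returning 0")
    return(0)
  }
  total <- 0
  for (t in seq_len(dim(alpha)[1])) {
    at <- slice_mat(alpha, t, K, dim(alpha)[3])
    total <- total + sum(stats::dist(at))
  }
  total
}

# Gradient of topic_diversity_loss w.r.t. alpha (same shaped array).
topic_diversity_grad <- function(alpha) {
  K <- dim(alpha)[2]; L <- dim(alpha)[3]
  g <- array(0, dim = dim(alpha))
  if (K < 2) return(g)
  for (t in seq_len(dim(alpha)[1])) {
    at <- slice_mat(alpha, t, K, L)
    gt <- matrix(0, K, L)
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      diff <- at[i, ] - at[j, ]
      nrm <- sqrt(sum(diff^2))
      if (nrm > 1e-12) {
        gt[i, ] <- gt[i, ] + diff / nrm
        gt[j, ] <- gt[j, ] - diff / nrm
      }
    }
    g[t, , ] <- gt
  }
  g
}

#' Label-classification loss
#'
#' Mean categorical cross-entropy of the classifier head's softmaxed scores
#' against the document labels: the model is encouraged to infer topic
#' proportions from which the funding label is predictable. Equals `log(M)`
#' for a scorer that is constant across classes.
#'
#' @param theta_batch B x K matrix of topic proportions (rows on the
#'   simplex).
#' @param labels integer vector in `1..M`.
#' @param head classifier head created by the fitting routine (fields `Wc1`,
#'   `bc1`, `Wc2`, `bc2`, `M`).
#' @return non-negative scalar.
#' @export
ic_classification_loss <- function(theta_batch, labels, head) {
  if (is.null(dim(theta_batch))) theta_batch <- matrix(theta_batch, nrow = 1)
  if (any(labels < 1L) || any(labels > head$M))
    stop("label out of range 1..M")
  cache <- clf_forward(theta_batch, head)
  logp <- cache$O - apply(cache$O, 1, function(o) max(o) + log(sum(exp(o - max(o)))))
  -mean(logp[cbind(seq_along(labels), labels)])
}

#' Combined multitask training objective
#'
#' The scalar the optimizer minimizes:
#' `-ELBO + dynamics_penalty - lambda1 * TD + lambda2 * CE`.
#' Minimizing it maximizes the evidence lower bound and the topic-diversity
#' reward while minimizing the classification cross-entropy; the random-walk
#' priors on the topic embeddings and proportion means enter as the
#' (MAP) dynamics penalty.
#'
#' @param elbo evidence lower bound (to be maximized).
#' @param td topic-diversity loss value, see [topic_diversity_loss()].
#' @param ce classification cross-entropy, see [ic_classification_loss()].
#' @param dynamics_penalty random-walk negative log-prior, see
#'   [dynamics_penalty()].
#' @param lambda1,lambda2 non-negative multitask weights (defaults 1 and
#'   0.5).
#' @return scalar to minimize.
#' @export
total_objective <- function(elbo, td, ce, dynamics_penalty = 0,
                            lambda1 = 1, lambda2 = 0.5) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  -elbo + dynamics_penalty - lambda1 * td + lambda2 * ce
}
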