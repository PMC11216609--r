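#' Normalized word-probability trend within a topic
#'
#' For each requested word, the per-slice generative probability
#' `beta^t_{k, word}` divided by its value at `base_slice`, so every series
#' equals 1 at the base slice and the plot shows relative growth or decline
#' of the word inside the topic over time.
#'
#' @param object a `topic_fit` or [tm_params()] with a vocabulary.
#' @param words character vector of words to trace.
#' @param topic topic index `k`.
#' @param base_slice slice whose probability defines the normalization
#'   (default 1, the earliest).
#' @return tibble of class `tm_trend` with columns `word`, `topic`, `slice`,
#'   `year`, `beta`, `value` (normalized).
#' @export
word_trend <- function(object, words, topic = 1L, base_slice = 1L) {
  params <- if (inherits(object, "topic_fit")) object$params else object
  years <- if (inherits(object, "topic_fit")) object$years else
    seq_len(params$T)
  vocab <- params$vocabulary
  if (is.null(vocab)) vocab <- sprintf("w%04d", seq_len(params$V))
  stopifnot(topic >= 1, topic <= params$K,
            base_slice >= 1, base_slice <= params$T)
  missing_w <- setdiff(words, vocab)
  if (length(missing_w) > 0) {
    near <- vapply(missing_w, function(w) {
      d <- utils::adist(w, vocab)
      paste(vocab[order(d)[1:3]], collapse = ", ")
    }, character(1))
    stop("word(s) not in vocabulary: ",
         paste(sprintf("%s (nearest: %s)", missing_w, near), collapse = "; "))
  }
  beta <- compute_beta_all(params)
  out <- purrr::map_dfr(words, function(w) {
    j <- match(w, vocab)
    series <- beta[, topic, j]
    tibble::tibble(word = w, topic = topic, slice = seq_len(params$T),
                   year = years, beta = series,
                   value = series / series[base_slice])
  })
  class(out) <- c("tm_trend", class(out))
  attr(out, "base_slice") <- base_slice
  out
}

#' Cross-resolution topic hierarchy between two models
#'
#' Relates the topics of two models trained on a shared vocabulary (for
#' instance a coarse 5-topic and a finer 10-topic model) by the Pearson
#' correlation of their time-averaged topic vectors: in `"beta"` space the
#' topic-word distributions (default, always comparable across models), in
#' `"alpha"` space the topic embeddings (meaningful only when both models
#' share a fixed embedding table). For every parent topic of `a` the
#' `top_links` most similar child topics of `b` are returned, with the full
#' similarity matrix attached as attribute `"matrix"`.
#'
#' @param a,b `topic_fit` or [tm_params()] objects.
#' @param space `"beta"` or `"alpha"`.
#' @param top_links children per parent to keep.
#' @return tibble with columns `parent`, `child`, `similarity`, `rank`;
#'   attribute `"matrix"` holds the `K_a x K_b` correlation matrix.
#' @export
topic_hierarchy <- function(a, b, space = c("beta", "alpha"), top_links = 3L) {
  space <- match.arg(space)
  pa <- if (inherits(a, "topic_fit")) a$params else a
  pb <- if (inherits(b, "topic_fit")) b$params else b
  va <- topic_vectors(pa, space); vb <- topic_vectors(pb, space)
  if (ncol(va) != ncol(vb))
    stop(if (space == "beta") "models do not share a vocabulary"
         else "models do not share an embedding dimension")
  sim <- stats::cor(t(va), t(vb))
  links <- purrr::map_dfr(seq_len(nrow(sim)), function(i) {
    ord <- order(-sim[i, ])[seq_len(min(top_links, ncol(sim)))]
    tibble::tibble(parent = i, child = ord, similarity = sim[i, ord],
                   rank = seq_along(ord))
  })
  attr(links, "matrix") <- sim
  links
}

topic_vectors <- function(params, space) {
  if (space == "beta") {
    beta <- compute_beta_all(params)
    matrix(apply(beta, c(2, 3), mean), params$K, params$V)
  } else {
    matrix(apply(params$alpha, c(2, 3), mean), params$K, params$L)
  }
}

#' Topic-proportion features for every document
#'
#' Deterministic per-document features: the variational posterior mean
#' `theta = softmax(mu(d))` from the amortized encoder (no sampling), one
#' row per document on the K-simplex, alongside the document label. Empty
#' documents are excluded and counted in the `n_excluded` attribute.
#'
#' @param corpus a [tm_corpus][new_tm_corpus].
#' @param fit a `topic_fit`.
#' @return tibble with `doc_id`, `slice`, `label`, and `theta_1..theta_K`;
#'   attribute `n_excluded`.
#' @export
extract_topic_features <- function(corpus, fit) {
  params <- fit$params
  keep <- Matrix::rowSums(corpus$counts) > 0
  n_excluded <- sum(!keep)
  theta <- matrix(0, sum(keep), params$K)
  kept_idx <- which(keep)
  sl <- corpus$docs$slice[kept_idx]
  for (t in unique(sl)) {
    rows <- kept_idx[sl == t]
    it <- infer_theta(corpus$counts[rows, , drop = FALSE], fit$encoder,
                      params$eta[min(t, params$T), ])
    theta[match(rows, kept_idx), ] <- softmax_rows(it$mu)
  }
  out <- tibble::as_tibble(stats::setNames(as.data.frame(theta),
                                           paste0("theta_", seq_len(params$K))))
  out <- dplyr::bind_cols(
    tibble::tibble(doc_id = corpus$docs$doc_id[kept_idx],
                   slice = sl, label = corpus$docs$label[kept_idx]), out)
  attr(out, "n_excluded") <- n_excluded
  out
}

theta_matrix <- function(features) {
  as.matrix(dplyr::select(features, dplyr::starts_with("theta_")))
}

#' Label classification from topic-proportion features
#'
#' Trains a seeded classifier (random forest by default) on training
#' features and reports top-k accuracy on test features: the fraction of
#' test documents whose true label is among the k highest-probability
#' classes. Labels present only in the test set are necessarily misses and
#' are reported in the `unseen_labels` attribute.
#'
#' @param features_train,features_test tibbles from
#'   [extract_topic_features()] (or any data frame with `theta_*` columns
#'   and a `label` column).
#' @param ks integer vector of k values (default `c(1, 5)`).
#' @param classifier `"rf"` for a random forest, or a function
#'   `(x_train, y_train, x_test) -> probability matrix` with one column per
#'   training class (named by class).
#' @param n_trees trees for the random forest.
#' @param seed seed for the classifier.
#' @return tibble with columns `k` and `accuracy`, non-decreasing in `k`.
#' @export
classify_labels <- function(features_train, features_test, ks = c(1L, 5L),
                            classifier = "rf", n_trees = 200L, seed = 1L) {
  x_tr <- theta_matrix(features_train); y_tr <- features_train$label
  x_te <- theta_matrix(features_test); y_te <- features_test$label
  stopifnot(ncol(x_tr) == ncol(x_te), length(ks) > 0, all(ks >= 1))
  unseen <- setdiff(unique(y_te), unique(y_tr))
  prob <- if (is.function(classifier)) {
    classifier(x_tr, y_tr, x_te)
  } else if (identical(classifier, "rf")) {
    if (length(unique(y_tr)) < 2) {
      # degenerate training set: a single observed class
      matrix(1, nrow(x_te), 1,
             dimnames = list(NULL, as.character(y_tr[1])))
    } else {
      rng <- local_rng(seed)
      rf <- randomForest::randomForest(x = x_tr, y = factor(y_tr),
                                       ntree = n_trees)
      stats::predict(rf, x_te, type = "prob")
    }
  } else stop("unknown classifier: ", classifier)
  classes <- colnames(prob)
  res <- purrr::map_dfr(sort(unique(as.integer(ks))), function(k) {
    kk <- min(k, ncol(prob))
    hit <- vapply(seq_len(nrow(prob)), function(i) {
      topk <- classes[order(-prob[i, ])[seq_len(kk)]]
      as.character(y_te[i]) %in% topk
    }, logical(1))
    tibble::tibble(k = k, accuracy = mean(hit))
  })
  attr(res, "unseen_labels") <- unseen
  res
}

#' Two-dimensional embedding of topic-proportion features
#'
#' Projects the per-document topic proportions to 2-D by classical
#' multidimensional scaling on Euclidean distances (deterministic;
#' documents with identical proportions land on identical coordinates), for
#' visualizing how documents with different labels separate in topic space.
#'
#' @param features tibble from [extract_topic_features()].
#' @param seed accepted for interface stability; the embedding is
#'   deterministic and ignores it.
#' @return tibble of class `tm_embedding` with `doc_id`, `label`, `dim1`,
#'   `dim2`.
#' @export
embed_theta_2d <- function(features, seed = 1L) {
  x <- theta_matrix(features)
  if (nrow(x) < 10) stop("need at least 10 documents to embed; got ", nrow(x))
  xy <- stats::cmdscale(stats::dist(x), k = 2)
  out <- tibble::tibble(doc_id = features$doc_id, label = features$label,
                        dim1 = xy[, 1], dim2 = xy[, 2])
  class(out) <- c("tm_embedding", class(out))
  out
}

#' Match estimated topics to simulated truth
#'
#' Finds the one-to-one topic assignment maximizing total cosine similarity
#' between time-averaged true and estimated topic-word distributions
#' (exhaustive over permutations for small K), and reports the matched
#' per-topic beta cosines and, when the corpus is supplied, the mean
#' per-document cosine between true and matched inferred proportions.
#'
#' @param truth `tm_truth` from [sample_corpus()].
#' @param fit a `topic_fit`.
#' @param corpus the simulated corpus (for the theta comparison); optional.
#' @return list with `perm` (estimated topic matched to each true topic),
#'   `beta_cosine` (per-topic), `mean_beta_cosine`, and (with `corpus`)
#'   `mean_theta_cosine`.
#' @export
evaluate_recovery <- function(truth, fit, corpus = NULL) {
  bt <- compute_beta_all(truth$params)
  bf <- compute_beta_all(fit$params)
  K <- truth$params$K
  mt <- matrix(apply(bt, c(2, 3), mean), K, truth$params$V)
  mf <- matrix(apply(bf, c(2, 3), mean), fit$params$K, fit$params$V)
  stopifnot(K == fit$params$K)
  sim <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    sim[i, j] <- cosine_sim(mt[i, ], mf[j, ])
  perm <- best_assignment(sim)
  out <- list(perm = perm, beta_cosine = sim[cbind(seq_len(K), perm)],
              mean_beta_cosine = mean(sim[cbind(seq_len(K), perm)]))
  if (!is.null(corpus)) {
    feats <- extract_topic_features(corpus, fit)
    th_hat <- theta_matrix(feats)[, perm, drop = FALSE]
    cs <- vapply(seq_len(nrow(th_hat)), function(d)
      cosine_sim(th_hat[d, ], truth$theta[d, ]), numeric(1))
    out$mean_theta_cosine <- mean(cs)
  }
  out
}
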