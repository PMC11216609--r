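#' Co-occurrence statistics for coherence evaluation
#'
#' Counts, over a reference collection, how many units contain each word and
#' each word pair. Units are whole documents (`window = NULL`) or sliding
#' context windows of width `window` over token sequences. Document-level
#' counts can be built from a [tm_corpus][new_tm_corpus] (bag-of-words) or
#' from token streams; window-level counts require token streams, since a
#' bag of words has no token order. A word is counted once per unit however
#' often it occurs inside it.
#'
#' @param reference a `tm_corpus`, or a list of character vectors (one token
#'   stream per document).
#' @param window `NULL` for document-level counting, or an integer window
#'   width `>= 2`. A document shorter than the window contributes a single
#'   window.
#' @return object of class `tm_cooc` with fields `vocab`, `doc_freq`
#'   (named counts), `joint` (sparse symmetric pair-count matrix),
#'   `n_units`, and `mode` (`"document"` or `"window"`).
#' @export
build_cooccurrence <- function(reference, window = NULL) {
  if (!is.null(window)) {
    if (window < 2) stop("window width must be at least 2")
    if (inherits(reference, "tm_corpus"))
      stop("window-level counting needs token streams; a bag-of-words corpus has no token order")
  }
  if (inherits(reference, "tm_corpus")) {
    pat <- 1 * (reference$counts > 0)
    vocab <- reference$vocabulary
    df <- Matrix::colSums(pat)
    joint <- Matrix::crossprod(pat)
    n_units <- nrow(pat)
    mode <- "document"
  } else {
    stopifnot(is.list(reference), length(reference) > 0)
    vocab <- sort(unique(unlist(reference, use.names = FALSE)))
    units <- list()
    if (is.null(window)) {
      units <- lapply(reference, unique)
      mode <- "document"
    } else {
      for (tk in reference) {
        n <- length(tk)
        if (n == 0) next
        if (n <= window) units[[length(units) + 1L]] <- unique(tk)
        else for (s in seq_len(n - window + 1))
          units[[length(units) + 1L]] <- unique(tk[s:(s + window - 1)])
      }
      mode <- "window"
    }
    if (length(units) == 0) stop("empty reference: no counting units")
    i_idx <- rep.int(seq_along(units), vapply(units, length, integer(1)))
    j_idx <- match(unlist(units, use.names = FALSE), vocab)
    pat <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1,
                                dims = c(length(units), length(vocab)))
    df <- Matrix::colSums(pat)
    joint <- Matrix::crossprod(pat)
    n_units <- length(units)
  }
  names(df) <- vocab
  dimnames(joint) <- list(vocab, vocab)
  structure(list(vocab = vocab, doc_freq = df, joint = joint,
                 n_units = n_units, mode = mode),
            class = "tm_cooc")
}

# Marginal and joint probabilities for a word pair; NA marginal for words
# absent from the reference.
pair_probs <- function(wi, wj, stats) {
  pi_ <- unname(stats$doc_freq[wi] / stats$n_units)
  pj <- unname(stats$doc_freq[wj] / stats$n_units)
  pij <- if (is.na(pi_) || is.na(pj)) NA_real_ else
    unname(stats$joint[wi, wj] / stats$n_units)
  list(pi = pi_, pj = pj, pij = pij)
}

#' Normalized pointwise mutual information of a word pair
#'
#' `NPMI(i, j) = log((P(i,j) + s) / (P(i) P(j))) / (-log(P(i,j) + s))` with
#' unit probabilities from `stats` and smoothing `s`. Bounded in (-1, 1]:
#' 1 for a pair that always co-occurs (up to smoothing), 0 for independent
#' words, approaching -1 for words that never co-occur as `s -> 0`.
#'
#' @param pair character vector of two words.
#' @param stats a [build_cooccurrence()] result.
#' @param smoothing small constant added to the joint probability.
#' @param strict if `TRUE`, a word missing from the reference is an error;
#'   otherwise the value is 0 with a warning.
#' @return scalar in `[-1, 1]`.
#' @export
npmi <- function(pair, stats, smoothing = 1e-12, strict = FALSE) {
  stopifnot(length(pair) == 2)
  pr <- pair_probs(pair[1], pair[2], stats)
  if (is.na(pr$pij) || pr$pi == 0 || pr$pj == 0) {
    msg <- paste0("word(s) absent from reference: ",
                  paste(pair[is.na(stats$doc_freq[pair]) | stats$doc_freq[pair] == 0],
                        collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; NPMI set to 0")
    return(0)
  }
  log((pr$pij + smoothing) / (pr$pi * pr$pj)) / (-log(pr$pij + smoothing))
}

# Fitelson confirmation m_p = [P(j|i) - P(j|~i)] / [P(j|i) + P(j|~i)].
fitelson_cp <- function(pair, stats, smoothing = 1e-12) {
  pr <- pair_probs(pair[1], pair[2], stats)
  if (is.na(pr$pij) || pr$pi == 0 || pr$pj == 0) return(0)
  p_given <- pr$pij / pr$pi
  p_not <- if (pr$pi >= 1) 0 else (pr$pj - pr$pij) / (1 - pr$pi)
  if (p_given + p_not < smoothing) return(0)
  (p_given - p_not) / (p_given + p_not)
}

#' Topic coherence of top-word lists
#'
#' Mean pairwise association of each topic's top-`p` words over unordered
#' distinct pairs, under one of three confirmation measures: `"npmi"`
#' (document-level NPMI), `"ca"` (NPMI on sliding-window statistics — pass
#' `stats` built with a window), and `"cp"` (Fitelson's confirmation on
#' document-level statistics). For asymmetric `"cp"` the higher-ranked word
#' of each pair plays the conditioning role.
#'
#' @param top_words character vector (one topic) or list of character
#'   vectors (one per topic) of ranked top words.
#' @param stats a [build_cooccurrence()] result (window-level for `"ca"`).
#' @param measure `"ca"`, `"cp"` or `"npmi"`.
#' @param smoothing smoothing constant, see [npmi()].
#' @return numeric vector of per-topic coherence scores.
#' @export
topic_coherence <- function(top_words, stats, measure = c("npmi", "ca", "cp"),
                            smoothing = 1e-12) {
  measure <- match.arg(measure)
  if (!is.list(top_words)) top_words <- list(top_words)
  if (measure == "ca" && stats$mode != "window")
    warning("CA coherence is defined on window statistics; using the supplied ",
            stats$mode, "-level counts")
  if (measure != "ca" && stats$mode != "document")
    warning(measure, " coherence is defined on document statistics; using the supplied ",
            stats$mode, "-level counts")
  f <- switch(measure,
              npmi = function(p) npmi(p, stats, smoothing),
              ca = function(p) npmi(p, stats, smoothing),
              cp = function(p) fitelson_cp(p, stats, smoothing))
  vapply(top_words, function(ws) {
    ws <- ws[!duplicated(ws)]
    if (length(ws) < 2) {
      warning("topic with fewer than 2 distinct words; coherence NA")
      return(NA_real_)
    }
    vals <- c()
    for (i in seq_len(length(ws) - 1)) for (j in (i + 1):length(ws))
      vals <- c(vals, f(c(ws[i], ws[j])))
    mean(vals)
  }, numeric(1))
}

#' Topic diversity of top-word lists
#'
#' Fraction of distinct words among the `K * p` top words pooled over all
#' `K` topics: 1 when every list is disjoint, `1/K` when all lists
#' coincide.
#'
#' @param top_lists list of `K` character vectors, each of the same length
#'   `p`.
#' @return scalar in `[1/K, 1]`.
#' @export
topic_diversity <- function(top_lists) {
  stopifnot(is.list(top_lists), length(top_lists) >= 1)
  p <- unique(vapply(top_lists, length, integer(1)))
  if (length(p) != 1) stop("ragged top-word lists: all topics must supply the same p")
  length(unique(unlist(top_lists))) / (length(top_lists) * p)
}

#' Ranked top words of every topic
#'
#' Extracts each topic's `p` highest-probability words from `beta`,
#' time-averaged over slices unless one `slice` is requested. Ties are
#' broken deterministically (stable order, lexicographic on equal
#' probability).
#'
#' @param object a `topic_fit` or [tm_params()].
#' @param p words per topic.
#' @param slice optional slice index; default averages `beta` over slices.
#' @return tibble with columns `topic`, `rank`, `term`, `beta`.
#' @export
top_words <- function(object, p = 10L, slice = NULL) {
  params <- if (inherits(object, "topic_fit")) object$params else object
  stopifnot(inherits(params, "tm_params"))
  beta <- compute_beta_all(params)
  bmat <- if (is.null(slice)) {
    matrix(apply(beta, c(2, 3), mean), params$K, params$V)
  } else {
    stopifnot(slice >= 1, slice <= params$T)
    slice_mat(beta, slice, params$K, params$V)
  }
  vocab <- if (!is.null(params$vocabulary)) params$vocabulary else
    sprintf("w%04d", seq_len(params$V))
  purrr::map_dfr(seq_len(params$K), function(k) {
    ord <- order(-bmat[k, ], vocab)[seq_len(min(p, params$V))]
    tibble::tibble(topic = k, rank = seq_along(ord), term = vocab[ord],
                   beta = bmat[k, ord])
  })
}

# top_words as a plain list of character vectors (metrics input).
top_word_lists <- function(object, p = 10L, slice = NULL) {
  tw <- top_words(object, p = p, slice = slice)
  split(tw$term, tw$topic)
}

#' Held-out perplexity by document completion
#'
#' Splits each test document in half by alternating token positions (tokens
#' enumerated in vocabulary order), infers the topic proportions from the
#' first half via the variational mean `softmax(mu)`, and scores the second
#' half under the mixture `sum_k theta_k beta^t_{k, w}`. Perplexity is
#' `exp(-total log-likelihood / tokens scored)`; a uniform model scores
#' exactly `V` on any corpus. Documents too short to split are excluded and
#' counted in the `n_excluded` attribute. `protocol = "bound"` instead
#' exponentiates the negative full-document ELBO per token.
#'
#' @param test a [tm_corpus][new_tm_corpus]; its vocabulary must equal the
#'   model's.
#' @param params a [tm_params()].
#' @param encoder fitted encoder state.
#' @param protocol `"completion"` (default) or `"bound"`.
#' @param seed seed for the `"bound"` protocol's Monte-Carlo draw.
#' @return positive scalar with attribute `n_excluded`.
#' @export
perplexity <- function(test, params, encoder, protocol = c("completion", "bound"),
                       seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(test, "tm_corpus"))
  if (length(test$vocabulary) != params$V)
    stop("test vocabulary incompatible with the model")
  beta <- compute_beta_all(params)
  if (protocol == "bound") {
    ll <- corpus_elbo(test, params, encoder, seed = seed)
    return(structure(exp(-ll / sum(test$counts)), n_excluded = 0L))
  }
  total_ll <- 0; total_tokens <- 0; n_excluded <- 0L
  X <- as.matrix(test$counts)
  for (d in seq_len(nrow(X))) {
    tokens <- rep.int(seq_len(ncol(X)), X[d, ])
    if (length(tokens) < 2) { n_excluded <- n_excluded + 1L; next }
    first <- tokens[seq(1, length(tokens), by = 2)]
    second <- tokens[seq(2, length(tokens), by = 2)]
    half <- tabulate(first, nbins = params$V)
    t_d <- test$docs$slice[d]
    it <- infer_theta(half, encoder, params$eta[t_d, ], n_samples = 1,
                      seed = seed)
    theta <- drop(softmax_rows(it$mu))
    probs <- drop(theta %*% slice_mat(beta, t_d, params$K, params$V))
    total_ll <- total_ll + sum(log(probs[second]))
    total_tokens <- total_tokens + length(second)
  }
  if (total_tokens == 0) stop("no document long enough to split")
  structure(exp(-total_ll / total_tokens), n_excluded = n_excluded)
}

#' Topic-quality report
#'
#' Computes the standard topic-quality battery for a fitted model: per-topic
#' coherence under the requested measures, topic diversity over the pooled
#' top words, and held-out perplexity. The co-occurrence reference defaults
#' to document-level statistics of `reference` (conventionally the training
#' split); sliding-window statistics for the CA measure are built from
#' `reference_tokens` when token streams are available, otherwise CA falls
#' back to document-level counts with a warning.
#'
#' @param fit a `topic_fit`.
#' @param test held-out [tm_corpus][new_tm_corpus] for perplexity (optional).
#' @param reference `tm_corpus` providing co-occurrence statistics; defaults
#'   to `test`.
#' @param reference_tokens optional list of token streams for window
#'   statistics.
#' @param measures subset of `c("ca", "cp", "npmi")`.
#' @param p_coherence top words per topic for coherence (default 10).
#' @param p_diversity top words per topic for diversity (default 25).
#' @param window window width for CA statistics (default 5).
#' @return object of class `topic_quality`: tibble `per_topic`, named list
#'   `summary` (mean coherences, `td`, `perplexity`), and the settings used.
#' @export
evaluate_topics <- function(fit, test = NULL, reference = NULL,
                            reference_tokens = NULL,
                            measures = c("ca", "cp", "npmi"),
                            p_coherence = 10L, p_diversity = 25L,
                            window = 5L) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.null(reference)) reference <- test
  if (is.null(reference)) stop("need a reference corpus (or test corpus) for coherence")
  doc_stats <- build_cooccurrence(reference)
  win_stats <- if (!is.null(reference_tokens))
    build_cooccurrence(reference_tokens, window = window) else NULL
  lists_c <- top_word_lists(fit, p = p_coherence)
  lists_d <- top_word_lists(fit, p = p_diversity)
  per_topic <- purrr::map_dfr(measures, function(ms) {
    st <- if (ms == "ca" && !is.null(win_stats)) win_stats else doc_stats
    sc <- suppressWarnings(topic_coherence(lists_c, st, measure = ms))
    tibble::tibble(topic = seq_along(sc), measure = ms, coherence = sc)
  })
  summary <- as.list(tapply(per_topic$coherence, per_topic$measure, mean))
  summary$td <- topic_diversity(lists_d)
  summary$perplexity <- if (!is.null(test))
    as.numeric(perplexity(test, fit$params, fit$encoder)) else NA_real_
  structure(list(per_topic = per_topic, summary = summary,
                 p_coherence = p_coherence, p_diversity = p_diversity,
                 window = window, top_words = lists_c),
            class = "topic_quality")
}

#' @export
print.topic_quality <- function(x, ...) {
  cat("<topic_quality>\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-10s %s\n", nm,
                ifelse(is.na(x$summary[[nm]]), "NA",
                       format(x$summary[[nm]], digits = 4))))
  invisible(x)
}
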