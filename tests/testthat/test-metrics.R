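test_that("document and window co-occurrence counts are exact", {
  stats <- build_cooccurrence(list(c("a", "b"), c("a", "c")))
  expect_equal(stats$doc_freq[["a"]], 2)
  expect_equal(stats$doc_freq[["b"]], 1)
  expect_equal(stats$joint["a", "b"], 1)
  expect_equal(stats$joint["b", "c"], 0)
  expect_equal(stats$n_units, 2)

  w <- build_cooccurrence(list(c("a", "b", "a")), window = 2)
  expect_equal(w$n_units, 2)              # windows {a,b}, {b,a}
  expect_equal(w$joint["a", "b"], 2)
  expect_error(build_cooccurrence(list(c("a", "b")), window = 1), "window")
  expect_error(build_cooccurrence(toy_corpus(), window = 3), "token")

  # brute-force scan over a random 30-document reference
  set.seed(31)
  docs <- replicate(30, sample(letters[1:8], sample(2:6, 1), replace = TRUE),
                    simplify = FALSE)
  st <- build_cooccurrence(docs)
  bc <- brute_cooc(lapply(docs, unique))
  expect_equal(unname(st$doc_freq[bc$vocab]), unname(bc$df))
  for (i in 1:7) for (j in (i + 1):8) {
    wi <- letters[i]; wj <- letters[j]
    expect_equal(st$joint[wi, wj], bc$joint[wi, wj])
  }

  # window counts against enumerated sliding windows
  stw <- build_cooccurrence(docs, window = 3)
  units <- unlist(lapply(docs, brute_windows, w = 3), recursive = FALSE)
  bcw <- brute_cooc(units)
  expect_equal(stw$n_units, bcw$n)
  expect_equal(unname(stw$doc_freq[bcw$vocab]), unname(bcw$df))
})

test_that("NPMI has its analytic fixed points and matches the direct formula", {
  # perfect association: each word in half the docs, always together
  s2 <- build_cooccurrence(list(c("x", "y"), c("x", "y"), "z", "z"))
  expect_equal(npmi(c("x", "y"), s2), 1, tolerance = 1e-9)

  # exact independence on a constructed 8-document corpus:
  # P(i) = P(j) = 1/2, P(i,j) = 1/4
  docs8 <- list(c("i", "j"), c("i", "j"), "i", "i", "j", "j", "o", "o")
  s8 <- build_cooccurrence(docs8)
  expect_equal(npmi(c("i", "j"), s8), 0, tolerance = 1e-9)

  # 6-document toy corpus with counts df(a)=3, df(b)=4, joint=2
  docs6 <- list(c("a", "b"), c("a", "b"), c("a"), c("b"), c("b"), c("o"))
  s6 <- build_cooccurrence(docs6)
  s <- 1e-12
  hand <- log((2 / 6 + s) / ((3 / 6) * (4 / 6))) / (-log(2 / 6 + s))
  expect_equal(npmi(c("a", "b"), s6), hand, tolerance = 1e-12)

  # symmetry, bounds, monotonicity in the joint count
  expect_equal(npmi(c("a", "b"), s6), npmi(c("b", "a"), s6))
  expect_gte(npmi(c("a", "b"), s6), -1); expect_lte(npmi(c("a", "b"), s6), 1)
  docs6b <- list(c("a", "b"), c("a", "b"), c("a", "b"), c("b"), c("a"), c("o"))
  expect_gt(npmi(c("a", "b"), build_cooccurrence(docs6b)), npmi(c("a", "b"), s6))

  # never co-occurring pair tends to -1 as smoothing vanishes
  expect_lt(npmi(c("a", "o"), s6, smoothing = 1e-300), -0.99)

  # absent word: 0 with warning; strict mode fails
  expect_warning(v <- npmi(c("a", "zzz"), s6), "absent")
  expect_equal(v, 0)
  expect_error(npmi(c("a", "zzz"), s6, strict = TRUE), "absent")
})

test_that("coherence equals exhaustive pair enumeration on a toy corpus", {
  docs <- lapply(strsplit(c("a b c", "a b", "a c d", "b d", "c d a", "b c"),
                          " "), identity)
  st <- build_cooccurrence(docs)
  bc <- brute_cooc(lapply(docs, unique))
  top3 <- c("a", "b", "c")
  pairs <- utils::combn(3, 2)
  or_npmi <- mean(sapply(seq_len(ncol(pairs)), function(i)
    brute_npmi(top3[pairs[1, i]], top3[pairs[2, i]], bc)))
  or_cp <- mean(sapply(seq_len(ncol(pairs)), function(i)
    brute_cp(top3[pairs[1, i]], top3[pairs[2, i]], bc)))
  expect_equal(topic_coherence(top3, st, "npmi"), or_npmi, tolerance = 1e-12)
  expect_equal(topic_coherence(top3, st, "cp"), or_cp, tolerance = 1e-12)

  # CA: same confirmation on window statistics
  stw <- build_cooccurrence(docs, window = 2)
  bcw <- brute_cooc(unlist(lapply(docs, brute_windows, w = 2), recursive = FALSE))
  or_ca <- mean(sapply(seq_len(ncol(pairs)), function(i)
    brute_npmi(top3[pairs[1, i]], top3[pairs[2, i]], bcw)))
  expect_equal(topic_coherence(top3, stw, "ca"), or_ca, tolerance = 1e-12)

  # maximal coherence: a set of words that always co-occur
  stm <- build_cooccurrence(list(c("p", "q", "r"), c("p", "q", "r"), "z"))
  expect_equal(unname(topic_coherence(c("p", "q", "r"), stm, "npmi")), 1,
               tolerance = 1e-9)
  expect_warning(topic_coherence(c("a", "a"), st, "npmi"), "fewer than 2")
})

test_that("topic diversity counts unique words over pooled top lists", {
  expect_equal(topic_diversity(list(c("a", "b"), c("c", "d"))), 1)
  expect_equal(topic_diversity(list(c("a", "b"), c("a", "b"))), 0.5)
  set.seed(33)
  lists <- replicate(3, sample(letters[1:8], 4), simplify = FALSE)
  expect_equal(topic_diversity(lists),
               length(unique(unlist(lists))) / 12)
  # order within lists is irrelevant
  expect_equal(topic_diversity(lapply(lists, rev)), topic_diversity(lists))
  expect_error(topic_diversity(list(c("a", "b"), c("c"))), "ragged")
})

test_that("top words are ranked deterministically with lexicographic ties", {
  rho <- matrix(0, 2, 4)            # all-equal beta: pure tie-break
  alpha <- array(0, dim = c(1, 2, 2))
  params <- tm_params(rho, alpha, matrix(0, 1, 2),
                      vocabulary = c("delta", "alpha", "charlie", "bravo"))
  tw <- top_words(params, p = 4)
  expect_equal(tw$term[tw$topic == 1],
               c("alpha", "bravo", "charlie", "delta"))
  fit <- fit_small()
  tw2 <- top_words(fit, p = 5)
  expect_equal(nrow(tw2), 15)
  expect_true(all(tapply(tw2$beta, tw2$topic, function(b) all(diff(b) <= 0))))
})

test_that("uniform models have perplexity exactly V", {
  V <- 100
  params <- random_params(K = 2, V = V, L = 4, T_ = 2, eps = 1, seed = 5)
  params$alpha[] <- 0               # beta uniform on every slice
  sim <- sample_corpus(params, c(15, 15), tokens_per_doc = 20, seed = 6)
  enc <- topicdrift:::init_encoder(V, 2, hidden = c(8, 8), seed = 1)
  expect_equal(as.numeric(perplexity(sim$corpus, params, enc)), V,
               tolerance = 1e-9)
})

test_that("a matched single-topic model attains the test entropy", {
  # one topic whose beta equals the empirical test unigram distribution
  sim <- sample_corpus(random_params(K = 2, V = 30, L = 4, T_ = 1, eps = 1, seed = 7),
                       docs_per_slice = 40L, tokens_per_doc = 30L, seed = 8)
  test <- sim$corpus
  freq <- (Matrix::colSums(test$counts) + 0.5) / (sum(test$counts) + 15)
  # build a K=1-equivalent model: two identical topics with beta = freq
  L <- 29
  rho <- rbind(log(freq), matrix(0, L - 1, 30))
  alpha <- array(0, dim = c(1, 2, L)); alpha[1, , 1] <- 1
  params <- tm_params(rho, alpha, matrix(0, 1, 2), eps = 1)
  enc <- topicdrift:::init_encoder(30, 2, hidden = c(8, 8), seed = 2)
  beta <- compute_beta(matrix(alpha[1, , ], 2, L), rho)
  expect_equal(beta[1, ], freq, ignore_attr = TRUE, tolerance = 1e-12)
  # alternating split scores exactly the unigram model on every half
  ppl <- perplexity(test, params, enc)
  # compare against entropy of the scored second halves
  X <- as.matrix(test$counts)
  ll <- 0; n <- 0
  for (d in seq_len(nrow(X))) {
    tokens <- rep(seq_len(30), X[d, ])
    second <- tokens[seq(2, length(tokens), by = 2)]
    ll <- ll + sum(log(freq[second])); n <- n + length(second)
  }
  expect_equal(as.numeric(ppl), exp(-ll / n), tolerance = 1e-10)
})

test_that("perplexity matches a hand computation on a 3-document test set", {
  V <- 5
  beta_target <- matrix(c(0.4, 0.3, 0.1, 0.1, 0.1,
                          0.05, 0.05, 0.3, 0.3, 0.3), 2, V, byrow = TRUE)
  rho <- rbind(log(beta_target[1, ]), log(beta_target[2, ]))
  alpha <- array(0, dim = c(1, 2, 2))
  alpha[1, 1, ] <- c(1, 0); alpha[1, 2, ] <- c(0, 1)
  params <- tm_params(rho, alpha, matrix(0, 1, 2), eps = 1)
  beta <- compute_beta(matrix(alpha[1, , ], 2, 2), rho)
  # rows are softmax(log beta_target + const) = beta_target exactly
  expect_equal(beta, beta_target, tolerance = 1e-12, ignore_attr = TRUE)
  counts <- matrix(c(2, 1, 0, 1, 0,
                     0, 0, 2, 2, 2,
                     1, 1, 1, 1, 0), 3, V, byrow = TRUE)
  cp <- new_tm_corpus(counts, tibble::tibble(doc_id = as.character(1:3),
                                             slice = 1L, year = 2000L,
                                             label = 1L),
                      sprintf("w%d", 1:5), "A", 2000L)
  enc <- topicdrift:::init_encoder(V, 2, hidden = c(8, 8), seed = 3)
  ppl <- perplexity(cp, params, enc)
  # oracle: replicate the protocol by hand
  ll <- 0; n <- 0
  for (d in 1:3) {
    tokens <- rep(1:V, counts[d, ])
    first <- tokens[seq(1, length(tokens), 2)]
    second <- tokens[seq(2, length(tokens), 2)]
    half <- tabulate(first, nbins = V)
    it <- infer_theta(half, enc, params$eta[1, ], n_samples = 1, seed = 1)
    th <- drop(topicdrift:::softmax_rows(it$mu))
    for (w in second) { ll <- ll + log(sum(th * beta[, w])); n <- n + 1 }
  }
  expect_equal(as.numeric(ppl), exp(-ll / n), tolerance = 1e-12)
  # too-short documents are excluded and reported
  cp1 <- new_tm_corpus(matrix(c(1, 0, 0, 0, 0), 1), cp$docs[1, ],
                       cp$vocabulary, "A", 2000L)
  expect_error(perplexity(cp1, params, enc), "no document")
})

test_that("the quality report aggregates coherence, diversity and perplexity", {
  fit <- fit_small()
  sim <- sim_small()
  q <- evaluate_topics(fit, test = sim$corpus, p_coherence = 5,
                       p_diversity = 10)
  expect_s3_class(q$per_topic, "tbl_df")
  expect_setequal(unique(q$per_topic$measure), c("ca", "cp", "npmi"))
  expect_true(all(q$per_topic$coherence >= -1 & q$per_topic$coherence <= 1))
  expect_gte(q$summary$td, 1 / 3); expect_lte(q$summary$td, 1)
  expect_gt(q$summary$perplexity, 0)
  expect_output(print(q), "topic_quality")
})
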