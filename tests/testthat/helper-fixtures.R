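# Shared fixtures, memoized so expensive simulations/fits run once per
# test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, .fixtures)) assign(name, fun(), .fixtures)
  get(name, .fixtures)
}

# Tiny raw corpus as a tibble (deterministic text).
toy_raw_docs <- function() {
  tibble::tibble(
    text = c("gene expression tumor cell growth signal",
             "tumor cell growth factor receptor kinase",
             "neuron synapse brain cortex signal plasticity",
             "brain imaging cortex network neuron memory",
             "virus vaccine antibody immune response infection",
             "immune cell antibody response pathogen clearance"),
    year = c(2000L, 2000L, 2001L, 2001L, 2002L, 2002L),
    label = c("NCI", "NCI", "NIMH", "NIMH", "NIAID", "NIAID"))
}

toy_corpus <- function() {
  fixture("toy_corpus", function() {
    preprocess_corpus(toy_raw_docs(), stopwords = character(0),
                      max_df = 1, min_count = 1, min_doc_len = 1)
  })
}

# Identifiable simulation regime used by the unit/property tests: enough
# per-document theta variation (eps = 1) for topics to be recoverable.
sim_small <- function() {
  fixture("sim_small", function() {
    params <- random_params(K = 3, V = 60, L = 8, T_ = 2, eps = 1,
                            delta = 0.01, gamma = 0.01, seed = 41)
    sample_corpus(params, docs_per_slice = c(120, 120), tokens_per_doc = 40,
                  seed = 42)
  })
}

# A quickly trained model on the small simulation, reused by the analysis
# and metric tests that need a fitted object.
fit_small <- function() {
  fixture("fit_small", function() {
    cfg <- fit_config(K = 3, L = 8, epochs = 300, learning_rate = 0.005,
                      batch_size = 128, eps = 1, delta = 0.01, gamma = 0.01,
                      hidden = c(64L, 64L), head_hidden = 32L, seed = 7)
    fit_topics(sim_small()$corpus, cfg)
  })
}

# Brute-force co-occurrence oracle: plain loops over unit token sets.
brute_cooc <- function(units) {
  vocab <- sort(unique(unlist(units)))
  df <- stats::setNames(numeric(length(vocab)), vocab)
  joint <- matrix(0, length(vocab), length(vocab),
                  dimnames = list(vocab, vocab))
  for (u in units) {
    ws <- unique(u)
    for (w in ws) df[w] <- df[w] + 1
    if (length(ws) >= 2) {
      prs <- utils::combn(sort(ws), 2)
      for (c_i in seq_len(ncol(prs))) {
        joint[prs[1, c_i], prs[2, c_i]] <- joint[prs[1, c_i], prs[2, c_i]] + 1
        joint[prs[2, c_i], prs[1, c_i]] <- joint[prs[2, c_i], prs[1, c_i]] + 1
      }
    }
  }
  list(vocab = vocab, df = df, joint = joint, n = length(units))
}

brute_npmi <- function(wi, wj, bc, s = 1e-12) {
  pi_ <- bc$df[[wi]] / bc$n; pj <- bc$df[[wj]] / bc$n
  pij <- bc$joint[wi, wj] / bc$n
  log((pij + s) / (pi_ * pj)) / (-log(pij + s))
}

brute_cp <- function(wi, wj, bc, s = 1e-12) {
  pi_ <- bc$df[[wi]] / bc$n; pj <- bc$df[[wj]] / bc$n
  pij <- bc$joint[wi, wj] / bc$n
  a <- pij / pi_
  b <- if (pi_ >= 1) 0 else (pj - pij) / (1 - pi_)
  if (a + b < s) return(0)
  (a - b) / (a + b)
}

# Sliding windows of width w over one token vector (oracle version).
brute_windows <- function(tokens, w) {
  n <- length(tokens)
  if (n <= w) return(list(tokens))
  lapply(seq_len(n - w + 1), function(s) tokens[s:(s + w - 1)])
}

expect_simplex_rows <- function(x, tol = 1e-8) {
  expect_true(all(abs(rowSums(x) - 1) < tol))
  expect_true(all(x >= 0))
}
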