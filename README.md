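# topicdrift

Time-aware embedded topic models for labeled, time-sliced document
corpora — built for collections like funding-agency grant abstracts, where
research topics drift over decades and every document carries a
categorical label (for example, the institute it was submitted to).

## The model

Each topic `k` at time slice `t` is a point `alpha_k^t` in an
`L`-dimensional word-embedding space, and its word distribution is
`beta_k^t = softmax(rho^T alpha_k^t)` over the shared embedding table
`rho`. Topics and the per-slice prior mean of the topic proportions evolve
by Gaussian random walks (`alpha_k^t ~ N(alpha_k^{t-1}, gamma^2 I)`,
`eta_t ~ N(eta_{t-1}, delta^2 I)`), so topics change smoothly rather than
being re-fit per slice. A document at slice `t` draws a logistic-normal
topic proportion `theta_d = softmax(N(eta_t, eps^2 I))`, then per token a
topic `z ~ Cat(theta_d)` and a word `w ~ Cat(beta_z^t)`.

Fitting is amortized variational inference: an encoder network maps each
bag of words to a Gaussian posterior over the pre-softmax `theta`, and the
reparameterized ELBO is optimized jointly with two auxiliary terms — a
topic-diversity reward `sum_t sum_{i<j} ||alpha_i^t - alpha_j^t||` that
keeps topic embeddings apart, and a cross-entropy loss from a small
classifier head that makes document labels predictable from the inferred
proportions. The minimized objective is
`-ELBO + dynamics_penalty - lambda1 * TD + lambda2 * CE`
(defaults `lambda1 = 1`, `lambda2 = 0.5`). All gradients are analytic and
checked against finite differences in the test suite.

The package also provides the generative simulator with recorded latent
truth, topic-quality metrics (NPMI / window-based CA / Fitelson CP
coherence, topic diversity, document-completion perplexity), and the
downstream analyses: word-probability trends, cross-resolution topic
hierarchies, label classification from topic proportions, and a 2-D
document embedding. See the methods vignette
(`vignettes/time-aware-topic-models.Rmd`) for the full model account.

## Worked example

Simulate a 600-document corpus from the model itself, fit it, and inspect
what comes back:

```r
library(topicdrift)

params <- random_params(K = 3, V = 120, L = 8, T_ = 3, eps = 1, seed = 1)
sim <- sample_corpus(params, docs_per_slice = rep(200, 3),
                     tokens_per_doc = 50, seed = 2)
sim$corpus
#> <tm_corpus> 600 documents, 120 terms, 3 slices (2000-2002), 5 labels
#>   docs per slice: 200 200 200

splits <- split_corpus(sim$corpus, c(0.85, 0.05, 0.10), seed = 3)
cfg <- fit_config(K = 3, L = 8, epochs = 200, learning_rate = 0.005,
                  batch_size = 256, eps = 1, seed = 4)
fit <- fit_topics(splits$train, cfg, valid = splits$valid)
fit
#> <topic_fit> K=3 topics, V=120 words, L=8 dims, T=3 slices; 200 epochs (best 174)
#>   final elbo -24343.9, td 20.30, ce 0.361

head(top_words(fit, p = 3), 6)
#> # A tibble: 6 × 4
#>   topic  rank term    beta
#>   <int> <int> <chr>  <dbl>
#> 1     1     1 w0073 0.596
#> 2     1     2 w0054 0.110
#> 3     1     3 w0100 0.0510
#> 4     2     1 w0117 0.0998
#> 5     2     2 w0039 0.0938
#> 6     2     3 w0073 0.0771

evaluate_topics(fit, test = splits$test, reference = splits$train)
#> <topic_quality>
#>   ca         0.03721
#>   cp         0.0952
#>   npmi       0.03721
#>   td         0.64
#>   perplexity 15.47

classify_labels(extract_topic_features(splits$train, fit),
                extract_topic_features(splits$test, fit), ks = c(1, 5),
                seed = 5)
#> # A tibble: 2 × 2
#>       k accuracy
#>   <int>    <dbl>
#> 1     1      0.9
#> 2     5      1

evaluate_recovery(sim$truth, fit, sim$corpus)[c("mean_beta_cosine", "mean_theta_cosine")]
#> $mean_beta_cosine
#> [1] 0.962...
#> $mean_theta_cosine
#> [1] 0.981...
```

Reading the numbers: the fitted topic-word distributions match the
simulation's true topics at mean cosine 0.96 after optimal topic matching,
and the inferred per-document proportions match the true ones at 0.98 —
the estimator recovers the structure that generated the data. Held-out
top-1 label accuracy of 0.9 (chance 0.2 with five labels) shows the
inferred proportions carry the label signal the classification loss asks
for; coherence is computed against the training split and topic diversity
is the fraction of distinct words among the pooled top-25 words.

Trends, hierarchies and plots:

```r
word_trend(fit, c("w0073", "w0054"), topic = 1) |> autoplot()
topic_hierarchy(fit_5topics, fit_10topics)   # Pearson correlation in beta space
autoplot(fit)                                # top words per topic
tidy(fit, "beta"); glance(fit)               # broom-style accessors
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/topicdrift` with subcommands `simulate`, `preprocess`, `train`,
`evaluate`, `trends`, `hierarchy`, `classify`; every run writes a
resolved-config snapshot and derives all randomness from one `--seed`.

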