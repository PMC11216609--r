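test_that("diagonal-Gaussian KL matches quadrature and is zero iff identical", {
  expect_equal(kl_diag_gaussians(c(1, 2), c(0.5, 2), c(1, 2), c(0.5, 2)), 0)
  expect_error(kl_diag_gaussians(0, -1, 0, 1), "positive")
  set.seed(8)
  for (i in 1:5) {
    mq <- rnorm(1); sq <- runif(1, 0.3, 2); mp <- rnorm(1); sp <- runif(1, 0.3, 2)
    quad <- stats::integrate(function(x) {
      q <- dnorm(x, mq, sq)
      q * (dnorm(x, mq, sq, log = TRUE) - dnorm(x, mp, sp, log = TRUE))
    }, mq - 12 * sq, mq + 12 * sq, rel.tol = 1e-10)$value
    closed <- kl_diag_gaussians(mq, sq, mp, sp)
    expect_gte(closed, 0)
    expect_lt(abs(closed - quad) / max(abs(quad), 1e-12), 1e-6)
  }
})

test_that("posterior samples are reparameterized, seeded and simplex-valued", {
  enc <- topicdrift:::init_encoder(20, 3, hidden = c(16, 16), seed = 1)
  counts <- matrix(rpois(2 * 20, 2) + 1, 2, 20)
  it <- infer_theta(counts, enc, eta_t = rep(0, 3), n_samples = 4, seed = 3)
  expect_simplex_rows(it$samples[, , 1])
  expect_true(all(it$sigma > 0))
  it2 <- infer_theta(counts, enc, eta_t = rep(0, 3), n_samples = 4, seed = 3)
  expect_identical(it$samples, it2$samples)
  # sigma -> 0 collapses every sample onto softmax(mu)
  enc0 <- enc; enc0$Ws <- enc$Ws * 0; enc0$bs <- rep(-40, 3)
  it0 <- infer_theta(counts, enc0, eta_t = rep(0, 3), n_samples = 3, seed = 5)
  target <- topicdrift:::softmax_rows(it0$mu)
  for (s in 1:3) expect_equal(it0$samples[, , s], target, tolerance = 1e-4)
  expect_error(infer_theta(matrix(0, 1, 20), enc, rep(0, 3)), "empty")
})

test_that("pre-softmax sample moments recover (mu, sigma) at Monte-Carlo scale", {
  counts <- matrix(rpois(10, 3) + 1, 1, 10)
  enc2 <- topicdrift:::init_encoder(10, 2, hidden = c(8, 8), use_eta = FALSE, seed = 2)
  fw <- topicdrift:::enc_forward(counts / sum(counts), enc2)
  set.seed(11)
  mu <- drop(fw$mu); sg <- drop(fw$sigma)
  draws <- sweep(matrix(rnorm(10000 * 2), 10000, 2) %*% diag(sg), 2, mu, `+`)
  m_hat <- colMeans(draws); s_hat <- apply(draws, 2, sd)
  expect_true(all(abs(m_hat - mu) < 3 * sg / sqrt(10000)))
  expect_true(all(abs(s_hat - sg) < 3 * sg / sqrt(2 * (10000 - 1))))
})

test_that("single-topic ELBO reduces to exact closed forms", {
  # K = 1: theta is always (1), reconstruction is sum count * log beta
  V <- 6
  rho <- matrix(rnorm(3 * V), 3, V)
  alpha <- array(rnorm(3), dim = c(1, 1, 3))
  params <- tm_params(rho, alpha, matrix(0, 1, 1), eps = 0.5,
                      delta = 0.01, gamma = 0.01)
  enc <- topicdrift:::init_encoder(V, 1, hidden = c(8, 8), seed = 3)
  X <- matrix(rpois(2 * V, 3) + 1, 2, V)
  eb <- elbo_batch(X, 1, params, enc, n_mc = 1, seed = 4)
  beta <- compute_beta(matrix(alpha[1, , ], 1, 3), rho)
  recon_exact <- sum(X * log(rep(1, 2) %o% drop(beta) + 1e-10))
  expect_equal(eb$recon, recon_exact, tolerance = 1e-10)
  # KL is the 1-D closed form per document
  inp <- X / rowSums(X)
  fw <- topicdrift:::enc_forward(cbind(inp, 0), enc)
  kl_exact <- sum(sapply(1:2, function(d)
    kl_diag_gaussians(fw$mu[d, ], fw$sigma[d, ], 0, 0.5)))
  expect_equal(eb$kl, kl_exact, tolerance = 1e-10)
  # ELBO never exceeds the exact log-likelihood (here the K=1 likelihood
  # does not involve theta at all, so the bound gap is exactly the KL)
  expect_lte(eb$elbo, recon_exact)
})

test_that("a one-hot document scored under a one-hot theta gives log beta", {
  set.seed(12)
  beta <- softmax_rows(matrix(rnorm(2 * 5), 2, 5))
  mu <- matrix(c(40, -40), 1, 2)     # softmax -> (1, 0)
  sigma <- matrix(1e-9, 1, 2)
  X <- matrix(0, 1, 5); X[1, 4] <- 1
  core <- topicdrift:::elbo_core(mu, sigma, matrix(0, 1, 2), X, beta,
                                 c(0, 0), 1, floor = 0)
  expect_equal(core$recon, log(beta[1, 4]), tolerance = 1e-8)
})

test_that("deterministic two-document ELBO matches a term-by-term hand computation", {
  # sigma -> 0 makes the bound deterministic: theta = softmax(mu)
  beta <- matrix(c(0.7, 0.2, 0.1,
                   0.1, 0.3, 0.6), 2, 3, byrow = TRUE)
  mu <- matrix(c(0.5, -0.5,
                 -1.0, 1.0), 2, 2, byrow = TRUE)
  sigma <- matrix(1e-8, 2, 2)
  X <- matrix(c(2, 1, 0,
                0, 1, 3), 2, 3, byrow = TRUE)
  eta <- c(0.2, -0.2); epsp <- 0.7
  core <- topicdrift:::elbo_core(mu, sigma, matrix(0, 2, 2), X, beta, eta, epsp,
                                 floor = 0)
  theta <- topicdrift:::softmax_rows(mu)
  recon_hand <- 0
  for (d in 1:2) for (w in 1:3)
    recon_hand <- recon_hand + X[d, w] * log(sum(theta[d, ] * beta[, w]))
  kl_hand <- sum(sapply(1:2, function(d)
    kl_diag_gaussians(mu[d, ], sigma[d, ], eta, epsp)))
  expect_equal(core$recon, recon_hand, tolerance = 1e-9)
  expect_equal(core$kl, kl_hand, tolerance = 1e-9)
  expect_gte(core$kl, 0)
})

test_that("analytic ELBO gradients agree with finite differences", {
  set.seed(42)
  B <- 2; V <- 3; K <- 2
  X <- matrix(rpois(B * V, 4) + 1, B, V)
  beta <- topicdrift:::softmax_rows(matrix(rnorm(K * V), K, V))
  eta <- rnorm(K); epsp <- 0.7
  mu <- matrix(rnorm(B * K), B, K)
  sig <- matrix(runif(B * K, 0.3, 1), B, K)
  epsd <- matrix(rnorm(B * K), B, K)
  val <- function(mu, sig)
    topicdrift:::elbo_core(mu, sig, epsd, X, beta, eta, epsp, want_grad = FALSE)$elbo
  core <- topicdrift:::elbo_core(mu, sig, epsd, X, beta, eta, epsp)
  h <- 1e-6
  for (i in seq_len(B)) for (k in seq_len(K)) {
    mp <- mu; mp[i, k] <- mp[i, k] + h; mm <- mu; mm[i, k] <- mm[i, k] - h
    fd <- (val(mp, sig) - val(mm, sig)) / (2 * h)
    expect_lt(abs(fd - core$delbo_dmu[i, k]) / max(abs(fd), 1e-8), 1e-4)
    sp <- sig; sp[i, k] <- sp[i, k] + h; sm <- sig; sm[i, k] <- sm[i, k] - h
    fd_s <- (val(mu, sp) - val(mu, sm)) / (2 * h)
    expect_lt(abs(fd_s - core$delbo_dsigma[i, k]) / max(abs(fd_s), 1e-8), 1e-4)
  }
})

test_that("embedding-space gradients agree with finite differences", {
  set.seed(43)
  B <- 2; V <- 4; K <- 2; L <- 3
  X <- matrix(rpois(B * V, 4) + 1, B, V)
  mu <- matrix(rnorm(B * K), B, K); sig <- matrix(0.5, B, K)
  epsd <- matrix(rnorm(B * K), B, K)
  eta <- rep(0, K); epsp <- 1
  alpha_t <- matrix(rnorm(K * L), K, L); rho <- matrix(rnorm(L * V), L, V)
  val <- function(alpha_t, rho)
    topicdrift:::elbo_core(mu, sig, epsd, X, compute_beta(alpha_t, rho),
                           eta, epsp, want_grad = FALSE)$recon
  b0 <- compute_beta(alpha_t, rho)
  core <- topicdrift:::elbo_core(mu, sig, epsd, X, b0, eta, epsp)
  dS <- topicdrift:::softmax_rows_grad(b0, core$dbeta_recon)
  g_alpha <- dS %*% t(rho); g_rho <- crossprod(alpha_t, dS)
  h <- 1e-6
  for (i in 1:K) for (l in 1:L) {
    ap <- alpha_t; ap[i, l] <- ap[i, l] + h
    am <- alpha_t; am[i, l] <- am[i, l] - h
    fd <- (val(ap, rho) - val(am, rho)) / (2 * h)
    expect_lt(abs(fd - g_alpha[i, l]) / max(abs(fd), 1e-8), 1e-4)
  }
  for (i in 1:L) for (w in 1:V) {
    rp <- rho; rp[i, w] <- rp[i, w] + h
    rm <- rho; rm[i, w] <- rm[i, w] - h
    fd <- (val(alpha_t, rp) - val(alpha_t, rm)) / (2 * h)
    expect_lt(abs(fd - g_rho[i, w]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("dynamics penalty matches direct Gaussian log-densities", {
  # T=3, K=1, L=1 numeric trajectory
  alpha <- array(c(0.3, 0.8, 0.5), dim = c(3, 1, 1))
  eta <- matrix(c(-0.2, 0.1, 0.0), 3, 1)
  params <- tm_params(matrix(0, 1, 2), alpha, eta, eps = 1,
                      delta = 0.3, gamma = 0.5)
  pen <- dynamics_penalty(params)
  # negative log N(x; m, s^2) without constants = (x - m)^2 / (2 s^2),
  # initial slices against N(0, 1)
  hand <- 0.3^2 / 2 + (0.8 - 0.3)^2 / (2 * 0.5^2) + (0.5 - 0.8)^2 / (2 * 0.5^2) +
    (-0.2)^2 / 2 + (0.1 + 0.2)^2 / (2 * 0.3^2) + (0.0 - 0.1)^2 / (2 * 0.3^2)
  expect_equal(pen, hand, tolerance = 1e-12)

  # constant-zero trajectories -> 0
  params0 <- tm_params(matrix(0, 1, 2), array(0, dim = c(3, 2, 1)),
                       matrix(0, 3, 2), eps = 1, delta = 0.3, gamma = 0.5)
  expect_equal(dynamics_penalty(params0), 0)

  # doubling a single increment quadruples that term
  a1 <- array(0, dim = c(2, 1, 1)); a1[2, 1, 1] <- 1
  a2 <- array(0, dim = c(2, 1, 1)); a2[2, 1, 1] <- 2
  p1 <- tm_params(matrix(0, 1, 2), a1, matrix(0, 2, 1), delta = 1, gamma = 1)
  p2 <- tm_params(matrix(0, 1, 2), a2, matrix(0, 2, 1), delta = 1, gamma = 1)
  expect_equal(dynamics_penalty(p2), 4 * dynamics_penalty(p1))

  # gradient against finite differences
  g <- topicdrift:::dynamics_penalty_grad(alpha, eta, 0.3, 0.5)
  h <- 1e-7
  for (t in 1:3) {
    ap <- alpha; ap[t, 1, 1] <- ap[t, 1, 1] + h
    pp <- tm_params(matrix(0, 1, 2), ap, eta, delta = 0.3, gamma = 0.5)
    expect_equal((dynamics_penalty(pp) - pen) / h, g$alpha[t, 1, 1],
                 tolerance = 1e-5)
  }
})

test_that("short training increases the smoothed ELBO and is reproducible", {
  sim <- sim_small()
  cfg <- fit_config(K = 3, L = 8, epochs = 25, learning_rate = 0.005,
                    batch_size = 128, eps = 1, delta = 0.01, gamma = 0.01,
                    hidden = c(32L, 32L), head_hidden = 16L, seed = 5)
  f1 <- fit_topics(sim$corpus, cfg)
  expect_gt(mean(tail(f1$log$elbo, 5)), mean(head(f1$log$elbo, 3)))
  f2 <- fit_topics(sim$corpus, cfg)
  expect_identical(f1$params$rho, f2$params$rho)
  expect_identical(f1$params$alpha, f2$params$alpha)
  expect_identical(f1$encoder$W1, f2$encoder$W1)
  expect_identical(f1$log, f2$log)
})

test_that("training recovers simulated topics in an identifiable regime", {
  # eps = 1 gives documents genuinely distinct topic proportions, making
  # the decomposition identifiable at this size
  sim <- sim_small()
  fit <- fit_small()
  rec <- evaluate_recovery(sim$truth, fit, sim$corpus)
  expect_gte(rec$mean_beta_cosine, 0.9)
  expect_gte(rec$mean_theta_cosine, 0.8)
})

test_that("validation tracking returns the best-validation checkpoint", {
  sim <- sim_small()
  sp <- split_corpus(sim$corpus, c(0.7, 0.15, 0.15), seed = 2)
  cfg <- fit_config(K = 3, L = 8, epochs = 12, learning_rate = 0.005,
                    batch_size = 128, eps = 1, delta = 0.01, gamma = 0.01,
                    hidden = c(32L, 32L), head_hidden = 16L, seed = 6)
  fit <- fit_topics(sp$train, cfg, valid = sp$valid)
  expect_false(any(is.na(fit$log$val_elbo)))
  expect_equal(fit$best_epoch, which.max(fit$log$val_elbo))
})

test_that("inference rejects invalid inputs with clear messages", {
  sim <- sim_small()
  enc <- topicdrift:::init_encoder(60, 3, hidden = c(16, 16), seed = 1)
  expect_error(elbo_batch(as.matrix(sim$corpus$counts[1:3, ]), 99,
                          sim$truth$params, enc),
               "slice without prior mean")
  cfg <- fit_config(K = 3, L = 4, epochs = 1,
                    embeddings = matrix(0, 2, 60))  # wrong embedding shape
  expect_error(fit_topics(sim$corpus, cfg))
})
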