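#' Training configuration
#'
#' Collects every tunable of the fitting routine with the model's standard
#' defaults: learning rate 0.001 with a small weight decay, batch size 1024,
#' dropout 0.1, multitask weights `lambda1 = 1` (topic diversity) and
#' `lambda2 = 0.5` (label classification), and prior scales
#' `eps = delta = gamma = 0.01`. The default 500 epochs suits large corpora;
#' simulation studies in this package use far fewer.
#'
#' @param K number of topics.
#' @param L word-embedding dimension.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 weight decay added to parameter gradients.
#' @param batch_size maximum documents per minibatch (batches never cross a
#'   time slice).
#' @param dropout dropout rate of the encoder hidden layers.
#' @param lambda1,lambda2 multitask weights of the topic-diversity reward
#'   and the classification loss.
#' @param eps,delta,gamma prior scales: topic-proportion prior standard
#'   deviation and the `eta`/`alpha` random-walk standard deviations.
#' @param n_mc Monte-Carlo samples per document per step.
#' @param hidden integer vector, encoder hidden widths.
#' @param head_hidden classifier-head hidden width.
#' @param embeddings optional L x V matrix of pretrained word embeddings
#'   (columns aligned to the corpus vocabulary); default random
#'   initialization.
#' @param freeze_embeddings if `TRUE`, `rho` is not updated.
#' @param use_eta_input if `TRUE` (default) the encoder also sees the
#'   slice's prior mean `eta_t`.
#' @param seed master seed; all randomness (initialization, batching,
#'   posterior draws, dropout) derives from it.
#' @param verbose print a progress line every `verbose` epochs (0 = silent).
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(K = 50L, L = 200L, epochs = 500L,
                       learning_rate = 0.001, weight_decay = 1.2e-6,
                       batch_size = 1024L, dropout = 0.1,
                       lambda1 = 1, lambda2 = 0.5,
                       eps = 0.01, delta = 0.01, gamma = 0.01,
                       n_mc = 1L, hidden = c(256L, 256L), head_hidden = 64L,
                       embeddings = NULL, freeze_embeddings = FALSE,
                       use_eta_input = TRUE, seed = 1L, verbose = 0L) {
  stopifnot(K >= 1, L >= 1, epochs >= 1, learning_rate > 0, batch_size >= 1,
            dropout >= 0, dropout < 1, lambda1 >= 0, lambda2 >= 0,
            eps > 0, delta > 0, gamma > 0, n_mc >= 1)
  structure(as.list(environment()), class = "fit_config")
}

# Adam optimizer over a flat named list of arrays.
adam_new <- function(pars) {
  list(m = lapply(pars, function(p) p * 0), v = lapply(pars, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, pars, grads, lr, skip = character(0)) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(pars)) {
    if (nm %in% skip || is.null(grads[[nm]])) next
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    pars[[nm]] <- pars[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, pars = pars)
}

#' Fit the time-aware embedded topic model
#'
#' Trains the generative parameters (word embeddings `rho`, per-slice topic
#' embeddings `alpha`, per-slice prior means `eta`), the amortized
#' variational encoder, and the label-classifier head by stochastic gradient
#' descent (Adam) on the combined objective
#' `-ELBO + dynamics penalty - lambda1 * TD + lambda2 * CE`
#' (see [total_objective()]). Gradients are computed analytically.
#' Minibatches are drawn within a single time slice per step, with
#' `N_t / batch` rescaling of the ELBO terms so each step sees an unbiased
#' full-data estimate; the random-walk priors enter through their MAP
#' penalty once per step. Runs are bit-reproducible under a fixed seed.
#'
#' @param corpus a [tm_corpus][new_tm_corpus] training corpus.
#' @param config a [fit_config()].
#' @param valid optional validation `tm_corpus`; when given, the returned
#'   model is the epoch with the best validation ELBO, and `val_elbo` is
#'   logged per epoch.
#' @return object of class `topic_fit`: `params` ([tm_params()] with learned
#'   values), `encoder`, `classifier`, `config`, `log` (tibble with one row
#'   per epoch: `epoch`, `objective`, `elbo`, `recon`, `kl`, `td_loss`,
#'   `ce_loss`, `val_elbo`), `best_epoch`.
#' @export
fit_topics <- function(corpus, config = fit_config(), valid = NULL) {
  stopifnot(inherits(corpus, "tm_corpus"), inherits(config, "fit_config"))
  dims <- corpus_dims(corpus)
  V <- dims$n_terms; T_ <- dims$n_slices; M <- dims$n_labels
  K <- as.integer(config$K); L <- as.integer(config$L)
  if (dims$n_docs == 0) stop("empty corpus")

  # --- initialization (seeded sub-streams) -------------------------------
  rng <- local_rng(derive_seed(config$seed, "init"))
  rho <- if (!is.null(config$embeddings)) {
    stopifnot(nrow(config$embeddings) == L, ncol(config$embeddings) == V)
    config$embeddings
  } else matrix(stats::rnorm(L * V, sd = 1 / sqrt(L)), L, V)
  alpha0 <- matrix(stats::rnorm(K * L, sd = 1 / sqrt(L)), K, L)
  alpha <- array(0, dim = c(T_, K, L))
  for (t in seq_len(T_)) alpha[t, , ] <- alpha0   # prior-friendly start
  eta <- matrix(0, T_, K)
  encoder <- init_encoder(V, K, hidden = config$hidden,
                          use_eta = config$use_eta_input,
                          seed = derive_seed(config$seed, "encoder"))
  classifier <- init_classifier(K, M, hidden = config$head_hidden,
                                seed = derive_seed(config$seed, "classifier"))

  pars <- c(list(rho = rho, alpha = alpha, eta = eta),
            stats::setNames(encoder[c("W1", "b1", "W2", "b2", "Wm", "bm", "Ws", "bs")],
                            paste0("enc.", c("W1", "b1", "W2", "b2", "Wm", "bm", "Ws", "bs"))),
            stats::setNames(classifier[c("Wc1", "bc1", "Wc2", "bc2")],
                            paste0("clf.", c("Wc1", "bc1", "Wc2", "bc2"))))
  opt <- adam_new(pars)
  skip <- if (config$freeze_embeddings) "rho" else character(0)

  slice_idx <- lapply(seq_len(T_), function(t) which(corpus$docs$slice == t))
  n_by_slice <- vapply(slice_idx, length, integer(1))
  labels <- corpus$docs$label

  sync_states <- function(pars) {
    for (f in c("W1", "b1", "W2", "b2", "Wm", "bm", "Ws", "bs"))
      encoder[[f]] <<- pars[[paste0("enc.", f)]]
    for (f in c("Wc1", "bc1", "Wc2", "bc2"))
      classifier[[f]] <<- pars[[paste0("clf.", f)]]
  }

  log_rows <- vector("list", config$epochs)
  best_val <- -Inf; best_epoch <- NA_integer_; best <- NULL
  rng2 <- local_rng(derive_seed(config$seed, "train"))

  for (epoch in seq_len(config$epochs)) {
    ep_elbo <- 0; ep_recon <- 0; ep_kl <- 0; ep_ce <- 0; n_steps <- 0L
    for (t in sample(seq_len(T_))) {
      idx <- slice_idx[[t]]
      if (length(idx) == 0) next
      idx <- idx[sample.int(length(idx))]
      starts <- seq(1, length(idx), by = config$batch_size)
      for (st in starts) {
        b_idx <- idx[st:min(st + config$batch_size - 1, length(idx))]
        step <- train_step(pars, encoder, classifier, corpus, b_idx, t,
                           n_by_slice[t], config)
        if (!is.finite(step$objective))
          stop(sprintf("non-finite loss at epoch %d, slice %d (batch starting %d)",
                       epoch, t, st))
        grads <- step$grads
        if (config$weight_decay > 0)
          for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + config$weight_decay * pars[[nm]]
        upd <- adam_step(opt, pars, grads, config$learning_rate, skip = skip)
        opt <- upd$opt; pars <- upd$pars
        sync_states(pars)
        ep_elbo <- ep_elbo + step$elbo; ep_recon <- ep_recon + step$recon
        ep_kl <- ep_kl + step$kl; ep_ce <- ep_ce + step$ce
        n_steps <- n_steps + 1L
      }
    }
    cur_params <- tm_params(pars$rho, pars$alpha, pars$eta, eps = config$eps,
                            delta = config$delta, gamma = config$gamma,
                            vocabulary = corpus$vocabulary)
    td_val <- if (K >= 2) topic_diversity_loss(pars$alpha) else 0
    val_elbo <- NA_real_
    if (!is.null(valid)) {
      val_elbo <- corpus_elbo(valid, cur_params, encoder,
                              seed = derive_seed(config$seed, paste0("val", epoch)))
      if (val_elbo > best_val) {
        best_val <- val_elbo; best_epoch <- epoch
        best <- list(pars = pars, encoder = encoder, classifier = classifier)
      }
    }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch,
      objective = total_objective(ep_elbo / n_steps, td_val, ep_ce / n_steps,
                                  dynamics_penalty(cur_params),
                                  config$lambda1, config$lambda2),
      elbo = ep_elbo / n_steps, recon = ep_recon / n_steps, kl = ep_kl / n_steps,
      td_loss = td_val, ce_loss = ep_ce / n_steps, val_elbo = val_elbo)
    if (config$verbose > 0 && epoch %% config$verbose == 0)
      message(sprintf("epoch %4d  elbo %.1f  td %.2f  ce %.3f  val %.1f",
                      epoch, ep_elbo / n_steps, td_val, ep_ce / n_steps, val_elbo))
  }

  if (!is.null(best)) {
    pars <- best$pars; encoder <- best$encoder; classifier <- best$classifier
  } else best_epoch <- config$epochs

  params <- tm_params(pars$rho, pars$alpha, pars$eta, eps = config$eps,
                      delta = config$delta, gamma = config$gamma,
                      vocabulary = corpus$vocabulary)
  structure(list(params = params, encoder = encoder, classifier = classifier,
                 config = config, log = dplyr::bind_rows(log_rows),
                 best_epoch = best_epoch,
                 label_names = corpus$label_names, years = corpus$years),
            class = "topic_fit")
}

# One gradient step on a same-slice minibatch; returns loss pieces and the
# full analytic gradient of the minimized objective.
train_step <- function(pars, encoder, classifier, corpus, b_idx, t, N_t,
                       config) {
  X <- as.matrix(corpus$counts[b_idx, , drop = FALSE])
  B <- nrow(X); K <- config$K
  scale <- N_t / B
  eta_t <- pars$eta[t, ]
  alpha_t <- slice_mat(pars$alpha, t, K, config$L)
  beta_t <- compute_beta(alpha_t, pars$rho)

  inp <- X / rowSums(X)
  if (encoder$use_eta) inp <- cbind(inp, matrix(eta_t, B, K, byrow = TRUE))
  drop_masks <- NULL
  if (config$dropout > 0) {
    keep <- 1 - config$dropout
    drop_masks <- list(
      matrix(stats::rbinom(B * encoder$hidden[1], 1, keep), B) / keep,
      matrix(stats::rbinom(B * encoder$hidden[2], 1, keep), B) / keep)
  }
  fw <- enc_forward(inp, encoder, drop_masks)

  # single-draw reparameterized ELBO (n_mc draws averaged)
  n_mc <- config$n_mc
  recon <- 0; kl <- NA; theta <- NULL
  dtheta_recon <- matrix(0, B, K); dbeta <- matrix(0, K, ncol(X))
  acc_dr <- matrix(0, B, K); acc_dsig <- matrix(0, B, K)
  for (s in seq_len(n_mc)) {
    epsd <- matrix(stats::rnorm(B * K), B, K)
    core <- elbo_core(fw$mu, fw$sigma, epsd, X, beta_t, eta_t, config$eps)
    recon <- recon + core$recon / n_mc
    kl <- core$kl
    theta <- core$theta
    dr <- softmax_rows_grad(core$theta, core$dtheta_recon)
    acc_dr <- acc_dr + dr / n_mc
    acc_dsig <- acc_dsig + (dr * epsd) / n_mc
    dbeta <- dbeta + core$dbeta_recon / n_mc
    klg <- list(dmu = core$kl_dmu, dsigma = core$kl_dsigma, deta = core$kl_deta)
  }
  elbo <- recon - kl

  # classifier on the (last-draw) inferred proportions
  cf <- clf_forward(theta, classifier)
  logp <- cf$O - apply(cf$O, 1, function(o) max(o) + log(sum(exp(o - max(o)))))
  ce <- -mean(logp[cbind(seq_len(B), corpus$docs$label[b_idx])])
  cb <- clf_backward(cf, classifier, corpus$docs$label[b_idx])

  # ---- gradients of the minimized objective -----------------------------
  # dLoss/dtheta = -scale * d recon/dtheta + lambda2 * dCE/dtheta,
  # both flowing through the same softmax into (mu, sigma).
  dr_ce <- softmax_rows_grad(theta, cb$dtheta)
  dmu <- -scale * acc_dr + config$lambda2 * dr_ce + scale * klg$dmu
  # the CE path reuses the last draw's epsilon (theta came from that draw)
  dsigma <- -scale * acc_dsig + config$lambda2 * dr_ce * epsd + scale * klg$dsigma
  eb <- enc_backward(fw, encoder, dmu, dsigma)

  grads <- list()
  for (f in c("W1", "b1", "W2", "b2", "Wm", "bm", "Ws", "bs"))
    grads[[paste0("enc.", f)]] <- eb[[f]]
  for (f in c("Wc1", "bc1", "Wc2", "bc2"))
    grads[[paste0("clf.", f)]] <- config$lambda2 * cb[[f]]

  # beta -> (alpha_t, rho)
  dS <- softmax_rows_grad(beta_t, -scale * dbeta)
  dyn <- dynamics_penalty_grad(pars$alpha, pars$eta, config$delta, config$gamma)
  galpha <- dyn$alpha
  if (config$lambda1 > 0 && K >= 2)
    galpha <- galpha - config$lambda1 * topic_diversity_grad(pars$alpha)
  galpha[t, , ] <- galpha[t, , ] + dS %*% t(pars$rho)
  grads$alpha <- galpha
  grads$rho <- crossprod(alpha_t, dS)

  geta <- dyn$eta
  geta[t, ] <- geta[t, ] + scale * klg$deta
  if (encoder$use_eta)
    geta[t, ] <- geta[t, ] + colSums(eb$dinp[, (ncol(X) + 1):(ncol(X) + K), drop = FALSE])
  grads$eta <- geta

  td_val <- if (K >= 2) topic_diversity_loss(pars$alpha) else 0
  objective <- total_objective(scale * elbo, td_val, ce,
                               dynamics_penalty_grad_value(pars, config),
                               config$lambda1, config$lambda2)
  list(grads = grads, objective = objective, elbo = scale * elbo,
       recon = scale * recon, kl = scale * kl, ce = ce)
}

dynamics_penalty_grad_value <- function(pars, config) {
  p <- list(alpha = pars$alpha, eta = pars$eta,
            K = dim(pars$alpha)[2], L = dim(pars$alpha)[3],
            T = dim(pars$alpha)[1], gamma = config$gamma, delta = config$delta)
  dynamics_penalty(p)
}

# Full-corpus ELBO (one MC draw per document), summed over slices.
corpus_elbo <- function(corpus, params, encoder, seed = 1L, n_mc = 1L) {
  total <- 0
  for (t in seq_len(params$T)) {
    idx <- which(corpus$docs$slice == t)
    if (length(idx) == 0) next
    eb <- elbo_batch(corpus$counts[idx, , drop = FALSE], t, params, encoder,
                     n_mc = n_mc, seed = derive_seed(seed, paste0("slice", t)))
    total <- total + eb$elbo
  }
  total
}

#' @export
print.topic_fit <- function(x, ...) {
  d <- x$params
  cat(sprintf("<topic_fit> K=%d topics, V=%d words, L=%d dims, T=%d slices; %d epochs (best %s)\n",
              d$K, d$V, d$L, d$T, nrow(x$log),
              ifelse(is.na(x$best_epoch), "last", x$best_epoch)))
  cat(sprintf("  final elbo %.1f, td %.2f, ce %.3f\n",
              utils::tail(x$log$elbo, 1), utils::tail(x$log$td_loss, 1),
              utils::tail(x$log$ce_loss, 1)))
  invisible(x)
}

#' Write the per-epoch training log as CSV
#' @param fit a [fit_topics()] result.
#' @param path output CSV path.
#' @export
write_training_log <- function(fit, path) {
  utils::write.csv(fit$log, path, row.names = FALSE)
  invisible(path)
}
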