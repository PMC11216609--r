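# Checkpointing: one archive per fitted model, carrying a versioned
# manifest (dimensions, hyperparameters, vocabulary hash, seed) next to the
# learned parameters and network states.

CHECKPOINT_VERSION <- 1L

# FNV-1a hash of the vocabulary, hex string; cheap integrity check that a
# checkpoint is evaluated against the corpus it was trained on.
vocab_hash <- function(vocab) {
  h <- 2166136261
  for (b in utf8ToInt(paste(vocab, collapse = "\n"))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

checkpoint_manifest <- function(fit) {
  p <- fit$params
  list(format_version = CHECKPOINT_VERSION,
       package = "topicdrift",
       package_version = as.character(utils::packageVersion("topicdrift")),
       K = p$K, V = p$V, L = p$L, T = p$T,
       eps = p$eps, delta = p$delta, gamma = p$gamma,
       lambda1 = fit$config$lambda1, lambda2 = fit$config$lambda2,
       seed = fit$config$seed,
       vocabulary_hash = vocab_hash(p$vocabulary))
}

#' Save / load a fitted model checkpoint
#'
#' A checkpoint is a single archive holding the learned parameters, the
#' encoder and classifier states, the training configuration and log, and a
#' versioned manifest (dimensions, hyperparameters, vocabulary hash, seed).
#' `load_checkpoint` refuses archives with an unknown format version.
#'
#' @param fit a `topic_fit`.
#' @param path file path for the archive.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the `topic_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "topic_fit"))
  saveRDS(list(manifest = checkpoint_manifest(fit), fit = fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  obj <- readRDS(path)
  if (is.null(obj$manifest) || !identical(obj$manifest$format_version, CHECKPOINT_VERSION))
    stop("unsupported checkpoint format")
  obj$fit
}

#' @rdname save_checkpoint
#' @export
write_checkpoint_manifest <- function(fit, path) {
  jsonlite::write_json(checkpoint_manifest(fit), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
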