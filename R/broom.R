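#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted topic model
#'
#' Returns the requested component as a long tibble, in the style of the
#' tidiers for other topic-model fits: `matrix = "beta"` gives per-slice
#' topic-word probabilities, `"eta"` the per-slice prior means, `"alpha"`
#' the topic-embedding coordinates.
#'
#' @param x a `topic_fit`.
#' @param matrix which component to tidy.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.topic_fit <- function(x, matrix = c("beta", "eta", "alpha"), ...) {
  matrix <- match.arg(matrix)
  p <- x$params
  vocab <- if (!is.null(p$vocabulary)) p$vocabulary else sprintf("w%04d", seq_len(p$V))
  if (matrix == "beta") {
    beta <- compute_beta_all(p)
    purrr::map_dfr(seq_len(p$T), function(t)
      tibble::tibble(slice = t, year = x$years[t],
                     topic = rep(seq_len(p$K), each = p$V),
                     term = rep(vocab, times = p$K),
                     beta = as.numeric(t(slice_mat(beta, t, p$K, p$V)))))
  } else if (matrix == "eta") {
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(p$eta, .name_repair = ~paste0("topic_", seq_len(p$K))),
                    slice = seq_len(p$T), year = x$years),
      dplyr::starts_with("topic_"), names_to = "topic", names_prefix = "topic_",
      values_to = "eta")
  } else {
    purrr::map_dfr(seq_len(p$T), function(t) {
      a <- slice_mat(p$alpha, t, p$K, p$L)
      tibble::tibble(slice = t, topic = rep(seq_len(p$K), each = p$L),
                     dimension = rep(seq_len(p$L), times = p$K),
                     alpha = as.numeric(t(a)))
    })
  }
}

#' One-row summary of a fitted topic model
#'
#' @param x a `topic_fit`.
#' @param ... unused.
#' @return one-row tibble with the dimensions, epochs trained, final
#'   training ELBO, topic-diversity loss, classification loss and best
#'   validation epoch.
#' @export
glance.topic_fit <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  tibble::tibble(K = x$params$K, V = x$params$V, L = x$params$L,
                 T = x$params$T, epochs = nrow(x$log),
                 elbo = last$elbo, td_loss = last$td_loss,
                 ce_loss = last$ce_loss, best_epoch = x$best_epoch)
}

#' Plot a fitted topic model
#'
#' `type = "topics"` shows the top words of each topic (time-averaged
#' probabilities) as faceted bars; `type = "training"` shows the per-epoch
#' training ELBO.
#'
#' @param object a `topic_fit`.
#' @param type `"topics"` or `"training"`.
#' @param p top words per topic for `type = "topics"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.topic_fit <- function(object, type = c("topics", "training"),
                               p = 8L, ...) {
  type <- match.arg(type)
  if (type == "topics") {
    tw <- top_words(object, p = p)
    ggplot2::ggplot(tw, ggplot2::aes(x = .data$beta,
                                     y = stats::reorder(paste(.data$term, .data$topic, sep = "\r"),
                                                        .data$beta))) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::facet_wrap(~topic, scales = "free_y") +
      ggplot2::scale_y_discrete(labels = function(l) sub("\r.*$", "", l)) +
      ggplot2::labs(x = "word probability", y = NULL,
                    title = "Top words per topic (time-averaged)")
  } else {
    ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$elbo)) +
      ggplot2::geom_line(color = "steelblue") +
      ggplot2::labs(x = "epoch", y = "training ELBO")
  }
}

#' Plot word trends within a topic
#'
#' Line plot of [word_trend()] series: per-slice word probability relative
#' to the base slice (dashed line at 1).
#'
#' @param object a `tm_trend` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tm_trend <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$value,
                                       color = .data$word)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "year", y = "probability relative to base slice",
                  title = sprintf("Word trends in topic %d", object$topic[1]))
}

#' Plot a 2-D document embedding colored by label
#'
#' @param object a `tm_embedding` tibble from [embed_theta_2d()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tm_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                       color = factor(.data$label))) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(color = "label", x = "dimension 1", y = "dimension 2")
}

#' @importFrom rlang .data
NULL
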