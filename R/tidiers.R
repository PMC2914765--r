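#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an IBD posterior into a long tibble
#'
#' @param x An `ibd_posterior`.
#' @param ... Unused.
#' @return A tibble with one row per (locus, state): `locus`, `cm`,
#'   `state`, `probability`, plus the summed `p_ibd` repeated per locus.
#' @export
tidy.ibd_posterior <- function(x, ...) {
  s <- nrow(x$posterior); K <- ncol(x$posterior)
  tibble::tibble(
    locus = rep(seq_len(s), times = K),
    cm = rep(x$cm, times = K),
    state = rep(colnames(x$posterior), each = s),
    probability = as.vector(x$posterior),
    p_ibd = rep(ibd_probability(x), times = K)
  )
}

#' @rdname tidy.ibd_posterior
#' @export
glance.ibd_posterior <- function(x, ...) {
  tibble::tibble(model = x$model, sample_a = x$pair[1], sample_b = x$pair[2],
                 n_loci = nrow(x$posterior), loglik = x$loglik,
                 ibd_fraction = mean(ibd_probability(x) > 0.5))
}

#' Tidy the iteration history of a pipeline run
#'
#' @param x An `ibd_pipeline`.
#' @param ... Unused.
#' @return The per-iteration history tibble.
#' @export
tidy.ibd_pipeline <- function(x, ...) x$history

#' @rdname tidy.ibd_pipeline
#' @export
glance.ibd_pipeline <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    iterations = max(h$iteration), converged = x$converged,
    initial_ibd_fraction = h$mean_ibd_fraction[1],
    final_ibd_fraction = tail(h$mean_ibd_fraction, 1),
    n_segments = nrow(x$segments)
  )
}

#' Plot the per-locus IBD posterior of a sample pair
#'
#' @param object An `ibd_posterior`.
#' @param ... Unused.
#' @return A ggplot: summed IBD probability along the genetic map, with the
#'   0.5 decoding threshold.
#' @export
autoplot.ibd_posterior <- function(object, ...) {
  df <- tibble::tibble(cm = object$cm, p_ibd = ibd_probability(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cm, y = .data$p_ibd)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "position (cM)", y = "P(IBD)",
                  title = sprintf("%s model: %s vs %s", object$model,
                                  object$pair[1], object$pair[2])) +
    ggplot2::ylim(0, 1)
}

#' Plot pipeline progress across iterations
#'
#' @param object An `ibd_pipeline`.
#' @param ... Unused.
#' @return A ggplot of the mean per-pair IBD fraction per iteration.
#' @export
autoplot.ibd_pipeline <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration,
                               y = .data$mean_ibd_fraction)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "mean per-pair IBD fraction")
}
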