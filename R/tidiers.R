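#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sudden-expansion fit
#'
#' @param x An `mt_expansion_fit`.
#' @param ... Unused.
#' @return One row per model parameter (`tau`, `theta0`, `theta1`).
#' @method tidy mt_expansion_fit
#' @export
tidy.mt_expansion_fit <- function(x, ...) {
  tibble::tibble(term = c("tau", "theta0", "theta1"),
                 estimate = c(x$tau, x$theta0, x$theta1))
}

#' @rdname tidy.mt_expansion_fit
#' @method glance mt_expansion_fit
#' @export
glance.mt_expansion_fit <- function(x, ...) {
  tibble::tibble(ssd = x$ssd, raggedness = x$raggedness,
                 n_pairs = x$n_pairs,
                 d_max = max(x$histogram$differences))
}

#' Tidy a haplotype network
#'
#' @param x An `mt_haplonet`.
#' @param ... Unused.
#' @return The edge list as a tibble (`from`, `to`, `n_mutations`).
#' @method tidy mt_haplonet
#' @export
tidy.mt_haplonet <- function(x, ...) {
  tibble::tibble(from = x$edges$from, to = x$edges$to,
                 n_mutations = as.integer(x$edges$n_mutations))
}

#' @rdname tidy.mt_haplonet
#' @method glance mt_haplonet
#' @export
glance.mt_haplonet <- function(x, ...) {
  st <- network_stats(x)
  tibble::tibble(
    n_sampled = sum(x$nodes$type == "sampled"),
    n_median = sum(x$nodes$type == "median"),
    n_edges = nrow(x$edges),
    n_peripheral = sum(st$peripheral),
    max_degree = max(st$degree),
    total_length = sum(x$edges$weight)
  )
}

#' Plot a mismatch distribution
#'
#' Bars show the observed relative frequencies of pairwise differences;
#' when a fitted sudden-expansion model is supplied (or when called on the
#' fit itself) the expected curve is overlaid, the classical
#' observed-vs-expected mismatch figure.
#'
#' @param object An `mt_mismatch` histogram or `mt_expansion_fit`.
#' @param fit Optional `mt_expansion_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mt_mismatch
#' @export
autoplot.mt_mismatch <- function(object, fit = NULL, ...) {
  df <- tibble::tibble(differences = object$differences,
                       frequency = object$frequency)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$differences,
                                        y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Pairwise differences", y = "Relative frequency") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- 0:max(object$differences)
    exp_df <- tibble::tibble(
      differences = xs,
      frequency = expected_mismatch(xs, fit$tau, fit$theta0, fit$theta1))
    p <- p + ggplot2::geom_line(data = exp_df, colour = "firebrick",
                                linewidth = 0.8) +
      ggplot2::geom_point(data = exp_df, colour = "firebrick", size = 1.2)
  }
  p
}

#' @rdname autoplot.mt_mismatch
#' @method autoplot mt_expansion_fit
#' @export
autoplot.mt_expansion_fit <- function(object, ...) {
  autoplot(object$histogram, fit = object)
}

#' Plot a haplotype network
#'
#' Fruchterman-Reingold layout (seeded for reproducibility); sampled
#' haplotypes are drawn with area proportional to frequency, median vectors
#' as small squares, and edges labelled with their mutation counts.
#'
#' @param object An `mt_haplonet`.
#' @param seed Layout seed.
#' @param label Draw node labels?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mt_haplonet
#' @export
autoplot.mt_haplonet <- function(object, seed = 1, label = TRUE, ...) {
  g <- as_igraph(object)
  xy <- with_preserved_seed(seed, igraph::layout_with_fr(g))
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- tibble::tibble(
    x = nd$x[match(object$edges$from, nd$node_id)],
    y = nd$y[match(object$edges$from, nd$node_id)],
    xend = nd$x[match(object$edges$to, nd$node_id)],
    yend = nd$y[match(object$edges$to, nd$node_id)],
    n_mutations = object$edges$n_mutations
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = nd[nd$type == "median", ],
                        ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 15, size = 1.5, colour = "grey30") +
    ggplot2::geom_point(data = nd[nd$type == "sampled", ],
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$frequency),
                        shape = 21, fill = "steelblue", colour = "black") +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "n")
  if (label) {
    p <- p + ggplot2::geom_text(data = nd[nd$type == "sampled", ],
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             label = .data$node_id),
                                size = 2.6, vjust = -1.2)
  }
  p
}

#' @importFrom rlang .data
NULL
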