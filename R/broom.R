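#' Tidy the iteration history of a TGLRR fit
#'
#' One row per solver iteration with the objective value, the relative
#' feasibility residuals of the two constraints, the penalty parameter and
#' the change statistic driving the adaptive penalty.
#'
#' @param x A `"tglrr_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `objective`, `residual`,
#'   `residual_split`, `mu`, `change`.
#' @method tidy tglrr_fit
#' @export
tidy.tglrr_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a TGLRR fit
#'
#' @param x A `"tglrr_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: parameters, convergence flag, iteration
#'   count, final objective and residuals, and the rank of `Z`.
#' @method glance tglrr_fit
#' @export
glance.tglrr_fit <- function(x, ...) {
  last <- x$history[x$iterations, ]
  tibble::tibble(
    lambda = x$lambda, beta = x$beta, r = x$r, k_graph = x$k_graph,
    converged = x$converged, iterations = x$iterations,
    objective = last$objective, residual = last$residual,
    residual_split = last$residual_split,
    rank_Z = sum(svd(x$Z, nu = 0, nv = 0)$d >
                   max(dim(x$Z)) * .Machine$double.eps *
                   max(svd(x$Z, nu = 0, nv = 0)$d, 1))
  )
}

#' Tidy a clustering evaluation
#'
#' @param x A `"cluster_eval"` object from [aggregate_runs()].
#' @param ... Unused.
#' @return The per-run metrics tibble (`run`, `acc`, `nmi`, `f_measure`).
#' @method tidy cluster_eval
#' @export
tidy.cluster_eval <- function(x, ...) {
  x$per_run
}

#' One-row summary of a clustering evaluation
#'
#' @param x A `"cluster_eval"` object.
#' @param ... Unused.
#' @return A one-row tibble with mean and variance of each index.
#' @method glance cluster_eval
#' @export
glance.cluster_eval <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    acc = s$mean[s$metric == "acc"],
    acc_var = s$variance[s$metric == "acc"],
    nmi = s$mean[s$metric == "nmi"],
    nmi_var = s$variance[s$metric == "nmi"],
    f_measure = s$mean[s$metric == "f_measure"],
    f_measure_var = s$variance[s$metric == "f_measure"],
    n_runs = s$n_runs[1]
  )
}

#' Convergence plot of a TGLRR fit
#'
#' Objective value and relative feasibility residual against iteration;
#' the residual panel is on a log scale.
#'
#' @param object A `"tglrr_fit"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tglrr_fit
#' @export
autoplot.tglrr_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(iteration = h$iteration, value = h$objective,
               panel = "objective"),
    data.frame(iteration = h$iteration, value = pmax(h$residual, 1e-16),
               panel = "relative residual")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_y_continuous(trans = "identity") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "LADMAP convergence") +
    ggplot2::theme_minimal()
}

#' Scree-style plot of a singular-value curve
#'
#' Visual aid for choosing the truncation level `r`: plot the singular
#' values of `X` and the suggestion of [suggest_r()].
#'
#' @param X Expression matrix.
#' @param n_values How many leading singular values to show (default 20).
#' @return A ggplot object.
#' @export
plot_singular_values <- function(X, n_values = 20L) {
  d <- singular_value_curve(X)
  r <- suggest_r(d)
  d <- head(d, n_values)
  df <- data.frame(index = seq_along(d), sigma = d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$sigma)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = r, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "index", y = "singular value",
                  title = sprintf("Singular-value curve (suggested r = %d)",
                                  r)) +
    ggplot2::theme_minimal()
}

#' Bar plot of the top-ranked genes
#'
#' @param ranking A `"gene_ranking"` tibble from [score_genes()].
#' @param top How many genes to show (default 20).
#' @return A ggplot object.
#' @export
plot_gene_ranking <- function(ranking, top = 20L) {
  df <- head(ranking, top)
  df$gene_id <- factor(df$gene_id, levels = rev(df$gene_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "score (row norm of G X)", y = NULL,
                  title = "Top-ranked genes") +
    ggplot2::theme_minimal()
}
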