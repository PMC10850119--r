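#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a methylation cluster assignment
#'
#' @param x An `mc_assignment` from [rpmm_cluster()].
#' @param ... Unused.
#' @return Tibble: `sample_id`, `mc` (integer), `mc_label` (`"MC1"`, ...),
#'   and `project` when known.
#' @export
tidy.mc_assignment <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = names(x$labels),
    mc = unname(x$labels),
    mc_label = paste0("MC", unname(x$labels))
  )
  if (!is.null(x$project)) out$project <- x$project
  out
}

#' @rdname tidy.mc_assignment
#' @return For `glance()`: one row with `n_samples`, `n_clusters`,
#'   `n_probes`, `mean_mc1`, `mean_mcn`.
#' @export
glance.mc_assignment <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$labels),
    n_clusters = x$n_clusters,
    n_probes = length(x$probe_set),
    mean_mc1 = unname(x$cluster_means[1]),
    mean_mcn = unname(x$cluster_means[x$n_clusters])
  )
}

#' Tidy a panel evaluation
#'
#' @param x A `panel_eval` from [evaluate_panel()] or
#'   [evaluate_metastasis_panel()].
#' @param ... Unused.
#' @return For `tidy()`: the per-sample call table. For `glance()`: the
#'   one-row metrics tibble.
#' @export
tidy.panel_eval <- function(x, ...) x$calls

#' @rdname tidy.panel_eval
#' @export
glance.panel_eval <- function(x, ...) x$metrics

#' Tidy a pipeline run
#'
#' @param x A `meth_run` from [run_nonclustered()] or [run_clustered()].
#' @param ... Unused.
#' @return For `tidy()`: the candidate table. For `glance()`: per-cancer
#'   panel metrics.
#' @export
tidy.meth_run <- function(x, ...) x$candidates

#' @rdname tidy.meth_run
#' @export
glance.meth_run <- function(x, ...) x$metrics

#' Plot the max-beta distribution of a panel evaluation
#'
#' Boxplots of each sample's maximum beta over the panel probes, grouped
#' by project and tissue class, with the call cutoff drawn as a dashed
#' line -- the standard way to show how a panel separates its target
#' cancer from everything else.
#'
#' @param object A `panel_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panel_eval <- function(object, ...) {
  d <- object$calls
  d$group <- paste(d$project, substr(d$tissue_class, 1, 1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$max_beta,
                                  fill = .data$project == object$panel$target)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$panel$cutoff, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70")) +
    ggplot2::labs(
      title = sprintf("%s panel (%s approach), %s scope",
                      object$panel$target, object$panel$approach, object$scope),
      x = NULL, y = "max beta over panel probes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot cluster mean methylation of an assignment
#'
#' @param object An `mc_assignment`.
#' @param ... Unused.
#' @return A ggplot object: cluster sizes and mean beta per methylation
#'   cluster, ordered MC1 (most methylated) downwards.
#' @export
autoplot.mc_assignment <- function(object, ...) {
  d <- tibble::tibble(
    mc = factor(names(object$cluster_means), levels = names(object$cluster_means)),
    mean_beta = unname(object$cluster_means),
    n = as.integer(table(factor(object$labels,
                                levels = seq_len(object$n_clusters))))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mc, y = .data$mean_beta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(
      title = if (is.null(object$project)) "Methylation clusters" else
        paste(object$project, "methylation clusters"),
      x = NULL, y = "mean beta over clustering probes") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Published worked-example confusion counts
#'
#' Confusion-count rows transcribed from published diagnostic-panel
#' evaluations of seven adenocarcinomas (identification and independent
#' verification cohorts, plus liver-metastasis rows), bundled as worked
#' examples for [metrics_from_counts()] and
#' [metastasis_metrics_from_counts()]. Each row carries the raw counts and
#' the percentages as printed at one-decimal precision; a handful of
#' printed cells are arithmetically inconsistent with their own counts and
#' are flagged by the package tests rather than silently corrected.
#'
#' @return Tibble with columns `table`, `cancer`, `dataset`, `approach`,
#'   `variant` (`primary` or `metastasis`), `n_probes`, the count columns
#'   and the printed percentage columns (`printed_*`).
#' @export
panel_count_examples <- function() {
  path <- system.file("extdata", "panel_count_examples.csv",
                      package = "methpanel", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    table = readr::col_character(),
    cancer = readr::col_character(),
    dataset = readr::col_character(),
    approach = readr::col_character(),
    variant = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
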