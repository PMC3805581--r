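# Quick-look plots for the pipeline's tabular results.

#' Plot submission completeness patterns
#'
#' Horizontal bars of the most frequent presence/absence patterns, labelled
#' by the object kinds each pattern includes.
#'
#' @param profiles Output of [completeness_profiles()].
#' @param top Number of patterns to show.
#' @return A ggplot object.
#' @export
plot_completeness <- function(profiles, top = 15) {
  stopifnot(nrow(profiles) > 0)
  lab <- apply(profiles[.sra_kinds], 1, function(b)
    paste(substr(.sra_kinds[b], 1, 3), collapse = "+"))
  df <- profiles |>
    mutate(pattern = factor(lab, levels = rev(unique(lab)))) |>
    dplyr::slice_head(n = top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "submissions", y = NULL,
                  title = "Metadata objects present per submission")
}

#' Plot a facet tabulation of the project list
#'
#' @param tab Output of [tabulate_by()].
#' @param top Number of categories to show.
#' @return A ggplot object.
#' @export
plot_facet <- function(tab, top = 15) {
  stopifnot(nrow(tab) > 0)
  df <- tab |>
    dplyr::slice_head(n = top) |>
    mutate(category = factor(.data$category, levels = rev(.data$category)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_studies, y = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "studies", y = NULL)
}

#' Plot the disease frequency list
#'
#' @param freq Output of [disease_frequency()].
#' @param top Number of diseases to show.
#' @return A ggplot object.
#' @export
plot_disease_frequency <- function(freq, top = 10) {
  stopifnot(nrow(freq) > 0)
  df <- freq |>
    dplyr::slice_head(n = top) |>
    mutate(name = factor(.data$name, levels = rev(.data$name)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_projects, y = .data$name)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "projects", y = NULL,
                  title = "Studies per disease term")
}

#' Plot study counts down the disease hierarchy
#'
#' Bars of rolled-up study counts for the nodes at one depth of the tree.
#'
#' @param object A `mesh_tree` from [build_disease_tree()].
#' @param depth Hierarchy depth to display (1 = branch roots).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mesh_tree
#' @export
autoplot.mesh_tree <- function(object, depth = 1, ...) {
  df <- as_tibble(object) |>
    filter(.data$depth == .env$depth) |>
    arrange(desc(.data$rolled_count)) |>
    mutate(label = dplyr::coalesce(.data$name, .data$tree_number),
           label = factor(.data$label, levels = rev(.data$label)))
  stopifnot(nrow(df) > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rolled_count, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "studies (subtree)", y = NULL)
}
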