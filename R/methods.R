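#' @export
print.coremix_fit <- function(x, ...) {
  cat(sprintf("<coremix_fit> %d species, %d reads (%.2f%% unassigned)\n",
              nrow(x$species), x$n_total, 100 * x$unassigned_fraction))
  cat(sprintf("  sweeps: %d burn-in + %d kept (thinning %d)%s\n",
              x$config$burn_in_sweeps, x$config$kept_samples,
              x$config$thinning,
              if (is.null(x$config$seed)) "" else
                sprintf(", seed %d", x$config$seed)))
  print(dplyr::arrange(x$species, dplyr::desc(.data$abundance_hat)), n = 10)
  invisible(x)
}

#' Tidy a fitted abundance model
#'
#' @param x A `coremix_fit`.
#' @param ... Unused.
#' @return One row per reference species: `species_id`, `length`,
#'   `mean_count` (posterior mean assigned reads), `theta_hat` (mixture
#'   weight) and `abundance_hat` (length-corrected relative abundance).
#' @export
tidy.coremix_fit <- function(x, ...) {
  x$species
}

#' One-row summary of a fitted abundance model
#'
#' @param x A `coremix_fit`.
#' @param ... Unused.
#' @return A tibble with the run-level numbers: read counts, unassigned
#'   fraction, sweep configuration, seed and the convergence flag (`NA` when
#'   no tolerance was requested).
#' @export
glance.coremix_fit <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$species),
    n_reads = x$n_total,
    n_assigned = x$n_occurrences,
    unassigned_fraction = x$unassigned_fraction,
    burn_in_sweeps = x$config$burn_in_sweeps,
    kept_samples = x$config$kept_samples,
    thinning = x$config$thinning,
    seed = x$config$seed %||% NA_integer_,
    converged = x$converged
  )
}

#' Plot estimated relative abundances
#'
#' @param object A `coremix_fit`.
#' @param truth Optional named vector of preset abundances to overlay.
#' @param ... Unused.
#' @return A ggplot: one bar per species, tallest first.
#' @export
autoplot.coremix_fit <- function(object, truth = NULL, ...) {
  tb <- dplyr::mutate(object$species, species_id = stats::reorder(
    .data$species_id, -.data$abundance_hat))
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$species_id,
                                        y = .data$abundance_hat)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "relative abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(truth)) {
    tt <- tibble::tibble(species_id = names(truth), abundance = unname(truth))
    p <- p + ggplot2::geom_point(
      data = tt, ggplot2::aes(x = .data$species_id, y = .data$abundance),
      colour = "black", shape = 4, size = 2)
  }
  p
}

#' Heatmap of between-sample Spearman distances
#'
#' @param dist_matrix Output of [sample_distance_matrix()].
#' @return A ggplot tile heatmap of the distances.
#' @export
plot_sample_distances <- function(dist_matrix) {
  tb <- tibble::as_tibble(as.data.frame(dist_matrix), rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "distance")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - Spearman") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
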