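#' Plot a similarity density profile
#'
#' @param object A `density_profile` from [density_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Jaccard similarity", y = "Density") +
    ggplot2::theme_minimal()
}

#' Plot Evanno diagnostics
#'
#' Two panels' worth of information in one: delta-K against K, with the
#' mean ln probability (rescaled) available via `which`.
#'
#' @param object A `delta_k` object from [compute_delta_k()].
#' @param which `"delta_k"` (default) or `"lnP"` (mean with SD bars).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_k
#' @export
autoplot.delta_k <- function(object, which = c("delta_k", "lnP"), ...) {
  which <- match.arg(which)
  d <- object$by_k
  if (which == "delta_k") {
    ggplot2::ggplot(dplyr::filter(d, !is.na(.data$delta_k)),
                    ggplot2::aes(x = .data$K, y = .data$delta_k)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(y = expression(Delta * K)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$K, y = .data$mean_lnP)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_lnP - .data$sd_lnP,
                                          ymax = .data$mean_lnP + .data$sd_lnP),
                             width = 0.2, na.rm = TRUE) +
      ggplot2::labs(y = "Mean ln P(data)") +
      ggplot2::theme_minimal()
  }
}

#' Overlaid density plot of similarity by relationship tier
#'
#' Emulates the classic one-dimensional density comparison of the whole
#' collection against documented relationship subsets.
#'
#' @param pairs A `similarity_pairs` tibble.
#' @param meta An [accession_meta()] with documented parents.
#' @param bandwidth Kernel SD on the 0--1 similarity scale (default
#'   0.0075, the percent-scale bandwidth 0.75 rescaled).
#' @return A ggplot object.
#' @export
plot_tier_densities <- function(pairs, meta, bandwidth = 0.0075) {
  p1 <- setNames(meta$parent1, meta$accession_id)
  p2 <- setNames(meta$parent2, meta$accession_id)
  shared <- function(i, j) {
    length(intersect(stats::na.omit(c(p1[i], p2[i])), stats::na.omit(c(p2[j], p1[j]))))
  }
  lab <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$acc_i[k]; j <- pairs$acc_j[k]
    if (j %in% c(p1[i], p2[i]) || i %in% c(p1[j], p2[j])) "parent_offspring"
    else if (shared(i, j) >= 2L) "full_siblings"
    else if (shared(i, j) >= 1L) "siblings"
    else "population"
  }, character(1))
  df <- bind_rows(
    tibble(jaccard = pairs$jaccard, tier = "population"),
    filter(tibble(jaccard = pairs$jaccard, tier = lab), .data$tier != "population")
  )
  df <- filter(df, !is.na(.data$jaccard))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$jaccard, colour = .data$tier)) +
    ggplot2::geom_density(bw = bandwidth) +
    ggplot2::labs(x = "Jaccard similarity", y = "Density", colour = "Tier") +
    ggplot2::theme_minimal()
}
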