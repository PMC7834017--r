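hdx_category_palette <- c(
  major_decrease = "#1f4e9c", modest_decrease = "#9ecae1",
  none = "grey85",
  modest_increase = "#a1d99b", major_increase = "#157f3b"
)

#' Plot a peptide-level difference map
#'
#' Peptide-by-time tile map colored with the standard HDX difference
#' palette (blues = protection on binding, greens = increased exchange).
#'
#' @param diffs Difference map from [difference_map()].
#' @return A ggplot object.
#' @export
plot_difference_map <- function(diffs) {
  d <- dplyr::mutate(diffs,
                     peptide = stats::reorder(
                       paste0(.data$start, "-", .data$end), .data$start),
                     time_f = factor(.data$time, levels = sort(unique(.data$time))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_f, y = .data$peptide,
                                  fill = .data$category)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = hdx_category_palette, drop = FALSE) +
    ggplot2::labs(x = "labeling time (s)", y = "peptide (N- to C-terminus)",
                  fill = "ΔD category",
                  title = paste0(attr(diffs, "state"), " - ",
                                 attr(diffs, "reference"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Plot consolidated residue annotations along the sequence
#'
#' @param annotations Tibble from [consolidate_residues()].
#' @param domains Optional domain map drawn as labeled spans.
#' @return A ggplot object.
#' @export
plot_residue_annotations <- function(annotations, domains = btk_domains()) {
  p <- ggplot2::ggplot(annotations,
                       ggplot2::aes(x = .data$residue, y = 1,
                                    fill = .data$category)) +
    ggplot2::geom_tile(height = 0.6) +
    ggplot2::scale_fill_manual(values = hdx_category_palette, drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(0, 2)) +
    ggplot2::labs(x = "residue", y = NULL, fill = "category") +
    ggplot2::theme_minimal()
  if (!is.null(domains)) {
    p <- p +
      ggplot2::annotate("rect", xmin = domains$start, xmax = domains$end,
                        ymin = 1.45, ymax = 1.75, fill = "grey70",
                        color = "white") +
      ggplot2::annotate("text", x = (domains$start + domains$end) / 2,
                        y = 1.9, label = domains$domain, size = 2.8)
  }
  p
}

#' Plot deuterium uptake curves for selected peptides
#'
#' @param table Uptake table.
#' @param peptide_ids Peptides to show.
#' @param states States to show; defaults to all.
#' @return A ggplot object (mean +/- sd per time, log-scaled time axis).
#' @export
plot_uptake_curves <- function(table, peptide_ids,
                               states = unique(table$state)) {
  curves <- dplyr::bind_rows(purrr::map(peptide_ids, function(pid) {
    dplyr::bind_rows(purrr::map(states, function(st) {
      aggregate_replicates(table, st, pid)
    }))
  }))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$mean,
                                       color = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             size = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~peptide_id, scales = "free_y") +
    ggplot2::labs(x = "labeling time (s)", y = "relative deuterium (Da)") +
    ggplot2::theme_bw()
}

#' @rdname fit_two_peaks
#' @param object A `peak_fit` object.
#' @exportS3Method ggplot2::autoplot
autoplot.peak_fit <- function(object, ...) {
  tr <- object$trace
  grid <- tibble::tibble(ppm = seq(max(tr$ppm), min(tr$ppm),
                                   length.out = 500))
  comp <- purrr::pmap(object$peaks, function(peak, center, fwhm, amplitude,
                                             area) {
    tibble::tibble(ppm = grid$ppm, peak = peak,
                   intensity = object$baseline +
                     amplitude / (1 + (2 * (grid$ppm - center) / fwhm)^2))
  })
  comp <- dplyr::bind_rows(comp)
  total <- dplyr::summarise(dplyr::group_by(comp, .data$ppm),
                            intensity = sum(.data$intensity) -
                              object$baseline, .groups = "drop")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.4, color = "grey50") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(color = .data$peak)) +
    ggplot2::geom_line(data = total, linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "1H chemical shift (ppm)", y = "intensity (a.u.)") +
    ggplot2::theme_bw()
}

#' Plot a covalent-inhibitor titration
#'
#' Recovered inactive-state fractions versus drug:protein molar ratio,
#' with the stoichiometric one-site model
#' `f0 + min(ratio, 1) * (1 - f0)` overlaid.
#'
#' @param titration Tibble from [analyze_titration()].
#' @return A ggplot object.
#' @export
plot_titration <- function(titration) {
  f0 <- titration$f_inactive[which.min(titration$molar_ratio)]
  grid <- tibble::tibble(molar_ratio = seq(0, max(titration$molar_ratio),
                                           length.out = 200))
  grid$f_inactive <- f0 + stoichiometric_bound_fraction(grid$molar_ratio) *
    (1 - f0)
  ggplot2::ggplot(titration, ggplot2::aes(x = .data$molar_ratio,
                                          y = .data$f_inactive)) +
    ggplot2::geom_line(data = grid, color = "grey60", linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "drug : protein molar ratio",
                  y = "inactive-state fraction") +
    ggplot2::theme_bw()
}
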