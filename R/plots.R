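#' Plot a conservation profile
#'
#' Modal-base frequency per pattern position, lettered with the modal base
#' and shaded by whether the position passes the conservation threshold.
#'
#' @param object A `palcore_profile` from [conservation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot palcore_profile
#' @export
autoplot.palcore_profile <- function(object, ...) {
  df <- as_tibble(object)
  thr <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$modal_freq,
                                   fill = .data$conserved)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$modal_base), vjust = -0.3,
                       size = 3) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70")) +
    ggplot2::scale_x_continuous(breaks = df$position) +
    ggplot2::labs(
      x = "pattern position", y = "modal base frequency",
      fill = sprintf("conserved (>= %.2f)", thr),
      title = sprintf("Conservation profile, stratum <= %s mismatches (n = %d)",
                      format(attr(object, "stratum")), attr(object, "n_sites"))
    ) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::theme_minimal()
}

#' Map site positions along the genome
#'
#' Site positions against mismatch count, optionally marking the replication
#' origin; a quick visual check of clustering and replichore balance.
#'
#' @param sites Site tibble from [scan_genome()] or a `palcore_report`.
#' @param L Genome length (taken from the report if one is given).
#' @param ori Optional origin coordinate to mark.
#' @return A ggplot object.
#' @export
plot_site_map <- function(sites, L = NULL, ori = NULL) {
  if (inherits(sites, "palcore_report")) {
    L <- sites$genome_summary$length
    ori <- ori %||% sites$provenance$ori
    sites <- sites$sites
  }
  stopifnot(!is.null(L))
  gg <- ggplot2::ggplot(sites, ggplot2::aes(
    x = .data$start, y = factor(.data$mismatches),
    colour = .data$orientation
  )) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::xlim(0, L) +
    ggplot2::labs(x = "genome position (bp)", y = "mismatches",
                  colour = "orientation") +
    ggplot2::theme_minimal()
  if (!is.null(ori)) {
    gg <- gg + ggplot2::geom_vline(xintercept = ori, linetype = "dotted")
  }
  gg
}

#' Plot cumulative GC skew
#'
#' @param skew Tibble from [cumulative_gc_skew()].
#' @return A ggplot object with the extremum positions marked.
#' @export
plot_gc_skew <- function(skew) {
  ggplot2::ggplot(skew, ggplot2::aes(x = .data$position, y = .data$skew)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(skew, "min_pos"),
                        linetype = "dotted", colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = attr(skew, "max_pos"),
                        linetype = "dotted", colour = "#b2182b") +
    ggplot2::labs(x = "genome position (bp)", y = "cumulative (G - C)") +
    ggplot2::theme_minimal()
}
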