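#' Interval genetic map from recombinant profiles
#'
#' Map length of each marked interval: 100 times the number of progeny with a
#' crossover called in that interval divided by the total progeny scored
#' (centimorgans). Because every observed crossover lies in exactly one
#' interval, the unrounded interval values sum to the chromosome total from
#' [total_map_length()] of the same profiles.
#'
#' @param profiles Output of [call_crossovers()].
#' @param map The [marker_map()]; defaults to the one attached to `profiles`.
#' @return A tibble of class `genetic_map` with columns `interval`, `index`,
#'   `recombinants` and `cM`, plus attributes `N` and `total_cM`.
#' @examples
#' x <- marker_map_x()
#' prog <- simulate_meiosis(2000, x, exchange_freqs = c(0.1, 0.6, 0.3),
#'                          seed = 7)
#' interval_map(call_crossovers(prog, x))
#' @export
interval_map <- function(profiles, map = NULL) {
  map <- map %||% attr(profiles, "marker_map")
  assert_marker_map(map)
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    abort("`profiles` must be a non-empty data frame of recombinant profiles.")
  }
  N <- nrow(profiles)
  hits <- tabulate(unlist(profiles$intervals), nbins = n_intervals(map))
  out <- tibble(
    interval = map$intervals$name,
    index = map$intervals$index,
    recombinants = hits,
    cM = 100 * hits / N
  )
  structure(out,
            class = c("genetic_map", class(out)),
            N = N,
            total_cM = sum(out$cM),
            marker_map = map)
}

#' Per-interval percent-of-control ratios
#'
#' The centromere-effect readout: each interval's map length in the test
#' genotype expressed as a percentage of the control genotype, computed on
#' unrounded centimorgan values and presented to the nearest integer percent.
#' A `Total` row compares the chromosome totals. Intervals where the control
#' map length is zero have an undefined ratio and are reported as `NA`.
#'
#' @param test,control `genetic_map` objects over the same marker map (or
#'   tibbles with `interval` and `cM` columns).
#' @return A tibble with columns `interval`, `cM_control`, `cM_test`,
#'   `ratio` (unrounded percent, `NA` where undefined) and `percent`
#'   (integer presentation value).
#' @examples
#' x <- marker_map_x()
#' a <- interval_map(call_crossovers(
#'   simulate_meiosis(1000, x, c(0.1, 0.9), seed = 1), x))
#' percent_of_control(a, a)  # 100% everywhere
#' @export
percent_of_control <- function(test, control) {
  if (!identical(test$interval, control$interval)) {
    abort("`test` and `control` must be genetic maps over the same intervals.")
  }
  tot_t <- attr(test, "total_cM") %||% sum(test$cM)
  tot_c <- attr(control, "total_cM") %||% sum(control$cM)
  out <- tibble(
    interval = c(test$interval, "Total"),
    cM_control = c(control$cM, tot_c),
    cM_test = c(test$cM, tot_t)
  )
  out$ratio <- ifelse(out$cM_control > 0, 100 * out$cM_test / out$cM_control,
                      NA_real_)
  out$percent <- round(out$ratio)
  out
}

#' Compare two genotypes interval by interval
#'
#' Builds the standard recombination-table comparison between a test and a
#' control genotype: per-interval map lengths, percent-of-control ratios, and
#' a two-sided Fisher exact test per interval on recombinant vs
#' non-recombinant progeny counts. P-values are raw (no multiple-testing
#' correction); significance stars at 0.05 and 0.01 are presentation only.
#'
#' @inheritParams percent_of_control
#' @return A tibble with columns `interval`, `cM_control`, `cM_test`,
#'   `percent`, `p.value` and `signif`.
#' @export
compare_genetic_maps <- function(test, control) {
  N_t <- attr(test, "N")
  N_c <- attr(control, "N")
  if (is.null(N_t) || is.null(N_c)) {
    abort("Both maps must carry an `N` attribute (use `interval_map()`).")
  }
  poc <- percent_of_control(test, control)
  p <- c(
    purrr::map2_dbl(test$recombinants, control$recombinants, function(rt, rc) {
      fisher_2x2(rt, N_t - rt, rc, N_c - rc)$p.value
    }),
    NA_real_
  )
  poc$p.value <- p
  poc$signif <- dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
  poc
}

#' @exportS3Method ggplot2::autoplot
autoplot.genetic_map <- function(object, ...) {
  d <- as_tibble(object)
  d$interval <- factor(d$interval, levels = d$interval)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval, y = .data$cM)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Interval", y = "Map length (cM)") +
    ggplot2::theme_minimal()
}

#' Percent-of-control bar chart
#'
#' Plots per-interval percent-of-control ratios with a dashed reference line
#' at 100% (the control level), the usual display for a shift in crossover
#' distribution along the chromosome arm.
#'
#' @param comparison Output of [percent_of_control()] or
#'   [compare_genetic_maps()].
#' @param include_total Keep the `Total` row in the plot? Default `FALSE`.
#' @return A ggplot object.
#' @export
plot_percent_of_control <- function(comparison, include_total = FALSE) {
  d <- comparison
  if (!include_total) d <- d[d$interval != "Total", , drop = FALSE]
  d$interval <- factor(d$interval, levels = unique(d$interval))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval, y = .data$ratio)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Interval", y = "Percent of control (%)") +
    ggplot2::theme_minimal()
}
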