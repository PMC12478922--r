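#' Viability-adjusted nondisjunction rates
#'
#' In the standard X^Y / compound-4 test cross, each recovered X-exceptional
#' progeny class (diplo-X and nullo-X ova) has a reciprocal zygote class that
#' dies, so every recovered exceptional represents two nondisjunction events
#' and the progeny total is adjusted upward by one inviable zygote per
#' recovered X-exceptional: `adjusted_total = regular + 2 * x_exceptional`.
#' Rates are then
#' `%X NDJ = 100 * 2 * x_exceptional / adjusted_total` and
#' `%4 NDJ = 100 * 2 * fourth_exceptional / adjusted_total` (4th-chromosome
#' exceptionals are doubled identically but do not enter the adjusted total,
#' which is the X-assay denominator used for both rates).
#'
#' Which phenotype classes count as diplo-X versus nullo-X ova is decided by
#' the cross design upstream; this function takes the tallied counts.
#'
#' @param regular Count of regular (non-exceptional) progeny.
#' @param x_exceptional Count of recovered X-exceptional progeny
#'   (diplo-X plus nullo-X classes).
#' @param fourth_exceptional Count of recovered 4th-chromosome exceptional
#'   progeny.
#' @return A one-row tibble of class `ndj_result`: the input counts,
#'   `raw_total`, `adjusted_total`, unrounded `pct_x_ndj` and `pct_4_ndj`,
#'   and 2-decimal `pct_x_label` / `pct_4_label` presentation values.
#' @examples
#' ndj_rates(regular = 980, x_exceptional = 10)  # 2.00% X NDJ of 1000
#' @export
ndj_rates <- function(regular, x_exceptional, fourth_exceptional = 0) {
  cnt <- c(regular, x_exceptional, fourth_exceptional)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    abort("Progeny counts must be non-negative integers.")
  }
  if (regular + x_exceptional == 0) {
    abort("No progeny scored; nondisjunction rates undefined.")
  }
  adj <- regular + 2 * x_exceptional
  out <- tibble(
    regular = regular,
    x_exceptional = x_exceptional,
    fourth_exceptional = fourth_exceptional,
    raw_total = regular + x_exceptional,
    adjusted_total = adj,
    pct_x_ndj = 100 * 2 * x_exceptional / adj,
    pct_4_ndj = 100 * 2 * fourth_exceptional / adj
  )
  out$pct_x_label <- sprintf("%.2f", round(out$pct_x_ndj, 2))
  out$pct_4_label <- sprintf("%.2f", round(out$pct_4_ndj, 2))
  class(out) <- c("ndj_result", class(out))
  out
}

#' Back-solve exceptional progeny counts from a printed NDJ rate
#'
#' Published nondisjunction tables often print only the percentage and the
#' adjusted total. Under the [ndj_rates()] formula the recovered exceptional
#' count is `E = pct/100 * adjusted_total / 2`; this function rounds that to
#' the nearest integer and checks that re-applying the formula reproduces the
#' printed percentage at 2 decimals.
#'
#' @param pct_ndj Printed percent nondisjunction (e.g. `0.64`).
#' @param adjusted_total Printed viability-adjusted progeny total.
#' @return A one-row tibble with `exceptional` (integer count), `regular`
#'   (implied regular count) and `consistent` (does the integer count
#'   reproduce the printed rate?).
#' @examples
#' ndj_invert(0.64, 1878)  # 6 recovered X-exceptional progeny
#' @export
ndj_invert <- function(pct_ndj, adjusted_total) {
  E <- round(pct_ndj / 100 * adjusted_total / 2)
  pct_back <- round(100 * 2 * E / adjusted_total, 2)
  tibble(
    exceptional = as.integer(E),
    regular = as.integer(adjusted_total - 2 * E),
    consistent = isTRUE(all.equal(pct_back, round(pct_ndj, 2)))
  )
}

#' Compare nondisjunction rates between two genotypes
#'
#' Two-sided exact test that the nondisjunction event probabilities differ.
#' Each recovered exceptional is treated as two events among the
#' viability-adjusted totals and the resulting event/non-event counts are
#' compared with [fisher_2x2()]. This exact conditional comparison stands in
#' for the classical normal-approximation treatment of such assays and is
#' flagged as such in the output.
#'
#' @param a,b `ndj_result` rows from [ndj_rates()] (or lists with `regular`
#'   and `x_exceptional` / `fourth_exceptional` fields).
#' @param chromosome Which assay to compare: `"X"` (default) or `"4"`.
#' @return A one-row tibble with the event counts, adjusted totals,
#'   `p.value` and a `method` note.
#' @examples
#' a <- ndj_rates(1866, 6)
#' b <- ndj_rates(1041, 1)
#' ndj_compare(a, b)
#' @export
ndj_compare <- function(a, b, chromosome = c("X", "4")) {
  chromosome <- match.arg(chromosome)
  exc <- function(x) {
    if (chromosome == "X") x$x_exceptional else x$fourth_exceptional
  }
  adj <- function(x) x$regular + 2 * x$x_exceptional
  ev_a <- 2 * exc(a); tot_a <- adj(a)
  ev_b <- 2 * exc(b); tot_b <- adj(b)
  if (tot_a == 0 || tot_b == 0) abort("Degenerate assay totals.")
  ft <- fisher_2x2(ev_a, tot_a - ev_a, ev_b, tot_b - ev_b)
  tibble(
    chromosome = chromosome,
    events_a = ev_a, adjusted_total_a = tot_a,
    events_b = ev_b, adjusted_total_b = tot_b,
    estimate = ft$estimate,
    p.value = ft$p.value,
    method = "Exact conditional (Fisher) comparison of doubled event counts; approximation to the classical NDJ test"
  )
}
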