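#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test on the table `rbind(c(a, b), c(c, d))`. The
#' two-sided p-value is the sum of hypergeometric point probabilities of all
#' tables (with the observed margins) whose probability does not exceed that
#' of the observed table — the convention of the common online contingency
#' calculators and of `stats::fisher.test()`. A relative tolerance of 1e-7 is
#' applied to the "does not exceed" comparison so ties are counted. The
#' reported odds ratio is the sample odds ratio `(a * d) / (b * c)`, not the
#' conditional MLE.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise: `a`, `b` are the
#'   first group's two outcome counts, `c`, `d` the second group's.
#' @return A one-row tibble with columns `estimate` (sample odds ratio),
#'   `p.value`, `method` and `alternative`.
#' @examples
#' fisher_2x2(5, 5, 5, 5)           # p = 1, symmetric table
#' fisher_2x2(2415, 211, 1254, 295) # NCO+SCO vs DCO+TCO, two genotypes
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("Cell counts must be non-negative integers.")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    abort("Fisher exact test undefined: a table margin is zero.")
  }
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n2):min(k, m)
  dens <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  # new_tibble keeps this cheap enough for exhaustive enumeration tests
  tibble::new_tibble(
    list(
      estimate = or,
      p.value = p,
      method = "Fisher exact test (two-sided, point-probability rule)",
      alternative = "two.sided"
    ),
    nrow = 1L
  )
}

#' Compare crossover class distributions between genotypes
#'
#' Collapses each genotype's class counts into low (NCO + SCO) versus high
#' (DCO and above) crossover classes and tests the 2x2 table with
#' [fisher_2x2()]. A significant result indicates an excess of chromatids
#' experiencing more than one crossover in one genotype.
#'
#' @param a,b [class_counts()] for the two genotypes (both with classes up to
#'   at least DCO).
#' @param labels Optional length-2 character vector naming the genotypes.
#' @return A one-row tibble with the collapsed table cells
#'   (`low_a`, `high_a`, `low_b`, `high_b`), `estimate` (odds ratio),
#'   `p.value` and `comparison` label.
#' @examples
#' ctrl <- class_counts(c(1233, 1182, 207, 4))
#' test <- class_counts(c(565, 689, 271, 24))
#' class_collapse_test(ctrl, test)
#' @export
class_collapse_test <- function(a, b, labels = c("a", "b")) {
  na <- cc_counts(a)
  nb <- cc_counts(b)
  if (length(na) < 3 || length(nb) < 3) {
    abort("Both class-count sets must extend to at least the DCO class.")
  }
  low_a <- sum(na[1:2]); high_a <- sum(na[-(1:2)])
  low_b <- sum(nb[1:2]); high_b <- sum(nb[-(1:2)])
  ft <- fisher_2x2(low_a, high_a, low_b, high_b)
  tibble(
    comparison = sprintf("NCO+SCO vs DCO+ (%s vs %s)", labels[1], labels[2]),
    low_a = low_a, high_a = high_a, low_b = low_b, high_b = high_b,
    estimate = ft$estimate,
    p.value = ft$p.value
  )
}

#' Progeny per producing female
#'
#' Fertility summary for a brood assay: total progeny divided by the number
#' of females that produced any progeny (non-producers are excluded from the
#' denominator).
#'
#' @param progeny_per_female Non-negative integer vector, one entry per mated
#'   female (zeros mark non-producing females).
#' @return A one-row tibble with `n_females`, `n_producing`, `total_progeny`
#'   and `progeny_per_female`.
#' @examples
#' fertility_summary(c(10, 10, 0))  # 10 progeny per producing female
#' @export
fertility_summary <- function(progeny_per_female) {
  x <- as.numeric(progeny_per_female)
  if (length(x) == 0 || any(is.na(x)) || any(x < 0)) {
    abort("`progeny_per_female` must be non-negative counts.")
  }
  producing <- x > 0
  if (!any(producing)) {
    abort("No producing females; progeny per female undefined.")
  }
  tibble(
    n_females = length(x),
    n_producing = sum(producing),
    total_progeny = sum(x),
    progeny_per_female = sum(x) / sum(producing)
  )
}
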