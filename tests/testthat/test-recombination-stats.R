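test_that("interval map lengths count recombinants per interval", {
  x <- marker_map_x()
  prof <- tibble::tibble(
    id = as.character(1:100),
    crossover_count = c(rep(1L, 10), rep(0L, 90)),
    intervals = c(replicate(10, 2L, simplify = FALSE),
                  replicate(90, integer(0), simplify = FALSE))
  )
  gm <- interval_map(prof, x)
  expect_equal(gm$cM, c(0, 10, 0, 0))
  expect_equal(attr(gm, "total_cM"), 10)

  all_nco <- tibble::tibble(id = "a", crossover_count = 0L,
                            intervals = list(integer(0)))
  expect_equal(interval_map(all_nco, x)$cM, rep(0, 4))
})

test_that("interval map lengths sum exactly to the class-count total", {
  x <- marker_map_x()
  prog <- simulate_meiosis(20000, x, c(0.0967, 0.5941, 0.2970, 0.0122),
                           interval_weights = c(13.6, 20.8, 19.5, 7.3) / 61.2,
                           seed = 33)
  prof <- call_crossovers(prog, x)
  gm <- interval_map(prof, x)
  expect_equal(attr(gm, "total_cM"),
               total_map_length(tabulate_classes(prof)),
               tolerance = 1e-12)
  # and each interval's rate is within 3 binomial SD of its exact expectation:
  # a rank-k tetrad marks interval i with its inclusion probability in k
  # weighted draws without replacement, and the recovered chromatid shows
  # that exchange with probability 1/2
  E <- c(0.0967, 0.5941, 0.2970, 0.0122)
  w <- c(13.6, 20.8, 19.5, 7.3) / 61.2
  p_int <- Reduce(`+`, lapply(0:3, function(k) {
    E[k + 1] * oracle_inclusion_prob(w, k) / 2
  }))
  for (i in 1:4) {
    sd_i <- sqrt(p_int[i] * (1 - p_int[i]) / 20000)
    expect_lt(abs(gm$cM[i] / 100 - p_int[i]), 3 * sd_i)
  }
})

test_that("percent-of-control ratios use unrounded map lengths", {
  x <- marker_map_x()
  prof <- tibble::tibble(id = "a", crossover_count = 1L, intervals = list(1L))
  gm <- interval_map(prof, x)
  poc <- percent_of_control(gm, gm)
  expect_equal(poc$percent[!is.na(poc$percent)],
               rep(100, sum(!is.na(poc$percent))))

  # chromosome totals from the published class counts give 137%
  ratio <- 100 * total_map_length(counts_x_mau) / total_map_length(counts_x_control)
  expect_equal(round(ratio), 137)

  # undefined where the control interval has no recombinants
  ctrl0 <- gm
  ctrl0$cM <- c(0, 1, 1, 1)
  poc0 <- percent_of_control(gm, ctrl0)
  expect_true(is.na(poc0$percent[1]))
})

test_that("fisher_2x2 matches enumeration, symmetry, and published calls", {
  expect_equal(fisher_2x2(5, 5, 5, 5)$p.value, 1)

  # NCO+SCO vs DCO+TCO, control vs replacement, X chromosome
  expect_lt(fisher_2x2(2415, 211, 1254, 295)$p.value, 0.0001)

  # row swap leaves p unchanged and inverts the odds ratio
  f1 <- fisher_2x2(12, 5, 3, 9)
  f2 <- fisher_2x2(3, 9, 12, 5)
  expect_equal(f1$p.value, f2$p.value)
  expect_equal(f1$estimate, 1 / f2$estimate)

  # exhaustive check against the enumeration oracle on small tables
  for (r1 in 1:8) for (r2 in 1:8) for (c1 in 1:(r1 + r2 - 1)) {
    if (r1 + r2 - c1 < 1) next
    for (a in max(0, c1 - r2):min(c1, r1)) {
      b <- r1 - a; cc <- c1 - a; d <- r2 - cc
      expect_equal(fisher_2x2(a, b, cc, d)$p.value,
                   oracle_fisher_p(a, b, cc, d),
                   tolerance = 1e-10)
    }
  }

  # cross-check against the reference implementation on random tables
  set.seed(5)
  for (i in 1:50) {
    t <- matrix(sample(0:25, 4, TRUE), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])$p.value,
                 stats::fisher.test(t)$p.value, tolerance = 1e-7)
  }

  expect_error(fisher_2x2(0, 0, 3, 4), "margin")
})

test_that("class-collapse comparison flags the excess of multi-crossover chromatids", {
  ctrl <- class_counts(counts_x_control)
  mau <- class_counts(counts_x_mau)
  expect_equal(class_collapse_test(ctrl, ctrl)$p.value, 1)

  res_x <- class_collapse_test(ctrl, mau, labels = c("control", "mau"))
  expect_equal(c(res_x$low_a, res_x$high_a, res_x$low_b, res_x$high_b),
               c(2415, 211, 1254, 295))
  expect_lt(res_x$p.value, 0.0001)

  res_3 <- class_collapse_test(class_counts(counts_3_control),
                               class_counts(counts_3_mau))
  expect_lt(res_3$p.value, 0.0001)
})

test_that("interval-wise genotype comparison mirrors the recombination table", {
  x <- marker_map_x()
  E <- c(0.0967, 0.5941, 0.2970, 0.0122)
  w <- c(13.6, 20.8, 19.5, 7.3) / 61.2
  gm_a <- interval_map(call_crossovers(simulate_meiosis(4000, x, E, w, seed = 1), x))
  gm_b <- interval_map(call_crossovers(simulate_meiosis(4000, x, E, w, seed = 2), x))
  cmp <- compare_genetic_maps(gm_a, gm_b)
  expect_equal(cmp$interval, c(x$intervals$name, "Total"))
  expect_true(all(cmp$p.value[1:4] >= 0 & cmp$p.value[1:4] <= 1))
  cmp_same <- compare_genetic_maps(gm_a, gm_a)
  expect_equal(cmp_same$percent[1:4], rep(100, 4))
  expect_equal(cmp_same$p.value[1:4], rep(1, 4))
})

test_that("fertility is progeny per producing female", {
  expect_equal(fertility_summary(c(10, 10))$progeny_per_female, 10)
  expect_equal(fertility_summary(c(0, 5))$progeny_per_female, 5)
  expect_equal(fertility_summary(c(0, 5))$n_producing, 1)
  expect_error(fertility_summary(c(0, 0)), "No producing females")
})
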