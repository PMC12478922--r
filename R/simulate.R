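#' Forward simulation of female meiosis over a marker map
#'
#' Generates progeny marker tables with exactly the statistical structure the
#' Weinstein estimator assumes. Per meiosis: the tetrad's exchange rank `k`
#' is drawn from `exchange_freqs`; each exchange is placed into a marked
#' interval according to `interval_weights`; each exchange involves one of
#' the two chromatids of each homolog, chosen uniformly and independently
#' (no chromatid interference); finally one of the four chromatids is
#' recovered uniformly at random and its parental-origin sequence over the
#' loci is emitted (the origin switches at every interval where the recovered
#' chromatid participated in an odd number of exchanges).
#'
#' By default exchanges of one tetrad are placed into *distinct* intervals
#' (weighted sampling without replacement), so every exchange is observable
#' and the Weinstein forward model holds exactly; this requires at least as
#' many positively-weighted intervals as the largest rank with
#' `exchange_freqs > 0`. Setting `allow_double_exchange = TRUE` places
#' exchanges independently (with replacement), allowing two exchanges in one
#' interval to cancel invisibly — useful to study undetected-double bias, not
#' part of the core model.
#'
#' Randomness is consumed in a fixed documented order — all ranks `k`, then
#' the interval placements meiosis by meiosis, then the per-exchange
#' chromatid picks (homolog 1 then homolog 2), then the recovery picks — so a
#' fixed `seed` reproduces the progeny table byte for byte.
#'
#' @param n Number of meioses (progeny records) to simulate.
#' @param map A [marker_map()].
#' @param exchange_freqs Numeric vector `(E_0, ..., E_kmax)` of tetrad
#'   exchange-rank frequencies; non-negative, summing to 1.
#' @param interval_weights Per-interval placement weights (non-negative,
#'   summing to 1); default uniform over the map's intervals.
#' @param seed Optional integer seed for reproducibility.
#' @param allow_double_exchange Place exchanges with replacement? Default
#'   `FALSE` (distinct intervals per tetrad).
#' @param keep_details Attach a `"details"` attribute with the per-exchange
#'   bookkeeping (meiosis, interval, chromatids involved, recovered
#'   chromatid, rank)? Default `FALSE`.
#' @return A tibble with columns `id` and one `"P1"`/`"P2"` column per locus,
#'   suitable for [call_crossovers()].
#' @examples
#' simulate_meiosis(5, marker_map_x(), exchange_freqs = c(0, 1), seed = 1)
#' @export
simulate_meiosis <- function(n, map, exchange_freqs, interval_weights = NULL,
                             seed = NULL, allow_double_exchange = FALSE,
                             keep_details = FALSE) {
  assert_marker_map(map)
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort("`n` must be a positive integer.")
  E <- as.numeric(exchange_freqs)
  check_simplex(E, "exchange_freqs")
  n_int <- n_intervals(map)
  w <- interval_weights %||% rep(1 / n_int, n_int)
  w <- as.numeric(w)
  if (length(w) != n_int) {
    abort(sprintf("`interval_weights` must have one weight per interval (%d).", n_int))
  }
  check_simplex(w, "interval_weights")
  kmax <- length(E) - 1L
  k_top <- if (any(E[-1] > 0)) max(which(E > 0)) - 1L else 0L
  if (!allow_double_exchange && k_top > sum(w > 0)) {
    abort(sprintf(
      "Cannot place %d exchanges into %d positively-weighted intervals without doubles; enlarge the map, adjust weights, or set `allow_double_exchange = TRUE`.",
      k_top, sum(w > 0)
    ))
  }

  if (!is.null(seed)) set.seed(seed)

  # 1. exchange rank per meiosis
  k <- sample.int(kmax + 1L, n, replace = TRUE, prob = E) - 1L
  n_ex <- sum(k)

  # 2. interval placement (meiosis by meiosis for the without-replacement draw)
  mei <- rep.int(seq_len(n), k)
  iv <- integer(n_ex)
  if (n_ex > 0) {
    if (allow_double_exchange) {
      iv <- sample.int(n_int, n_ex, replace = TRUE, prob = w)
    } else {
      pos <- 0L
      for (i in which(k > 0L)) {
        ki <- k[i]
        iv[pos + seq_len(ki)] <- if (ki == 1L) {
          sample.int(n_int, 1L, prob = w)
        } else {
          sample.int(n_int, ki, replace = FALSE, prob = w)
        }
        pos <- pos + ki
      }
    }
  }

  # 3. chromatid involvement: one of {1,2} from homolog 1, one of {3,4} from homolog 2
  chrom_a <- if (n_ex > 0) sample.int(2L, n_ex, replace = TRUE) else integer(0)
  chrom_b <- if (n_ex > 0) sample.int(2L, n_ex, replace = TRUE) + 2L else integer(0)

  # 4. recovered chromatid per meiosis
  recovered <- sample.int(4L, n, replace = TRUE)

  r_ex <- recovered[mei]
  participated <- (r_ex <= 2L & chrom_a == r_ex) | (r_ex >= 3L & chrom_b == r_ex)

  # parity of participations per (meiosis, interval)
  lin <- mei[participated] + n * (iv[participated] - 1L)
  parity <- matrix(tabulate(lin, nbins = n * n_int) %% 2L, n, n_int)

  # cumulative parity left of each locus boundary
  cum <- parity
  if (n_int > 1) {
    for (j in 2:n_int) cum[, j] <- cum[, j - 1L] + parity[, j]
  }
  start <- as.integer(recovered > 2L)        # 0 = P1 homolog, 1 = P2 homolog
  origin <- cbind(start, (start + cum) %% 2L)
  alleles <- matrix(c("P1", "P2")[origin + 1L], n, n_int + 1L,
                    dimnames = list(NULL, map$loci))

  out <- as_tibble(as.data.frame(alleles, stringsAsFactors = FALSE))
  out <- dplyr::bind_cols(tibble(id = sprintf("m%07d", seq_len(n))), out)
  attr(out, "marker_map") <- map
  if (keep_details) {
    attr(out, "details") <- list(
      rank = k,
      exchanges = tibble(meiosis = mei, interval = iv,
                         chromatid_a = chrom_a, chromatid_b = chrom_b),
      recovered = recovered
    )
  }
  out
}

check_simplex <- function(x, arg) {
  if (any(is.na(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", arg))
  }
  if (abs(sum(x) - 1) > 1e-8) {
    abort(sprintf("`%s` must sum to 1.", arg))
  }
  invisible(x)
}

#' Recover exchange ranks and genetic map from simulated progeny
#'
#' Closes the loop on the forward simulator: calls crossovers on the progeny
#' table, tabulates classes, estimates the exchange-rank distribution
#' (constrained MLE by default) and builds the interval genetic map.
#'
#' @param progeny Progeny tibble from [simulate_meiosis()] (or any table
#'   accepted by [call_crossovers()]).
#' @param map A [marker_map()]; defaults to the one attached to `progeny`.
#' @param kmax Passed to the estimator; defaults to the largest observed
#'   class.
#' @param method `"mle"` (default) or `"direct"`.
#' @return A list with elements `class_counts`, `exchange_ranks` and
#'   `genetic_map`.
#' @examples
#' x <- marker_map_x()
#' prog <- simulate_meiosis(5000, x, c(0.1, 0.6, 0.3), seed = 42)
#' fit <- recover_parameters(prog, x)
#' tidy(fit$exchange_ranks)
#' @export
recover_parameters <- function(progeny, map = NULL, kmax = NULL,
                               method = c("mle", "direct")) {
  method <- match.arg(method)
  map <- map %||% attr(progeny, "marker_map")
  assert_marker_map(map)
  profiles <- call_crossovers(progeny, map)
  cc <- tabulate_classes(profiles)
  er <- switch(method,
               mle = weinstein_mle(cc, kmax = kmax),
               direct = weinstein_direct(cc, kmax = kmax))
  list(
    class_counts = cc,
    exchange_ranks = er,
    genetic_map = interval_map(profiles, map)
  )
}
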