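#' Chromatid class probabilities implied by an exchange-rank distribution
#'
#' In female meiosis only one of the four chromatids of a tetrad is recovered
#' in a given offspring. Under the classical no-chromatid-interference model,
#' each exchange involves one randomly chosen chromatid per homolog, so a
#' chromatid drawn from a tetrad with `k` exchanges carries `j` crossovers
#' with binomial probability `choose(k, j) / 2^k`. The marginal probability
#' that a recovered chromatid shows exactly `j` crossovers is therefore
#' `p_j = sum_{k >= j} E_k * choose(k, j) / 2^k`.
#'
#' @param E An [exchange_ranks] object, or a non-negative numeric vector
#'   `(E_0, ..., E_kmax)` summing to 1.
#' @return Numeric vector `(p_0, ..., p_kmax)`; non-negative, sums to 1.
#' @examples
#' class_probabilities(c(0, 1, 0, 0))  # obligate single exchange: 1/2, 1/2
#' @export
class_probabilities <- function(E) {
  E <- er_freqs(E)
  if (any(E < 0)) {
    abort("Exchange-rank frequencies must be non-negative.")
  }
  if (abs(sum(E) - 1) > 1e-8) {
    abort("Exchange-rank frequencies must sum to 1.")
  }
  drop(E %*% recovery_matrix(length(E) - 1L))
}

# B[k+1, j+1] = choose(k, j) / 2^k : probability a chromatid from an E_k
# tetrad carries j observable crossovers (no chromatid interference).
recovery_matrix <- function(kmax) {
  k <- 0:kmax
  outer(k, k, function(k, j) ifelse(j <= k, choose(k, j) / 2^k, 0))
}

er_freqs <- function(E) {
  if (inherits(E, "exchange_ranks")) return(E$E)
  as.numeric(E)
}

new_exchange_ranks <- function(E, method, loglik = NA_real_, feasible = TRUE,
                               counts = NULL, converged = NA, iterations = NA_integer_) {
  structure(
    list(
      E = setNames(as.numeric(E), paste0("E", seq_along(E) - 1L)),
      kmax = length(E) - 1L,
      method = method,
      loglik = loglik,
      feasible = feasible,
      counts = counts,
      converged = converged,
      iterations = iterations
    ),
    class = "exchange_ranks"
  )
}

#' @export
print.exchange_ranks <- function(x, ...) {
  cat(sprintf("<exchange_ranks> method = %s, kmax = %d%s\n", x$method, x$kmax,
              if (!x$feasible) " (INFEASIBLE: negative frequencies)" else ""))
  print(round(x$E, 4))
  if (!is.na(x$loglik)) cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  cat(sprintf("mean exchanges per tetrad: %.4f\n", mean_exchanges(x)))
  invisible(x)
}

multinom_loglik <- function(n, p) {
  # kernel only (no multinomial coefficient); 0 * log(0) treated as 0
  use <- n > 0
  if (any(p[use] <= 0)) return(-Inf)
  sum(n[use] * log(p[use]))
}

#' Weinstein tetrad analysis: direct inversion
#'
#' Recovers the tetrad exchange-rank frequencies `E_0..E_kmax` from observed
#' chromatid class counts by inverting the recovery model
#' `p_j = sum_k E_k choose(k, j)/2^k`. The system is triangular, so it is
#' solved top-down: `E_k = 2^k * (phat_k - sum_{m > k} E_m choose(m, k)/2^m)`
#' for `k = kmax..1`, and `E_0 = 1 - sum_{k >= 1} E_k`.
#'
#' The direct solution can leave the simplex (negative `E_k`) when the
#' observed class frequencies are incompatible with the model; such solutions
#' are returned unclamped with `feasible = FALSE` as a diagnostic, and
#' [weinstein_mle()] should be used for a boundary-respecting estimate.
#'
#' @param counts A [class_counts()] object or count vector `(n_0, ...)`.
#' @param kmax Highest exchange rank to estimate; defaults to the largest
#'   observed crossover class. Ranks above the largest observed class are
#'   identifiable only through the likelihood, so raising `kmax` mainly pads
#'   zeros.
#' @return An `exchange_ranks` object (fields `E`, `method`, `loglik`,
#'   `feasible`); see also [tidy()] and [glance()] methods.
#' @examples
#' weinstein_direct(class_counts(c(1233, 1182, 207, 4)))
#' @export
weinstein_direct <- function(counts, kmax = NULL) {
  n <- cc_counts(counts)
  N <- sum(n)
  if (N <= 0) abort("Total count is zero.")
  obs_k <- max(which(n > 0)) - 1L
  kmax <- as.integer(kmax %||% obs_k)
  if (kmax < obs_k) {
    abort("`kmax` must be at least the largest observed crossover class.")
  }
  phat <- pad_counts(n, kmax) / N

  E <- numeric(kmax + 1L)
  for (k in seq(kmax, by = -1, length.out = kmax)) {
    tail_mass <- 0
    if (k < kmax) {
      m <- (k + 1L):kmax
      tail_mass <- sum(E[m + 1L] * choose(m, k) / 2^m)
    }
    E[k + 1L] <- 2^k * (phat[k + 1L] - tail_mass)
  }
  E[1L] <- 1 - sum(E[-1L])

  feasible <- all(E >= 0)
  ll <- if (feasible) {
    multinom_loglik(pad_counts(n, kmax), class_probabilities(E))
  } else NA_real_
  new_exchange_ranks(E, method = "direct", loglik = ll, feasible = feasible,
                     counts = pad_counts(n, kmax))
}

# pad with zero classes up to kmax (trailing observed classes are never cut;
# callers validate kmax >= largest observed class first)
pad_counts <- function(n, kmax) {
  c(n, rep(0, max(0L, kmax + 1L - length(n))))[seq_len(kmax + 1L)]
}

#' Weinstein tetrad analysis: constrained maximum likelihood
#'
#' Maximum likelihood estimate of the exchange-rank distribution under the
#' multinomial likelihood `sum_j n_j log p_j(E)` with the simplex constraints
#' `E_k >= 0`, `sum E_k = 1`. The fit uses expectation-maximisation over the
#' latent exchange rank of each recovered chromatid: the E-step attributes
#' each class-`j` chromatid to ranks `k >= j` with posterior weight
#' proportional to `E_k choose(k, j)/2^k`, and the closed-form M-step averages
#' those weights. EM keeps every iterate on the simplex, so the constraints
#' need no projection, and the log-likelihood is concave in `E` (log of a
#' linear function), so the fixed point is the global constrained optimum.
#'
#' When the direct inversion ([weinstein_direct()]) is feasible the model is
#' saturated and the MLE coincides with it; when it is infeasible the MLE
#' lands on the boundary of the simplex with some `E_k = 0`.
#'
#' @inheritParams weinstein_direct
#' @param tol Convergence tolerance on the certified log-likelihood gap:
#'   iteration stops once concavity guarantees the current face optimum lies
#'   within `tol` log-likelihood units (or once the largest per-component
#'   change falls below `tol / 1000`).
#' @param max_iter Iteration cap; exceeding it raises an error that carries
#'   the best iterate in its `E_best` field.
#' @return An `exchange_ranks` object with `method = "mle"`, the attained
#'   log-likelihood, and `feasible = TRUE`.
#' @examples
#' weinstein_mle(class_counts(c(565, 689, 271, 24)))
#' @export
weinstein_mle <- function(counts, kmax = NULL, tol = 1e-10, max_iter = 10000) {
  n <- cc_counts(counts)
  N <- sum(n)
  if (N <= 0) abort("Total count is zero.")
  obs_k <- max(which(n > 0)) - 1L
  kmax <- as.integer(kmax %||% obs_k)
  if (kmax < obs_k) {
    abort("`kmax` must be at least the largest observed crossover class.")
  }
  n <- pad_counts(n, kmax)
  B <- recovery_matrix(kmax)                  # rows k, cols j

  # one EM pass on the current face of the simplex (EM keeps exact zeros at
  # zero, so a run started on a face stays on it)
  em_face <- function(E, iters) {
    converged <- FALSE
    it <- 0L
    while (it < iters) {
      it <- it + 1L
      p <- drop(E %*% B)                      # p_j
      # responsibility r[k, j] = E_k B[k, j] / p_j for classes with data
      R <- (E * B) %*% diag(ifelse(p > 0, 1 / p, 0), nrow = length(p))
      E_new <- drop(R %*% n) / N
      delta <- max(abs(E_new - E))
      # concavity certificate: the log-likelihood can exceed the current
      # value by at most N * (max_k s_k - 1) anywhere on the current face,
      # where s_k = E_new_k / E_k is the EM multiplier (the directional
      # derivative toward vertex k is N * (s_k - 1))
      s_pos <- E_new[E > 0] / E[E > 0]
      gap_bound <- N * (max(s_pos, 1) - 1)
      E <- E_new
      if (gap_bound < tol || delta < 1e-3 * tol) {
        converged <- TRUE
        break
      }
    }
    list(E = E, converged = converged, iterations = it)
  }

  # EM update multiplier s_k = (1/N) sum_j n_j B[k, j] / p_j; the directional
  # derivative of the log-likelihood into component k is N (s_k - 1), which
  # gives the Karush-Kuhn-Tucker check for components held at zero
  em_multiplier <- function(E) {
    p <- drop(E %*% B)
    drop(B %*% ifelse(p > 0, n / p, 0)) / N
  }

  # Active-set EM. Plain EM approaches boundary optima only harmonically
  # (components crawling to zero shrink like 1/iteration), so when an EM
  # pass stalls, components that are tiny and still shrinking are clamped to
  # exact zero and the pass restarts on that face, where convergence is
  # geometric. Converged solutions are accepted only if every clamped
  # component satisfies the KKT condition s_k <= 1; violators re-enter.
  E <- rep(1 / (kmax + 1L), kmax + 1L)  # deterministic uniform-simplex start
  total_it <- 0L
  done <- FALSE
  for (outer in seq_len(kmax + 3L)) {
    run <- em_face(E, max_iter)
    total_it <- total_it + run$iterations
    E <- run$E
    if (run$converged) {
      s <- em_multiplier(E)
      violators <- which(E == 0 & s > 1 + 1e-8)
      if (length(violators) == 0L) {
        done <- TRUE
        break
      }
      E[violators] <- 1e-3
      E <- E / sum(E)
    } else {
      crawling <- which(E > 0 & E < 1e-3 & em_multiplier(E) < 1)
      if (length(crawling) == 0L) break
      E[crawling] <- 0
      E <- E / sum(E)
    }
  }
  if (!done) {
    abort(
      sprintf("Weinstein EM did not converge in %d iterations.", max_iter),
      class = "tetradr_em_no_convergence",
      E_best = E
    )
  }
  ll <- multinom_loglik(n, drop(E %*% B))
  new_exchange_ranks(E, method = "mle", loglik = ll, feasible = TRUE,
                     counts = n, converged = TRUE, iterations = total_it)
}

#' Total genetic map length from class counts
#'
#' The chromosome-wide map length in centimorgans implied by the crossover
#' class counts: `100 * sum_j j * n_j / N` (each crossover falls in exactly
#' one interval, so interval map lengths sum to this total).
#'
#' @inheritParams weinstein_direct
#' @return Map length in centimorgans (unrounded; print to 1 decimal).
#' @examples
#' total_map_length(class_counts(c(1233, 1182, 207, 4)))  # 61.2 cM
#' @export
total_map_length <- function(counts) {
  n <- cc_counts(counts)
  N <- sum(n)
  if (N <= 0) abort("Total count is zero.")
  100 * sum((seq_along(n) - 1) * n) / N
}

#' Mean exchanges per tetrad
#'
#' `sum_k k * E_k`. Because a recovered chromatid carries on average half of
#' its tetrad's exchanges, this always equals `2 * total_map_length / 100`
#' for a feasible fit to the same counts.
#'
#' @inheritParams class_probabilities
#' @return Mean number of exchanges per tetrad.
#' @examples
#' mean_exchanges(c(0, 0, 1))  # every tetrad has exactly 2 exchanges
#' @export
mean_exchanges <- function(E) {
  E <- er_freqs(E)
  sum((seq_along(E) - 1) * E)
}

#' @exportS3Method generics::tidy
tidy.exchange_ranks <- function(x, ...) {
  tibble(
    rank = names(x$E),
    k = seq_along(x$E) - 1L,
    estimate = unname(x$E)
  )
}

#' @exportS3Method generics::glance
glance.exchange_ranks <- function(x, ...) {
  tibble(
    method = x$method,
    kmax = x$kmax,
    logLik = x$loglik,
    feasible = x$feasible,
    mean_exchanges = mean_exchanges(x),
    total_cM = if (!is.null(x$counts)) total_map_length(x$counts) else NA_real_,
    N = if (!is.null(x$counts)) sum(x$counts) else NA_integer_
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.exchange_ranks <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "Exchange rank", y = "Tetrad frequency",
      title = sprintf("Weinstein exchange ranks (%s)", object$method)
    ) +
    ggplot2::theme_minimal()
}
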