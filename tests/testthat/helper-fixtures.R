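# Published class counts of the c(3)G replacement cross (also shipped in
# inst/extdata); used across the suite as realistic inputs.
counts_x_control <- c(1233, 1182, 207, 4)   # N = 2626
counts_x_mau     <- c(565, 689, 271, 24)    # N = 1549
counts_3_control <- c(1001, 759, 96, 6)     # N = 1862
counts_3_mau     <- c(662, 753, 169, 5)     # N = 1589

# random point on the k-simplex
random_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# independent oracle for crossover calling: direct pairwise scan of a
# complete origin sequence
oracle_switch_count <- function(origins) {
  sum(origins[-1] != origins[-length(origins)])
}

# independent oracle for the two-sided Fisher p-value: enumerate every table
# with the observed margins and sum the probabilities (from binomial
# coefficients) of tables no more probable than the observed one
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  p <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# all points of the 0.01-step grid on the 3-simplex (kmax = 3), as a matrix
simplex_grid_4 <- function(step = 0.01) {
  s <- round(1 / step)
  g <- expand.grid(i = 0:s, j = 0:s, k = 0:s)
  g <- g[g$i + g$j + g$k <= s, ]
  cbind(g$i, g$j, g$k, s - g$i - g$j - g$k) / s
}

# log-likelihood of class counts n at every row of an E matrix (rows on the
# simplex), computed straight from the model definition
grid_loglik <- function(E_mat, n) {
  kmax <- ncol(E_mat) - 1L
  k <- 0:kmax
  B <- outer(k, k, function(k, j) ifelse(j <= k, choose(k, j) / 2^k, 0))
  P <- E_mat %*% B
  lp <- log(P)
  lp[P <= 0] <- -Inf
  keep <- n > 0   # zero-count classes contribute nothing (avoid 0 * -Inf)
  drop(lp[, keep, drop = FALSE] %*% n[keep])
}

# exact inclusion probability of each interval in k successive weighted
# draws without replacement (enumeration over ordered k-tuples); the
# simulator's placement model for rank-k tetrads
oracle_inclusion_prob <- function(w, k) {
  n <- length(w)
  if (k == 0) return(rep(0, n))
  inc <- rep(0, n)
  recurse <- function(chosen, prob) {
    if (length(chosen) == k) {
      inc[chosen] <<- inc[chosen] + prob
      return(invisible())
    }
    rest <- setdiff(seq_len(n), chosen)
    denom <- 1 - sum(w[chosen])
    for (j in rest) {
      if (w[j] > 0) recurse(c(chosen, j), prob * w[j] / denom)
    }
  }
  recurse(integer(0), 1)
  inc
}

# progeny tibble from explicit origin strings, e.g. "P1,P1,P2,NA,P2"
progeny_from_strings <- function(strings, map) {
  rows <- lapply(strings, function(s) strsplit(s, ",", fixed = TRUE)[[1]])
  m <- do.call(rbind, rows)
  m[m == "NA"] <- NA
  colnames(m) <- map$loci
  dplyr::bind_cols(
    tibble::tibble(id = sprintf("r%d", seq_along(strings))),
    tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  )
}
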