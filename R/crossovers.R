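#' Call crossovers from per-progeny marker phenotypes
#'
#' Each scored offspring carries one recovered chromatid; a crossover is
#' observed wherever the parental origin of the alleles switches between two
#' adjacent scored loci. `call_crossovers()` converts a progeny table of
#' parental-origin codes into one recombinant profile per offspring: the set
#' of intervals containing a phase switch and the resulting crossover count.
#'
#' Missing marker calls are never imputed. A switch flanked by a run of
#' missing loci is still called when the run spans a single interval; when the
#' flanking scored loci are more than one interval apart the switch cannot be
#' placed and the record is dropped (and logged) rather than guessed. Records
#' with fewer than two scored loci are likewise dropped. Note that an even
#' number of crossovers between adjacent scored loci cancels and is
#' undetectable; counts are observable phase switches only.
#'
#' @param progeny A data frame with a character `id` column and one column per
#'   locus of `map`, each cell one of `"P1"`, `"P2"` or `NA`.
#' @param map A [marker_map()] whose loci all appear as columns of `progeny`.
#'
#' @return A tibble of class `recombinant_profiles` with columns `id`,
#'   `crossover_count` and `intervals` (list-column of integer interval
#'   indices). Dropped records are reported in the `"dropped"` attribute, a
#'   tibble with columns `id` and `reason`.
#'
#' @examples
#' x <- marker_map_x()
#' progeny <- tibble::tibble(
#'   id = c("a", "b"),
#'   sc = c("P1", "P1"), cv = c("P1", "P2"), v = c("P2", "P1"),
#'   f = c("P2", "P2"), `y+` = c("P2", "P1")
#' )
#' call_crossovers(progeny, x)
#' @export
call_crossovers <- function(progeny, map) {
  assert_marker_map(map)
  progeny <- as_tibble(progeny)
  if (!"id" %in% names(progeny)) {
    abort("`progeny` must have an `id` column.")
  }
  missing_loci <- setdiff(map$loci, names(progeny))
  if (length(missing_loci) > 0) {
    abort(sprintf("Progeny table lacks locus column(s): %s.",
                  paste(missing_loci, collapse = ", ")))
  }
  if (nrow(progeny) == 0) {
    abort("`progeny` has no rows.")
  }

  m <- as.matrix(progeny[, map$loci, drop = FALSE])
  bad <- !(m %in% c("P1", "P2") | is.na(m))
  if (any(bad)) {
    off <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Unknown parental-origin code %s at row %d, locus %s (expect P1/P2/NA).",
      deparse(m[off[1], off[2]]), off[1], map$loci[off[2]]
    ))
  }

  n <- nrow(m)
  n_loc <- ncol(m)
  org <- matrix(NA_integer_, n, n_loc)
  org[m == "P1"] <- 0L
  org[m == "P2"] <- 1L

  has_na <- rowSums(is.na(org)) > 0L

  intervals <- vector("list", n)
  counts <- integer(n)
  drop_reason <- character(n)

  if (any(!has_na)) {
    sw <- org[!has_na, -1, drop = FALSE] != org[!has_na, -n_loc, drop = FALSE]
    counts[!has_na] <- rowSums(sw)
    intervals[!has_na] <- apply(sw, 1, which, simplify = FALSE)
  }

  for (i in which(has_na)) {
    scored <- which(!is.na(org[i, ]))
    if (length(scored) < 2) {
      drop_reason[i] <- "fewer than 2 scored loci"
      next
    }
    iv <- integer(0)
    ambiguous <- FALSE
    for (s in seq_len(length(scored) - 1)) {
      a <- scored[s]
      b <- scored[s + 1]
      if (org[i, a] != org[i, b]) {
        if (b - a > 1L) {
          ambiguous <- TRUE
          break
        }
        iv <- c(iv, a)
      }
    }
    if (ambiguous) {
      drop_reason[i] <- "phase switch across a run of missing loci spanning >1 interval"
    } else {
      intervals[[i]] <- iv
      counts[i] <- length(iv)
    }
  }

  keep <- drop_reason == ""
  dropped <- tibble(id = as.character(progeny$id[!keep]),
                    reason = drop_reason[!keep])
  if (nrow(dropped) > 0) {
    warn(sprintf("Dropped %d of %d progeny records with ambiguous or insufficient marker calls.",
                 nrow(dropped), n))
  }

  out <- tibble(
    id = as.character(progeny$id[keep]),
    crossover_count = counts[keep],
    intervals = intervals[keep]
  )
  structure(out,
            class = c("recombinant_profiles", class(out)),
            marker_map = map,
            dropped = dropped)
}

#' Crossover class counts (NCO/SCO/DCO/TCO/...)
#'
#' A `class_counts` object tabulates recovered chromatids by their observed
#' crossover count: `n_j` chromatids with exactly `j` crossovers, for
#' `j = 0..kmax`. It is the input of Weinstein tetrad analysis.
#'
#' @param counts Non-negative integer vector; `counts[j + 1]` is the number of
#'   chromatids carrying exactly `j` crossovers (NCO, SCO, DCO, TCO, ...).
#'
#' @return A tibble of class `class_counts` with columns `n_crossovers`,
#'   `class` (NCO/SCO/DCO/TCO, then "4CO" etc.) and `count`.
#' @examples
#' class_counts(c(1233, 1182, 207, 4))
#' @export
class_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1 || any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("`counts` must be non-negative integers (n_0, n_1, ...).")
  }
  k <- seq_along(counts) - 1L
  out <- tibble(
    n_crossovers = k,
    class = crossover_class_label(k),
    count = as.integer(round(counts))
  )
  class(out) <- c("class_counts", class(out))
  out
}

crossover_class_label <- function(j) {
  lab <- c("NCO", "SCO", "DCO", "TCO")
  ifelse(j <= 3, lab[j + 1], paste0(j, "CO"))
}

cc_counts <- function(x) {
  if (inherits(x, "class_counts")) return(as.numeric(x$count))
  as.numeric(x)
}

cc_total <- function(x) sum(cc_counts(x))

#' Tabulate crossover classes from recombinant profiles
#'
#' Counts recovered chromatids by crossover number (NCO, SCO, DCO, TCO, ...)
#' from the output of [call_crossovers()] or [simulate_meiosis()] pipelines.
#'
#' @param profiles A `recombinant_profiles` tibble (or any data frame with a
#'   `crossover_count` column).
#' @param kmax Largest class to tabulate; defaults to the largest observed
#'   crossover count.
#'
#' @return A [class_counts()] tibble; total N is `sum(x$count)`.
#' @examples
#' x <- marker_map_x()
#' progeny <- simulate_meiosis(500, x, exchange_freqs = c(0.1, 0.6, 0.3),
#'                             seed = 1)
#' tabulate_classes(call_crossovers(progeny, x))
#' @export
tabulate_classes <- function(profiles, kmax = NULL) {
  if (!is.data.frame(profiles) || !"crossover_count" %in% names(profiles)) {
    abort("`profiles` must be a data frame with a `crossover_count` column.")
  }
  if (nrow(profiles) == 0) {
    abort("`profiles` is empty; nothing to tabulate.")
  }
  j <- profiles$crossover_count
  kmax <- kmax %||% max(j)
  if (kmax < max(j)) {
    abort("`kmax` is smaller than the largest observed crossover count.")
  }
  class_counts(tabulate(factor(j, levels = 0:kmax)))
}

#' Per-class percentages of scored progeny
#'
#' Expresses each crossover class as a percentage of the total scored
#' progeny N. Percentages are carried unrounded (they sum to exactly 100);
#' the `percent_label` column is the 1-decimal presentation value.
#'
#' @param counts A [class_counts()] object (or bare count vector).
#' @return A tibble with columns `n_crossovers`, `class`, `count`, `percent`
#'   (unrounded) and `percent_label`.
#' @examples
#' class_percentages(class_counts(c(1233, 1182, 207, 4)))
#' @export
class_percentages <- function(counts) {
  n <- cc_counts(counts)
  N <- sum(n)
  if (N <= 0) abort("Total count is zero; percentages undefined.")
  j <- seq_along(n) - 1L
  tibble(
    n_crossovers = j,
    class = crossover_class_label(j),
    count = as.integer(round(n)),
    percent = 100 * n / N,
    percent_label = sprintf("%.1f", round(100 * n / N, 1))
  )
}
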