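#' Define an ordered marker map for one chromosome
#'
#' A marker map lists the scored loci of a chromosome in their genetic order.
#' Adjacent loci delimit the intervals in which crossovers are called; a
#' crossover between non-adjacent markers cannot be localised more finely than
#' one interval. Optionally, one interval may be flagged as spanning the
#' centromere, which is the interval of interest for centromere-effect
#' readouts.
#'
#' @param loci Character vector of locus names in genetic order (at least 2,
#'   unique).
#' @param chromosome Label for the chromosome (e.g. `"X"`, `"3"`).
#' @param centromere_interval Optional integer index of the interval that
#'   spans the centromere (1-based, between 1 and `length(loci) - 1`).
#'
#' @return An object of class `marker_map`: a list with elements `chromosome`,
#'   `loci`, `intervals` (a tibble with columns `index`, `left`, `right`,
#'   `name`) and `centromere_interval`.
#'
#' @examples
#' marker_map(c("sc", "cv", "v", "f", "y+"), chromosome = "X",
#'            centromere_interval = 4)
#' @export
marker_map <- function(loci, chromosome = "chr", centromere_interval = NULL) {
  loci <- as.character(loci)
  if (length(loci) < 2) {
    abort("A marker map needs at least 2 loci.")
  }
  if (anyDuplicated(loci)) {
    abort("Locus names must be unique.")
  }
  n_int <- length(loci) - 1L
  if (!is.null(centromere_interval)) {
    centromere_interval <- as.integer(centromere_interval)
    if (length(centromere_interval) != 1L || is.na(centromere_interval) ||
        centromere_interval < 1L || centromere_interval > n_int) {
      abort(sprintf("`centromere_interval` must be a single index in 1..%d.", n_int))
    }
  }
  intervals <- tibble(
    index = seq_len(n_int),
    left  = loci[-length(loci)],
    right = loci[-1],
    name  = paste(loci[-length(loci)], loci[-1], sep = "-")
  )
  structure(
    list(
      chromosome = chromosome,
      loci = loci,
      intervals = intervals,
      centromere_interval = centromere_interval
    ),
    class = "marker_map"
  )
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("<marker_map> chromosome %s: %d loci, %d intervals\n",
              x$chromosome, length(x$loci), nrow(x$intervals)))
  cat("  loci:", paste(x$loci, collapse = " - "), "\n")
  if (!is.null(x$centromere_interval)) {
    cat("  centromere-spanning interval:",
        x$intervals$name[x$centromere_interval], "\n")
  }
  invisible(x)
}

n_intervals <- function(map) nrow(map$intervals)

assert_marker_map <- function(map, arg = "map") {
  if (!inherits(map, "marker_map")) {
    abort(sprintf("`%s` must be a <marker_map> (see `marker_map()`).", arg))
  }
  invisible(map)
}

#' Built-in marker maps for the standard X and 3rd chromosome crosses
#'
#' Convenience constructors for the two multiply-marked chromosomes used in
#' classical D. melanogaster recombination assays: the X scored at
#' sc, cv, v, f and a translocated y+ marker on the right arm (so the f-y+
#' interval spans the centromere), and the 3rd chromosome scored at
#' ru, h, th, st, cu (st-cu spans the centromere).
#'
#' @return A [marker_map()].
#' @examples
#' marker_map_x()
#' marker_map_3rd()
#' @export
marker_map_x <- function() {
  marker_map(c("sc", "cv", "v", "f", "y+"), chromosome = "X",
             centromere_interval = 4)
}

#' @rdname marker_map_x
#' @export
marker_map_3rd <- function() {
  marker_map(c("ru", "h", "th", "st", "cu"), chromosome = "3",
             centromere_interval = 4)
}
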