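#' Read and write progeny marker tables
#'
#' Progeny tables are plain TSV with a header: an `id` column plus one column
#' per locus, cells in `P1` / `P2` / `NA`. `read_progeny_table()` validates
#' the codes and, when a marker map is supplied, checks that every locus has
#' a column; offending cells are reported with their data line number.
#'
#' @param path File path.
#' @param map Optional [marker_map()] used to check the header.
#' @return A tibble with `id` and locus columns.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' prog <- simulate_meiosis(3, marker_map_x(), c(0, 1), seed = 2)
#' write_progeny_table(prog, f)
#' read_progeny_table(f, marker_map_x())
#' @export
read_progeny_table <- function(path, map = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("NA", ""), progress = FALSE)
  if (!"id" %in% names(tab)) {
    abort(sprintf("%s: progeny table must have an `id` column.", path))
  }
  loci <- setdiff(names(tab), "id")
  if (length(loci) < 2) {
    abort(sprintf("%s: progeny table needs at least 2 locus columns.", path))
  }
  if (!is.null(map)) {
    assert_marker_map(map)
    missing_loci <- setdiff(map$loci, loci)
    if (length(missing_loci) > 0) {
      abort(sprintf("%s: missing locus column(s): %s.", path,
                    paste(missing_loci, collapse = ", ")))
    }
  }
  m <- as.matrix(tab[, loci, drop = FALSE])
  bad <- !(m %in% c("P1", "P2") | is.na(m))
  if (any(bad)) {
    off <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("%s line %d: unknown parental-origin code %s in column %s.",
                  path, off[1] + 1L, deparse(unname(m[off[1], off[2]])), loci[off[2]]))
  }
  if (!is.null(map)) attr(tab, "marker_map") <- map
  tab
}

#' @rdname read_progeny_table
#' @param progeny Progeny tibble to write.
#' @export
write_progeny_table <- function(progeny, path) {
  readr::write_tsv(as_tibble(progeny), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read and write crossover class-count tables
#'
#' Class-count tables are TSV with columns `class_index` (0 for NCO, 1 for
#' SCO, ...) and `count`. Missing intermediate classes are filled with zero.
#'
#' @param path File path.
#' @return A [class_counts()] object.
#' @export
read_class_counts <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    class_index = readr::col_integer(),
    count = readr::col_integer()
  ), progress = FALSE)
  if (nrow(tab) == 0) abort(sprintf("%s: empty class-count table.", path))
  if (any(is.na(tab$class_index)) || any(is.na(tab$count))) {
    abort(sprintf("%s: malformed class-count table.", path))
  }
  counts <- integer(max(tab$class_index) + 1L)
  counts[tab$class_index + 1L] <- tab$count
  class_counts(counts)
}

#' @rdname read_class_counts
#' @param counts A [class_counts()] object to write.
#' @export
write_class_counts <- function(counts, path) {
  n <- cc_counts(counts)
  readr::write_tsv(
    tibble(class_index = seq_along(n) - 1L, count = as.integer(n)),
    path, progress = FALSE
  )
  invisible(path)
}

#' Assemble and write a tetrad-analysis JSON report
#'
#' Bundles the outputs of a tetrad analysis — exchange ranks, method,
#' log-likelihood, feasibility, mean exchanges per tetrad and total map
#' length — into a list and optionally writes it as JSON. Rounded
#' presentation values are reported alongside their unrounded counterparts.
#'
#' @param counts A [class_counts()] object.
#' @param kmax Passed to the estimators.
#' @param path Optional output path for the JSON report.
#' @param seed Optional seed to record (provenance only).
#' @return The report list, invisibly if written to `path`.
#' @export
tetrad_report <- function(counts, kmax = NULL, path = NULL, seed = NULL) {
  er_mle <- weinstein_mle(counts, kmax = kmax)
  er_dir <- weinstein_direct(counts, kmax = kmax)
  report <- list(
    tool = "tetradr",
    version = as.character(utils::packageVersion("tetradr")),
    seed = seed,
    N = cc_total(counts),
    counts = as.integer(cc_counts(counts)),
    E = unname(er_mle$E),
    E_rounded = unname(round(er_mle$E, 4)),
    method = er_mle$method,
    loglik = er_mle$loglik,
    feasible_direct = er_dir$feasible,
    E_direct = unname(er_dir$E),
    mean_exchanges = mean_exchanges(er_mle),
    total_cM = total_map_length(counts),
    total_cM_rounded = round(total_map_length(counts), 1)
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
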