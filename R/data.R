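#' Example recombination data from a synaptonemal-complex replacement cross
#'
#' Crossover class counts, interval genetic maps and a nondisjunction summary
#' from multiply-marked D. melanogaster crosses comparing a c(3)G+ control
#' with a line whose c(3)G gene is replaced by the D. mauritiana ortholog
#' (`"mau"`). The X chromosome was scored at sc, cv, v, f, y+ and the 3rd
#' chromosome at ru, h, th, st, cu. These tables ship with the package as
#' worked-example inputs and test fixtures.
#'
#' @param chromosome `"X"` or `"3"`.
#' @param genotype `"control"` or `"mau"`.
#' @return `example_class_counts()`: a [class_counts()] object.
#'   `example_interval_map()`: a tibble with columns `interval` and `cM`.
#'   `example_ndj_table()`: a tibble with the printed percent NDJ values and
#'   viability-adjusted totals per genotype.
#' @examples
#' example_class_counts("X", "control")
#' total_map_length(example_class_counts("X", "mau"))
#' @export
example_class_counts <- function(chromosome = c("X", "3"),
                                 genotype = c("control", "mau")) {
  chromosome <- match.arg(chromosome)
  genotype <- match.arg(genotype)
  tab <- read_example_tsv("class_counts.tsv")
  tab <- tab[tab$chromosome == chromosome & tab$genotype == genotype, ]
  counts <- integer(max(tab$class_index) + 1L)
  counts[tab$class_index + 1L] <- tab$count
  class_counts(counts)
}

#' @rdname example_class_counts
#' @export
example_interval_map <- function(chromosome = c("X", "3"),
                                 genotype = c("control", "mau")) {
  chromosome <- match.arg(chromosome)
  genotype <- match.arg(genotype)
  tab <- read_example_tsv("interval_maps.tsv")
  tab[tab$chromosome == chromosome & tab$genotype == genotype,
      c("interval", "cM")]
}

#' @rdname example_class_counts
#' @export
example_ndj_table <- function() {
  read_example_tsv("ndj_table.tsv")
}

read_example_tsv <- function(name) {
  path <- system.file("extdata", name, package = "tetradr", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
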