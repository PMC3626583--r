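#' Read and write genotype tables
#'
#' Delimited text with a header row of individual ids, one marker per row,
#' calls coded `A`/`H`/`B`/`-`.
#'
#' @param path File path.
#' @param population `"F2"` or `"RIL"`.
#' @param geno A genotype table.
#' @return `read_geno()` a genotype table; `write_geno()` the path,
#'   invisibly.
#' @export
read_geno <- function(path, population = c("F2", "RIL")) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  as_geno(x, match.arg(population))
}

#' @rdname read_geno
#' @export
write_geno <- function(geno, path) {
  readr::write_tsv(as_tibble(geno), path)
  invisible(path)
}

#' Read and write genetic map tables
#'
#' TSV with columns `marker`, `lg`, `cM` (extra columns preserved).
#'
#' @param path File path.
#' @param map A map tibble.
#' @param name Optional map name recorded as an attribute.
#' @return `read_map()` a map tibble; `write_map()` the path, invisibly.
#' @export
read_map <- function(path, name = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    marker = "c", lg = "c", cM = "d", .default = "?"))
  if (!all(c("marker", "lg", "cM") %in% names(x))) {
    abort("map file needs columns `marker`, `lg`, `cM`.")
  }
  if (!is.null(name)) attr(x, "map_name") <- name
  x
}

#' @rdname read_map
#' @export
write_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

#' Read primer pairs
#'
#' TSV with columns `marker`, `fwd_seq`, `rev_seq`.
#' @param path File path.
#' @return Tibble of primer pairs.
#' @export
read_primers <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("marker", "fwd_seq", "rev_seq") %in% names(x))) {
    abort("primer file needs columns `marker`, `fwd_seq`, `rev_seq`.")
  }
  x
}

#' Read gene/domain annotations
#'
#' TSV with columns `gene`, `scaffold`, `start`, `end` (1-based inclusive),
#' `domains` (ordered, comma-joined labels) and optionally `nb_start`,
#' `nb_end` (NB-domain span in the peptide).
#' @param path File path.
#' @return Tibble of annotations.
#' @export
read_annotations <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", scaffold = "c", start = "i", end = "i", domains = "c",
    .default = "?"))
  if (!all(c("gene", "scaffold", "start", "end", "domains") %in% names(x))) {
    abort("annotation file needs gene/scaffold/start/end/domains columns.")
  }
  if (any(x$start > x$end)) abort("annotation intervals must have start <= end.")
  x
}
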