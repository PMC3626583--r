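#' Genotype tables
#'
#' A genotype table is a tibble with one row per marker: a `marker` column of
#' unique marker ids followed by one column per individual. Calls are coded
#' `"A"` and `"B"` for the two parental homozygotes, `"H"` for the
#' heterozygote (F2 only) and `"-"` for missing. The population kind
#' (`"F2"` or `"RIL"`) travels as the `"population"` attribute.
#'
#' @param x A data frame in the layout above.
#' @param population `"F2"` or `"RIL"`.
#' @return A `cucumap_geno` tibble.
#' @export
as_geno <- function(x, population = c("F2", "RIL")) {
  population <- match.arg(population)
  x <- as_tibble(x)
  if (!"marker" %in% names(x)) abort("genotype table needs a `marker` column.")
  if (anyDuplicated(x$marker)) abort("marker ids must be unique.")
  calls <- as.matrix(x[setdiff(names(x), "marker")])
  bad <- setdiff(unique(as.vector(calls)), c("A", "H", "B", "-"))
  if (length(bad)) {
    abort(paste0("invalid genotype codes: ", paste(bad, collapse = ", ")))
  }
  if (population == "RIL" && any(calls == "H")) {
    warn("heterozygous calls in RIL data treated as missing.")
    calls[calls == "H"] <- "-"
    x[setdiff(names(x), "marker")] <- as_tibble(calls)
  }
  structure(x, population = population,
            class = c("cucumap_geno", class(x)))
}

geno_population <- function(geno) {
  attr(geno, "population") %||% abort("no `population` attribute on genotypes.")
}

# integer coding A=0, H=1, B=2, missing=NA; rows named by marker
geno_int <- function(geno) {
  calls <- as.matrix(geno[setdiff(names(geno), "marker")])
  m <- matrix(c(A = 0L, H = 1L, B = 2L, `-` = NA_integer_)[calls],
              nrow = nrow(calls), dimnames = list(geno$marker, colnames(calls)))
  m
}

#' Missing-call counts per marker
#'
#' @param geno A genotype table (see [as_geno()]).
#' @return Tibble with `marker` and `n_missing`.
#' @export
geno_missing_counts <- function(geno) {
  m <- geno_int(geno)
  tibble(marker = rownames(m), n_missing = rowSums(is.na(m)))
}
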