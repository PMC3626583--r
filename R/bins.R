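#' Build 1-cM bins on a component map
#'
#' A bin is a unique map location grouping all markers within `bin_width`
#' (default 1 cM). The scan is a greedy left-to-right pass anchored at each
#' bin's first (leftmost) marker: a new bin starts when the next marker lies
#' more than `bin_width` from the current bin's start. Bins partition the
#' loci of each linkage group.
#'
#' @param map A map tibble (`marker`, `lg`, `cM`), ordered within groups.
#' @param bin_width Bin width in cM.
#' @param map_name Name recorded in the output (defaults to the map's
#'   `map_name` attribute, else `"map"`).
#' @return Long tibble: `map`, `lg`, `bin`, `start_cM`, `end_cM`, `marker`,
#'   `cM`; one row per locus.
#' @examples
#' m <- tibble::tibble(marker = letters[1:4], lg = "LG1",
#'                     cM = c(0, 0.4, 0.9, 2))
#' build_bins(m) # bins {a,b,c} and {d}
#' @export
build_bins <- function(map, bin_width = 1, map_name = NULL) {
  map_name <- map_name %||% attr(map, "map_name") %||% "map"
  out <- lapply(split(seq_len(nrow(map)), map$lg), function(ix) {
    sub <- map[ix, ][order(map$cM[ix], map$marker[ix]), ]
    bin_id <- integer(nrow(sub))
    start <- sub$cM[1]
    b <- 1L
    for (i in seq_len(nrow(sub))) {
      if (sub$cM[i] > start + bin_width) {
        b <- b + 1L
        start <- sub$cM[i]
      }
      bin_id[i] <- b
    }
    tibble(map = map_name, lg = sub$lg, bin = paste0(sub$lg, ":", bin_id),
           marker = sub$marker, cM = sub$cM) |>
      group_by(.data$bin) |>
      mutate(start_cM = min(.data$cM), end_cM = max(.data$cM)) |>
      ungroup()
  })
  bind_rows(out)[, c("map", "lg", "bin", "start_cM", "end_cM", "marker", "cM")]
}

#' Select bridge representatives for each bin
#'
#' Per bin the preferred representative is (1) the marker shared with the
#' most other component maps (the bridge), then (2) the marker with the
#' fewest missing genotype calls, then (3) the lexicographically smallest
#' id. Markers inside configured exclusion regions (for example marker
#' clusters caused by recombination suppression) are skipped; a bin whose
#' members are all excluded is carried with zero representatives and a
#' warning.
#'
#' @param bins Output of [build_bins()] for one map.
#' @param shared_counts Tibble `marker`, `n_shared` (number of other maps
#'   carrying the marker). Missing markers count 0.
#' @param missing_counts Optional tibble `marker`, `n_missing`.
#' @param exclusions Optional tibble `map`, `lg`, `start_cM`, `end_cM`.
#' @return `bins` with a logical `is_representative` column.
#' @export
select_representatives <- function(bins, shared_counts,
                                   missing_counts = NULL, exclusions = NULL) {
  sh <- setNames(shared_counts$n_shared, shared_counts$marker)
  mi <- if (is.null(missing_counts)) setNames(numeric(0), character(0)) else
    setNames(missing_counts$n_missing, missing_counts$marker)
  excluded <- rep(FALSE, nrow(bins))
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      excluded <- excluded |
        (bins$map == exclusions$map[i] & bins$lg == exclusions$lg[i] &
           bins$cM >= exclusions$start_cM[i] & bins$cM <= exclusions$end_cM[i])
    }
  }
  bins$is_representative <- FALSE
  for (b in unique(bins$bin)) {
    ix <- which(bins$bin == b & !excluded)
    if (!length(ix)) {
      warn(paste0("bin ", b, " fully excluded; no representative selected."))
      next
    }
    n_sh <- sh[bins$marker[ix]]; n_sh[is.na(n_sh)] <- 0
    n_mi <- mi[bins$marker[ix]]; n_mi[is.na(n_mi)] <- 0
    best <- ix[order(-n_sh, n_mi, bins$marker[ix])][1]
    bins$is_representative[best] <- TRUE
  }
  bins
}
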