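#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure over marker pairs with
#' `lod >= lod_threshold` and `r_hat <= rf_threshold`. Groups are named by
#' their lexicographically smallest member; singletons are reported as
#' unlinked groups of size one.
#'
#' @param rf A pairwise table from [pairwise_rf()].
#' @param lod_threshold,rf_threshold Linkage thresholds.
#' @return Tibble with `marker`, `group` (smallest member id) and `lg`
#'   (groups renumbered `LG1`, `LG2`, ... in order of smallest member).
#' @export
group_markers <- function(rf, lod_threshold = 5, rf_threshold = 0.35) {
  markers <- sort(unique(c(rf$marker_a, rf$marker_b)))
  keep <- !is.na(rf$lod) & rf$lod >= lod_threshold & rf$r_hat <= rf_threshold
  g <- igraph::graph_from_data_frame(
    rf[keep, c("marker_a", "marker_b")], directed = FALSE,
    vertices = markers)
  comp <- igraph::components(g)$membership
  out <- tibble(marker = names(comp), comp = unname(comp)) |>
    group_by(.data$comp) |>
    mutate(group = min(.data$marker)) |>
    ungroup()
  lev <- sort(unique(out$group))
  out$lg <- paste0("LG", match(out$group, lev))
  arrange(out[, c("marker", "group", "lg")], .data$group, .data$marker)
}

sarf <- function(order_ix, rmat) {
  sum(rmat[cbind(order_ix[-length(order_ix)], order_ix[-1])])
}

#' Order markers within a linkage group
#'
#' Seeks the order minimising SARF (sum of adjacent recombination fractions):
#' greedy seriation grown from the strongest-linked (highest LOD) pair by
#' appending, at either end, the unplaced marker with the smallest r to that
#' end; then 2-opt segment reversal and single-marker reinsertion to a local
#' optimum. Marker pairs without an estimate count r = 0.5. The orientation
#' is canonicalised so the lexicographically smaller terminal marker comes
#' first. Deterministic (ties broken by lexicographic marker id).
#'
#' @param markers Character vector of marker ids (length >= 2).
#' @param rf Pairwise table from [pairwise_rf()] covering the markers.
#' @param seed Unused randomness guard, kept for interface stability.
#' @return Character vector: the ordered markers.
#' @export
order_markers <- function(markers, rf, seed = 1) {
  markers <- sort(unique(markers))
  n <- length(markers)
  if (n < 2) abort("need at least two markers to order.")
  rmat <- matrix(0.5, n, n, dimnames = list(markers, markers))
  lmat <- matrix(0, n, n, dimnames = list(markers, markers))
  sub <- rf[rf$marker_a %in% markers & rf$marker_b %in% markers, ]
  ia <- match(sub$marker_a, markers); ib <- match(sub$marker_b, markers)
  ok <- !is.na(sub$r_hat)
  rmat[cbind(ia, ib)[ok, , drop = FALSE]] <- sub$r_hat[ok]
  rmat[cbind(ib, ia)[ok, , drop = FALSE]] <- sub$r_hat[ok]
  lmat[cbind(ia, ib)[ok, , drop = FALSE]] <- sub$lod[ok]
  lmat[cbind(ib, ia)[ok, , drop = FALSE]] <- sub$lod[ok]
  diag(rmat) <- 0

  # connectivity under informative estimates
  g <- igraph::graph_from_adjacency_matrix(lmat > 0 & rmat < 0.5, "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1 && n > 2) {
    parts <- split(markers, comp$membership)
    abort(paste0("linkage group is disconnected; components: ",
                 paste(vapply(parts, paste, character(1), collapse = ","),
                       collapse = " | ")))
  }

  if (n == 2) return(markers)

  # greedy seriation from the strongest-linked pair
  start <- which(lmat == max(lmat), arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  path <- as.integer(start)
  left <- setdiff(seq_len(n), path)
  while (length(left)) {
    ends <- c(path[1], path[length(path)])
    cand <- rbind(rmat[ends[1], left], rmat[ends[2], left])
    best <- which(cand == min(cand), arr.ind = TRUE)
    best <- best[order(left[best[, 2]], best[, 1]), , drop = FALSE][1, ]
    nxt <- left[best[2]]
    path <- if (best[1] == 1) c(nxt, path) else c(path, nxt)
    left <- setdiff(left, nxt)
  }

  # 2-opt segment reversal + single-marker reinsertion
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        cand <- path
        cand[i:j] <- rev(cand[i:j])
        if (sarf(cand, rmat) < sarf(path, rmat) - 1e-12) {
          path <- cand
          improved <- TRUE
        }
      }
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j == i) next
        cand <- append(path[-i], path[i], after = j - 1)
        if (sarf(cand, rmat) < sarf(path, rmat) - 1e-12) {
          path <- cand
          improved <- TRUE
        }
      }
    }
  }

  out <- markers[path]
  if (out[length(out)] < out[1]) out <- base::rev(out)
  out
}

#' Flag unlikely local double crossovers
#'
#' A call is flagged when, within a three-marker window of the given order,
#' the two flanking calls of the same individual agree with each other but
#' disagree with the centre call - a pattern requiring a double
#' recombination in a short interval, far more often a genotyping error.
#' Flagged calls are replaced by missing.
#'
#' @param geno A genotype table.
#' @param order Tibble with `marker` and `lg` giving the map order (rows in
#'   order), or a character vector of ordered markers (single group).
#' @param window Window size; only the default 3 is implemented.
#' @return List with `geno` (cleaned table) and `report` (tibble `marker`,
#'   `n_flagged`).
#' @export
clean_double_crossovers <- function(geno, order, window = 3) {
  if (window != 3) abort("only the 3-marker window is implemented.")
  if (is.character(order)) order <- tibble(marker = order, lg = "LG1")
  calls <- as.matrix(geno[setdiff(names(geno), "marker")])
  rownames(calls) <- geno$marker
  flags <- matrix(FALSE, nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
  for (lg in unique(order$lg)) {
    mk <- order$marker[order$lg == lg]
    mk <- mk[mk %in% rownames(calls)]
    if (length(mk) < 3) next
    sub <- calls[mk, , drop = FALSE]
    for (i in 2:(length(mk) - 1)) {
      a <- sub[i - 1, ]; b <- sub[i, ]; c <- sub[i + 1, ]
      bad <- a != "-" & b != "-" & c != "-" & a == c & b != a
      flags[mk[i], bad] <- TRUE
    }
  }
  calls[flags] <- "-"
  cleaned <- bind_cols(tibble(marker = rownames(calls)), as_tibble(calls))
  cleaned <- as_geno(cleaned, geno_population(geno))
  attr(cleaned, "truth_map") <- attr(geno, "truth_map")
  report <- tibble(marker = rownames(flags), n_flagged = rowSums(flags))
  list(geno = cleaned, report = report)
}

#' Build a component genetic map from a genotype table
#'
#' Orchestrates the mapping stages: pairwise r/LOD estimation, grouping,
#' within-group ordering, double-crossover cleaning (followed by
#' re-estimation on the cleaned calls), and cumulative cM positions from
#' adjacent-pair recombination fractions through the chosen map function.
#' The first locus of each linkage group sits at 0.0 cM.
#'
#' @param geno A genotype table (see [as_geno()]).
#' @param lod_threshold,rf_threshold Grouping thresholds.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @param clean Apply double-crossover cleaning (default TRUE).
#' @param name Map name stored in the result.
#' @return A `cucumap_map` tibble: `marker`, `lg`, `cM`, with attributes
#'   `map_function`, `map_name`, `rf` (pairwise table on the cleaned calls)
#'   and `cleaning` (per-marker flag counts).
#' @export
build_component_map <- function(geno, lod_threshold = 5, rf_threshold = 0.35,
                                map_function = c("kosambi", "haldane"),
                                clean = TRUE, name = "map") {
  map_function <- match.arg(map_function)
  rf <- pairwise_rf(geno)
  groups <- group_markers(rf, lod_threshold, rf_threshold)
  lgs <- split(groups$marker, groups$lg)
  lgs <- lgs[order(as.integer(sub("LG", "", names(lgs))))]
  orders <- lapply(lgs, function(mk) {
    if (length(mk) < 2) mk else order_markers(mk, rf)
  })
  order_tbl <- bind_rows(lapply(names(orders), function(lg) {
    tibble(marker = orders[[lg]], lg = lg)
  }))

  cleaning <- NULL
  if (clean) {
    cl <- clean_double_crossovers(geno, order_tbl)
    geno <- cl$geno
    cleaning <- cl$report
    rf <- pairwise_rf(geno)
  }

  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rlookup <- setNames(rf$r_hat, key(rf$marker_a, rf$marker_b))
  out <- bind_rows(lapply(names(orders), function(lg) {
    mk <- orders[[lg]]
    if (length(mk) == 1) return(tibble(marker = mk, lg = lg, cM = 0))
    r_adj <- rlookup[key(mk[-length(mk)], mk[-1])]
    r_adj[is.na(r_adj)] <- 0.5 - 1e-9
    r_adj <- pmin(r_adj, 0.5 - 1e-9)
    tibble(marker = mk, lg = lg,
           cM = unname(c(0, cumsum(rf_to_cm(r_adj, map_function)))))
  }))
  structure(out, map_function = map_function, map_name = name,
            rf = rf, cleaning = cleaning,
            class = c("cucumap_map", class(out)))
}

#' Relabel linkage groups against reference assignments
#'
#' Renames each linkage group of a map to the majority label of its markers
#' in a reference assignment (for example the true chromosomes of a
#' simulated genome, or an established map). Groups without any reference
#' marker keep their name.
#'
#' @param map A map tibble (`marker`, `lg`, `cM`).
#' @param reference Tibble with `marker` and a label column `lg` (or
#'   `chromosome`, used if present).
#' @return The map with relabelled `lg`.
#' @export
align_linkage_groups <- function(map, reference) {
  lab <- if ("chromosome" %in% names(reference)) "chromosome" else "lg"
  ref <- setNames(reference[[lab]], reference$marker)
  relab <- vapply(split(map$marker, map$lg), function(mk) {
    v <- ref[mk]
    v <- v[!is.na(v)]
    if (!length(v)) NA_character_ else names(sort(table(v), decreasing = TRUE))[1]
  }, character(1))
  new <- relab[map$lg]
  map$lg <- ifelse(is.na(new), map$lg, new)
  map
}
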