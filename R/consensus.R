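#' Resolve conflicting chromosome assignments across component maps
#'
#' For every marker the linkage-group assignment is settled by precedence:
#' (1) the majority linkage group among mapped markers residing on the same
#' scaffold ("scaffold_majority"); (2) if no scaffold evidence or a tie, the
#' majority vote among the component maps ("map_majority"); (3) if still
#' tied, the designated reference map's assignment ("reference_map"). A
#' marker whose assignment cannot be settled is dropped with a report entry.
#' Markers placed identically by all maps carrying them are labelled
#' "unanimous".
#'
#' @param assignments Tibble `map`, `marker`, `lg`, `cM` (one row per marker
#'   per component map).
#' @param marker_scaffold Optional tibble `marker`, `scaffold`.
#' @param reference_map Optional name of the reference map for rule 3.
#' @return Tibble of conflict records: `marker`, `scaffold`, `assignments`
#'   (collapsed `map:lg` list), `resolution` (chosen lg or NA if dropped)
#'   and `rule_applied`.
#' @export
resolve_chromosome_conflicts <- function(assignments, marker_scaffold = NULL,
                                         reference_map = NULL) {
  if (length(unique(assignments$map)) < 2) {
    abort("need assignments from at least two component maps.")
  }
  scaf <- if (is.null(marker_scaffold)) c() else
    setNames(marker_scaffold$scaffold, marker_scaffold$marker)
  # modal lg per marker (used as each marker's vote for its scaffold)
  modal <- vapply(split(assignments$lg, assignments$marker), function(v) {
    names(sort(table(v), decreasing = TRUE))[1]
  }, character(1))

  per_marker <- split(assignments, assignments$marker)
  rows <- lapply(names(per_marker), function(mk) {
    a <- per_marker[[mk]]
    lgs <- unique(a$lg)
    rec <- tibble(
      marker = mk,
      scaffold = unname(scaf[mk]) %||% NA_character_,
      assignments = paste(a$map, a$lg, sep = ":", collapse = ";"),
      resolution = NA_character_, rule_applied = NA_character_
    )
    if (is.null(rec$scaffold) || length(rec$scaffold) == 0) rec$scaffold <- NA_character_
    if (length(lgs) == 1) {
      rec$resolution <- lgs
      rec$rule_applied <- "unanimous"
      return(rec)
    }
    # rule 1: majority lg among other mapped markers of the same scaffold
    if (!is.na(rec$scaffold)) {
      mates <- names(scaf)[scaf == rec$scaffold & names(scaf) != mk]
      votes <- modal[intersect(mates, names(modal))]
      if (length(votes)) {
        tab <- sort(table(votes), decreasing = TRUE)
        if (length(tab) == 1 || tab[1] > tab[2]) {
          rec$resolution <- names(tab)[1]
          rec$rule_applied <- "scaffold_majority"
          return(rec)
        }
      }
    }
    # rule 2: majority vote among component maps
    tab <- sort(table(a$lg), decreasing = TRUE)
    if (tab[1] > tab[2]) {
      rec$resolution <- names(tab)[1]
      rec$rule_applied <- "map_majority"
      return(rec)
    }
    # rule 3: the reference map's assignment
    if (!is.null(reference_map) && reference_map %in% a$map) {
      rec$resolution <- a$lg[a$map == reference_map][1]
      rec$rule_applied <- "reference_map"
      return(rec)
    }
    rec$rule_applied <- "dropped"
    rec
  })
  bind_rows(rows)
}

# pool rf tables across populations by LOD weighting
pool_rf <- function(rf_tables, markers) {
  tabs <- lapply(names(rf_tables), function(nm) {
    t <- rf_tables[[nm]]
    t <- t[t$marker_a %in% markers & t$marker_b %in% markers &
             !is.na(t$r_hat) & t$lod > 0, c("marker_a", "marker_b", "r_hat", "lod")]
    if (nrow(t)) {
      swap <- t$marker_a > t$marker_b
      tmp <- t$marker_a[swap]
      t$marker_a[swap] <- t$marker_b[swap]
      t$marker_b[swap] <- tmp
    }
    t
  })
  bind_rows(tabs) |>
    group_by(.data$marker_a, .data$marker_b) |>
    summarise(r_hat = sum(.data$r_hat * .data$lod) / sum(.data$lod),
              lod = sum(.data$lod), .groups = "drop")
}

#' Merge bin representatives into a consensus skeleton
#'
#' For marker pairs estimated in several populations the pooled
#' recombination fraction is the LOD-weighted mean (sum w_i r_i / sum w_i
#' with w_i = LOD_i; pairs with zero LOD everywhere are excluded) and the
#' pooled LOD is the sum. Ordering and cM assignment then proceed exactly as
#' in a component map ([order_markers()] and [rf_to_cm()]) on the pooled
#' table.
#'
#' @param representatives Tibble `marker`, `lg`: the skeleton marker set.
#' @param rf_tables Named list of pairwise tables (one per population, see
#'   [pairwise_rf()]).
#' @param map_function `"kosambi"` or `"haldane"`.
#' @return Skeleton tibble `marker`, `lg`, `cM` with attribute `pooled_rf`.
#' @export
merge_skeleton <- function(representatives, rf_tables,
                           map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  pooled_all <- list()
  out <- lapply(split(representatives$marker, representatives$lg), function(mk) {
    mk <- sort(unique(mk))
    if (length(mk) == 1) return(tibble(marker = mk, cM = 0))
    pooled <- pool_rf(rf_tables, mk)
    pooled_all[[length(pooled_all) + 1]] <<- pooled
    ord <- order_markers(mk, pooled)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    rl <- setNames(pooled$r_hat, key(pooled$marker_a, pooled$marker_b))
    r_adj <- rl[key(ord[-length(ord)], ord[-1])]
    r_adj[is.na(r_adj)] <- 0.5 - 1e-9
    r_adj <- pmin(r_adj, 0.5 - 1e-9)
    tibble(marker = ord,
           cM = unname(c(0, cumsum(rf_to_cm(r_adj, map_function)))))
  })
  skel <- bind_rows(out, .id = "lg")[, c("marker", "lg", "cM")]
  structure(skel, map_function = map_function,
            pooled_rf = bind_rows(pooled_all))
}

#' Refill residual markers onto the skeleton
#'
#' Every non-skeleton marker is re-introduced at its bin position: consensus
#' position = its bin representative's consensus cM plus the marker's
#' original-map offset from that representative (sign-corrected when the
#' skeleton orientation of the linkage group is reversed relative to the
#' source map), clamped so consensus positions stay non-decreasing.
#' Residuals in a bin with no mapped representative are appended at the
#' nearest flanking skeleton position with a warning.
#'
#' @param skeleton Output of [merge_skeleton()].
#' @param bins Combined [select_representatives()] output across maps (long
#'   tibble with `map`, `lg`, `bin`, `marker`, `cM`, `is_representative`).
#' @param final_lg Optional tibble `marker`, `lg` fixing each marker's
#'   resolved linkage group (from [resolve_chromosome_conflicts()]); source
#'   records disagreeing with it are ignored.
#' @return A `cucumap_consensus` tibble: `lg`, `marker`, `cM`,
#'   `is_skeleton`, `source_map`, `src_cM`.
#' @export
refill_residuals <- function(skeleton, bins, final_lg = NULL) {
  skel_pos <- setNames(skeleton$cM, skeleton$marker)
  if (!is.null(final_lg)) {
    keep_lg <- setNames(final_lg$lg, final_lg$marker)
    ok <- is.na(keep_lg[bins$marker]) | bins$lg == keep_lg[bins$marker]
    bins <- bins[ok, ]
  }
  # orientation of each (map, lg) against the skeleton
  orient <- bins |>
    filter(.data$marker %in% names(skel_pos)) |>
    group_by(.data$map, .data$lg) |>
    summarise(sign = {
      if (n() < 3) 1 else {
        s <- suppressWarnings(cor(.data$cM, skel_pos[.data$marker],
                                  method = "spearman"))
        if (is.na(s) || s >= 0) 1 else -1
      }
    }, .groups = "drop")

  residual <- bins[!bins$marker %in% skeleton$marker, ]
  # one source record per residual marker: first map carrying it
  residual <- residual[!duplicated(residual$marker), ]
  placed <- lapply(seq_len(nrow(residual)), function(i) {
    rr <- residual[i, ]
    sgn <- orient$sign[orient$map == rr$map & orient$lg == rr$lg]
    if (!length(sgn)) sgn <- 1
    bin_mates <- bins[bins$map == rr$map & bins$bin == rr$bin &
                        bins$is_representative &
                        bins$marker %in% names(skel_pos), ]
    if (nrow(bin_mates)) {
      rep_mk <- bin_mates$marker[1]
      pos <- skel_pos[rep_mk] + sgn * (rr$cM - bin_mates$cM[1])
    } else {
      # no mapped representative: nearest flanking skeleton locus
      warn(paste0("marker ", rr$marker,
                  " refilled at nearest flanking skeleton position."))
      sk <- skeleton[skeleton$lg == rr$lg, ]
      src <- bins[bins$map == rr$map & bins$lg == rr$lg &
                    bins$marker %in% sk$marker, ]
      if (!nrow(src)) return(NULL)
      nearest <- src$marker[which.min(abs(src$cM - rr$cM))]
      pos <- skel_pos[nearest]
    }
    tibble(lg = rr$lg, marker = rr$marker, cM = unname(max(0, pos)),
           is_skeleton = FALSE, source_map = rr$map, src_cM = rr$cM)
  })
  all_loci <- bind_rows(
    tibble(lg = skeleton$lg, marker = skeleton$marker, cM = skeleton$cM,
           is_skeleton = TRUE, source_map = "skeleton",
           src_cM = NA_real_),
    bind_rows(placed)
  )
  out <- all_loci |>
    arrange(.data$lg, .data$cM, desc(.data$is_skeleton), .data$marker) |>
    group_by(.data$lg) |>
    mutate(cM = cummax(.data$cM)) |>
    ungroup()
  structure(out, map_function = attr(skeleton, "map_function"),
            class = c("cucumap_consensus", class(out)))
}

#' Spearman concordance of marker orders between two maps
#'
#' Computes Spearman's rank correlation of the shared-marker orders for each
#' linkage group the two maps have in common (ties mid-ranked). Groups with
#' fewer than two shared markers are reported with `NA`.
#'
#' @param map_x,map_y Map tibbles (`marker`, `lg`, `cM`).
#' @return Tibble `lg`, `n_shared`, `spearman_r`.
#' @export
order_concordance <- function(map_x, map_y) {
  lgs <- intersect(unique(map_x$lg), unique(map_y$lg))
  rows <- lapply(lgs, function(lg) {
    a <- map_x[map_x$lg == lg, ]
    b <- map_y[map_y$lg == lg, ]
    shared <- intersect(a$marker, b$marker)
    if (length(shared) < 2) {
      return(tibble(lg = lg, n_shared = length(shared), spearman_r = NA_real_))
    }
    ra <- rank(a$cM[match(shared, a$marker)])
    rb <- rank(b$cM[match(shared, b$marker)])
    tibble(lg = lg, n_shared = length(shared),
           spearman_r = suppressWarnings(cor(ra, rb, method = "spearman")))
  })
  bind_rows(rows)
}

#' Integrate component maps into a consensus map
#'
#' Full bin-mapping integration: chromosome-conflict resolution first (so
#' excluded or reassigned markers never seed bins), per-map 1-cM bins,
#' bridge-representative selection, LOD-weighted skeleton merging, and
#' residual refill.
#'
#' @param maps Named list of map tibbles (`marker`, `lg`, `cM`). Linkage
#'   group names must be comparable across maps.
#' @param geno Optional named list of genotype tables matching `maps`; used
#'   for pairwise recombination pooling and missing-data counts. Maps
#'   without genotypes fall back to map-distance-derived recombination
#'   fractions with unit LOD weight.
#' @param marker_scaffold Optional tibble `marker`, `scaffold` for conflict
#'   resolution.
#' @param bin_width Bin width in cM (default 1).
#' @param exclusions Optional tibble `map`, `lg`, `start_cM`, `end_cM` of
#'   regions excluded from representative selection.
#' @param reference_map Name of the map trusted in unresolvable conflicts
#'   (default: first of `maps`).
#' @param lg_components Optional named list: for a linkage group, restrict
#'   skeleton construction to the named component maps (residuals from all
#'   maps are still refilled).
#' @param map_function `"kosambi"` or `"haldane"`.
#' @return A `cucumap_consensus` tibble with attributes `bins`, `conflicts`
#'   and `skeleton`.
#' @export
integrate_maps <- function(maps, geno = NULL, marker_scaffold = NULL,
                           bin_width = 1, exclusions = NULL,
                           reference_map = names(maps)[1],
                           lg_components = NULL,
                           map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (length(maps) < 2) abort("need at least two component maps.")
  assignments <- bind_rows(lapply(names(maps), function(nm) {
    tibble(map = nm, marker = maps[[nm]]$marker, lg = maps[[nm]]$lg,
           cM = maps[[nm]]$cM)
  }))
  conflicts <- resolve_chromosome_conflicts(assignments, marker_scaffold,
                                            reference_map)
  final_lg <- conflicts[!is.na(conflicts$resolution),
                        c("marker", "resolution")] |>
    rename(lg = "resolution")
  dropped <- conflicts$marker[is.na(conflicts$resolution)]

  keep_lg <- setNames(final_lg$lg, final_lg$marker)
  maps_ok <- lapply(names(maps), function(nm) {
    m <- maps[[nm]]
    m <- m[!m$marker %in% dropped & m$lg == keep_lg[m$marker], ]
    m
  })
  names(maps_ok) <- names(maps)

  shared_counts <- assignments |>
    distinct(.data$map, .data$marker) |>
    count(.data$marker, name = "n_maps") |>
    mutate(n_shared = .data$n_maps - 1L)

  rf_tables <- lapply(names(maps), function(nm) {
    if (!is.null(geno) && nm %in% names(geno)) {
      pairwise_rf(geno[[nm]])
    } else {
      m <- maps_ok[[nm]]
      bind_rows(lapply(split(m, m$lg), function(sub) {
        if (nrow(sub) < 2) return(NULL)
        ij <- which(upper.tri(diag(nrow(sub))), arr.ind = TRUE)
        d <- abs(sub$cM[ij[, 1]] - sub$cM[ij[, 2]])
        tibble(marker_a = sub$marker[ij[, 1]], marker_b = sub$marker[ij[, 2]],
               r_hat = cm_to_rf(d, map_function), lod = 1,
               n_informative = NA_integer_)
      }))
    }
  })
  names(rf_tables) <- names(maps)

  bins <- bind_rows(lapply(names(maps), function(nm) {
    b <- build_bins(maps_ok[[nm]], bin_width, map_name = nm)
    mc <- if (!is.null(geno) && nm %in% names(geno)) {
      geno_missing_counts(geno[[nm]])
    } else NULL
    select_representatives(b, shared_counts, mc, exclusions)
  }))

  reps <- bins[bins$is_representative, c("marker", "lg", "map")]
  if (!is.null(lg_components)) {
    for (lg in names(lg_components)) {
      reps <- reps[reps$lg != lg | reps$map %in% lg_components[[lg]], ]
    }
  }
  reps <- distinct(reps[, c("marker", "lg")])

  skeleton <- merge_skeleton(reps, rf_tables, map_function)
  consensus <- refill_residuals(skeleton, bins, final_lg)
  attr(consensus, "bins") <- bins
  attr(consensus, "conflicts") <- conflicts
  attr(consensus, "skeleton") <- skeleton
  consensus
}
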