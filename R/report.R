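#' Per-linkage-group map summary
#'
#' Aggregates a (consensus or component) map into the usual summary table:
#' loci counts, map lengths, mean adjacent-marker spacing, and - when an
#' anchor report is supplied - scaffolds anchored and anchored Mb per
#' linkage group. The overall mean spacing uses the count of adjacent
#' intervals as denominator, total cM / (total loci - number of linkage
#' groups). cM values are reported to one decimal, spacings to two.
#'
#' @param map Map tibble `marker`, `lg`, `cM`.
#' @param anchors Optional [anchor_scaffolds()] result.
#' @return Tibble with one row per linkage group plus a `Total` row:
#'   `lg`, `n_loci`, `length_cM`, `mean_spacing_cM` (and `n_scaffolds`,
#'   `anchored_mb` when anchored).
#' @export
summarize_map <- function(map, anchors = NULL) {
  per <- map |>
    group_by(.data$lg) |>
    summarise(n_loci = n(), length_cM = round(max(.data$cM) - min(.data$cM), 1),
              .groups = "drop") |>
    mutate(mean_spacing_cM = round(.data$length_cM / pmax(.data$n_loci - 1, 1), 2))
  total <- tibble(
    lg = "Total", n_loci = sum(per$n_loci),
    length_cM = round(sum(per$length_cM), 1),
    mean_spacing_cM = round(sum(per$length_cM) /
                              (sum(per$n_loci) - nrow(per)), 2)
  )
  out <- bind_rows(per, total)
  if (!is.null(anchors)) {
    a <- as_tibble(anchors) |>
      filter(.data$anchored) |>
      group_by(.data$lg) |>
      summarise(n_scaffolds = n(),
                anchored_mb = round(sum(.data$length_bp) / 1e6, 1),
                .groups = "drop")
    out <- left_join(out, a, by = "lg")
    out$n_scaffolds[out$lg == "Total"] <- sum(a$n_scaffolds)
    out$anchored_mb[out$lg == "Total"] <- round(sum(a$anchored_mb), 1)
  }
  out
}

#' RGH class-count summary
#'
#' @param genes Classified gene tibble (see [classify_rgh()]).
#' @return Tibble `class`, `n` in canonical class order, plus a `Total` row.
#' @export
summarize_classes <- function(genes) {
  lev <- c("CNL", "CN", "TNL", "TN", "NL", "N", "unclassified")
  tab <- table(factor(genes$class, levels = lev))
  out <- tibble(class = names(tab), n = as.integer(tab)) |>
    filter(.data$n > 0 | .data$class != "unclassified")
  bind_rows(out, tibble(class = "Total", n = sum(out$n)))
}

#' Cluster characteristics table
#'
#' Combines [detect_clusters()] membership with [cluster_stats()] into a
#' report like a published cluster-characteristics table.
#'
#' @param clusters [detect_clusters()] output.
#' @param genes Classified gene tibble (optional, for class composition).
#' @param map_positions Optional tibble `gene`, `cM`.
#' @return Tibble of per-cluster rows.
#' @export
summarize_clusters <- function(clusters, genes = NULL, map_positions = NULL) {
  st <- cluster_stats(clusters, map_positions)
  if (!is.null(genes) && "class" %in% names(genes)) {
    cls <- clusters |>
      left_join(genes[, c(if ("gene" %in% names(genes)) "gene" else "id",
                          "class")] |>
                  rename(gene = 1), by = "gene") |>
      group_by(.data$cluster) |>
      summarise(classes = paste(sort(unique(.data$class)), collapse = ","),
                .groups = "drop")
    st <- left_join(st, cls, by = "cluster")
  }
  st
}

#' Published cucumber reference summaries
#'
#' Summary statistics of the cucumber Gy14 NB-LRR complement and the
#' 1,681-locus cucumber consensus map, bundled as plain tibbles so the
#' package's aggregation arithmetic can be cross-checked against printed
#' values (class counts, cluster spans and densities, per-chromosome locus
#' counts and map lengths, genome anchoring).
#'
#' @return `cucumber_rgh_classes()`: class counts of the 70 NB-LRR genes.
#'   `cucumber_rgh_clusters()`: the nine physical clusters (members, span,
#'   density, genetic span). `cucumber_consensus_summary()`:
#'   per-chromosome locus counts and cM lengths of the consensus and its
#'   three component maps. `cucumber_genome_constants()`: genome size and
#'   anchoring totals.
#' @export
cucumber_rgh_classes <- function() {
  tibble(class = c("CNL", "CN", "TNL", "TN", "NL", "N"),
         n = c(25L, 1L, 19L, 5L, 17L, 3L))
}

#' @rdname cucumber_rgh_classes
#' @export
cucumber_rgh_clusters <- function() {
  tibble(
    cluster = 1:9,
    chromosome = paste0("chr", c(2, 2, 2, 2, 3, 3, 4, 5, 7)),
    scaffold = c("scaffold01037", "scaffold00894", "scaffold01227",
                 "scaffold00245", "scaffold02229", "scaffold03356",
                 "scaffold00919", "scaffold02023", "scaffold01024"),
    n_rgh = c(2L, 11L, 3L, 4L, 2L, 7L, 5L, 12L, 6L),
    span_kb = c(857.3, 288.8, 413.4, 109.5, 59.6, 1143.1, 43.4, 258.3, 94.4),
    genetic_span_cM = c(1.4, 1.8, 2.0, 2.5, 0.0, 5.9, 0.6, 0.5, 0.0)
  )
}

#' @rdname cucumber_rgh_classes
#' @export
cucumber_consensus_summary <- function() {
  tibble(
    chromosome = paste0("chr", 1:7),
    loci_csh_ril = c(118L, 126L, 187L, 41L, 160L, 203L, 87L),
    loci_css_f2 = c(155L, 93L, 167L, 105L, 84L, 113L, 67L),
    loci_css_ril = c(17L, 33L, 54L, 37L, 57L, 54L, 25L),
    loci_consensus = c(241L, 214L, 316L, 220L, 250L, 295L, 145L),
    length_csh_ril_cM = c(96.2, 100.2, 112.7, 96.0, 59.9, 106.5, 60.1),
    length_css_f2_cM = c(100.4, 103.6, 119.4, 107.4, 106.3, 102.2, 67.4),
    length_css_ril_cM = c(115.7, 88.0, 137.5, 107.9, 118.3, 111.4, 90.1),
    length_consensus_cM = c(102.8, 108.9, 121.9, 106.3, 101.0, 110.7, 78.4)
  )
}

#' @rdname cucumber_rgh_classes
#' @export
cucumber_genome_constants <- function() {
  tibble(
    genome_mbp = 367, anchored_mbp = 193.2, n_scaffolds_anchored = 308L,
    n_rgh = 70L, n_rgh_unanchorable = 3L,
    n_prior_f2_loci = 735L, n_new_rgh_markers = 48L,
    n_nb_complete = 58L
  )
}
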