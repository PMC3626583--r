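#' Synthetic truth-genome configuration
#'
#' Parameters of the simulated genome used throughout the package: a
#' seven-chromosome cucumber-like genome (~100 cM per chromosome), SSR-like
#' codominant markers hosted on draft-genome scaffolds, and an NB-LRR
#' resistance-gene complement of 70 genes placed as nine physical clusters
#' plus 18 singletons, with class counts matching the published cucumber
#' complement (25 CNL, 1 CN, 19 TNL, 5 TN, 17 NL, 3 N).
#'
#' Physical chromosome length defaults to 12 Mbp: sequence is only ever
#' generated for scaffolds, and 12 Mbp leaves room for >1 Mbp spacing
#' between gene-bearing scaffolds so planted clusters stay distinct under
#' the strict < 1 Mbp cluster rule.
#'
#' @param n_chr Number of chromosomes.
#' @param chr_length_cM,chr_length_bp Genetic and physical chromosome length.
#' @param markers_per_chr Codominant markers per chromosome.
#' @param marker_scaffolds_per_chr,marker_scaffold_bp Marker-hosting
#'   scaffolds per chromosome and their sequence length.
#' @param rgh_cluster_sizes,rgh_cluster_span_kb,rgh_cluster_chr Planted RGH
#'   cluster member counts, physical spans (kb) and host chromosomes.
#' @param rgh_singletons_per_chr Unclustered RGH genes per chromosome.
#' @param rgh_class_counts Named counts over the six architecture classes.
#' @param gene_length_bp RGH gene length.
#' @param n_incomplete_nb How many genes lack a complete NB domain (these are
#'   excluded from phylogeny, leaving 58 by default).
#' @param suppression_regions Optional tibble (`chromosome`, `start_cM`,
#'   `end_cM`, `multiplier`) of crossover-suppressed regions; multiplier in
#'   \[0,1\] thins simulated crossovers (0 = full suppression).
#' @param seed Integer master seed.
#' @return A validated config list of class `cucumap_truth_config`.
#' @export
sim_truth_config <- function(n_chr = 7,
                             chr_length_cM = 100,
                             chr_length_bp = 12e6,
                             markers_per_chr = 30,
                             marker_scaffolds_per_chr = 6,
                             marker_scaffold_bp = 10000,
                             rgh_cluster_sizes = c(2, 11, 3, 4, 2, 7, 5, 12, 6),
                             rgh_cluster_span_kb =
                               c(857.3, 288.8, 413.4, 109.5, 59.6, 990.0,
                                 43.4, 258.3, 94.4),
                             rgh_cluster_chr = c(2, 2, 2, 2, 3, 3, 4, 5, 7),
                             rgh_singletons_per_chr = c(4, 4, 2, 1, 4, 2, 1),
                             rgh_class_counts =
                               c(CNL = 25, CN = 1, TNL = 19, TN = 5,
                                 NL = 17, N = 3),
                             gene_length_bp = 2000,
                             n_incomplete_nb = 12,
                             suppression_regions = NULL,
                             seed = 1) {
  cfg <- as.list(environment())
  check_pos <- function(x, nm) {
    if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
      abort(paste0("invalid configuration: `", nm, "` must be positive."))
    }
  }
  for (nm in c("n_chr", "chr_length_cM", "chr_length_bp", "markers_per_chr",
               "marker_scaffolds_per_chr", "marker_scaffold_bp",
               "gene_length_bp")) {
    check_pos(cfg[[nm]], nm)
  }
  if (length(rgh_cluster_sizes) &&
      (length(rgh_cluster_span_kb) != length(rgh_cluster_sizes) ||
       length(rgh_cluster_chr) != length(rgh_cluster_sizes))) {
    abort("invalid configuration: cluster size/span/chr lengths differ.")
  }
  if (length(rgh_cluster_sizes) && any(rgh_cluster_sizes < 2)) {
    abort("invalid configuration: `rgh_cluster_sizes` must all be >= 2.")
  }
  if (any(rgh_cluster_chr > n_chr) ||
      length(rgh_singletons_per_chr) > n_chr) {
    abort("invalid configuration: RGH placement exceeds `n_chr`.")
  }
  n_genes <- sum(rgh_cluster_sizes) + sum(rgh_singletons_per_chr)
  if (n_genes != sum(rgh_class_counts)) {
    abort("invalid configuration: `rgh_class_counts` must sum to gene count.")
  }
  if (n_incomplete_nb < 0 || n_incomplete_nb > n_genes) {
    abort("invalid configuration: `n_incomplete_nb` out of range.")
  }
  if (!is.null(suppression_regions)) {
    if (any(suppression_regions$multiplier < 0 |
            suppression_regions$multiplier > 1)) {
      abort("invalid configuration: `suppression_regions` multiplier not in [0,1].")
    }
  }
  structure(cfg, class = "cucumap_truth_config")
}

class_domains <- function(class) {
  switch(class,
    N = "NB", CN = c("CC", "NB"), NL = c("NB", "LRR"),
    TN = c("TIR", "NB"), TNL = c("TIR", "NB", "LRR"),
    CNL = c("CC", "NB", "LRR")
  )
}

#' Simulate a ground-truth genome
#'
#' Generates chromosomes, markers with true genetic (cM) and physical (bp)
#' coordinates, draft-genome scaffolds, and an NB-LRR gene complement with
#' planted clusters, per [sim_truth_config()]. Deterministic for a fixed
#' config (the seed lives in the config).
#'
#' Marker genetic positions are near-evenly spaced with jitter (SSR framework
#' maps); marker physical positions are colinear with genetic positions so
#' error-free fixtures have genetic-physical colinearity r = 1. Gene-bearing
#' scaffolds are spaced > 1 Mbp apart so planted clusters are exactly the
#' maximal runs recovered by [detect_clusters()].
#'
#' @param config A [sim_truth_config()] list.
#' @return A list of class `cucumap_truth` with tibbles `chromosomes`,
#'   `markers`, `scaffolds`, `rgh_genes` and `suppression_regions`.
#' @export
simulate_truth <- function(config = sim_truth_config()) {
  if (!inherits(config, "cucumap_truth_config")) {
    config <- do.call(sim_truth_config, config)
  }
  set.seed(child_seed(config$seed, "truth"))
  n_chr <- config$n_chr
  chroms <- tibble(
    name = paste0("chr", seq_len(n_chr)),
    length_cM = config$chr_length_cM,
    length_bp = config$chr_length_bp
  )

  clusters <- tibble(
    cluster = seq_along(config$rgh_cluster_sizes),
    size = config$rgh_cluster_sizes,
    span_bp = round(config$rgh_cluster_span_kb * 1000),
    chromosome = paste0("chr", config$rgh_cluster_chr)
  )
  singles <- tibble(
    chromosome = paste0("chr", seq_along(config$rgh_singletons_per_chr)),
    n = config$rgh_singletons_per_chr
  )

  scaffolds <- list()
  genes <- list()
  markers <- list()
  scaf_counter <- 0L
  gene_counter <- 0L
  for (ci in seq_len(n_chr)) {
    chr <- chroms$name[ci]
    # gene-bearing scaffolds on this chromosome: clusters then singletons
    cl <- clusters[clusters$chromosome == chr, ]
    n_single <- sum(singles$n[singles$chromosome == chr])
    gene_lens <- c(cl$span_bp + 4000,
                   rep(config$gene_length_bp + 4000, n_single))
    n_gene_scaf <- length(gene_lens)
    min_gap <- 1.1e6
    if (n_gene_scaf > 0) {
      need <- sum(gene_lens) + min_gap * (n_gene_scaf - 1)
      if (need > config$chr_length_bp) {
        abort(paste0("invalid configuration: `chr_length_bp` too short for ",
                     "gene scaffolds on ", chr, "."))
      }
      slack <- config$chr_length_bp - need
      cuts <- runif(n_gene_scaf + 1)
      extras <- floor(slack * cuts / sum(cuts))
      # shuffle which slot holds which cluster/singleton scaffold
      ord <- sample.int(n_gene_scaf)
      lens <- gene_lens[ord]
      starts <- integer(n_gene_scaf)
      pos <- 1
      for (k in seq_len(n_gene_scaf)) {
        pos <- pos + extras[k] + if (k > 1) min_gap else 0
        starts[k] <- pos
        pos <- pos + lens[k]
      }
      gs <- tibble(
        start_bp = starts,
        length_bp = lens,
        role = c(rep("cluster", nrow(cl)), rep("singleton", n_single))[ord],
        cluster = c(cl$cluster, rep(NA_integer_, n_single))[ord]
      )
      gs$end_bp <- gs$start_bp + gs$length_bp - 1
    } else {
      gs <- tibble(start_bp = integer(), length_bp = integer(),
                   role = character(), cluster = integer(),
                   end_bp = integer())
    }

    # marker scaffolds dropped into the widest free intervals
    occ <- gs[order(gs$start_bp), c("start_bp", "end_bp")]
    free_start <- c(1, occ$end_bp + 1)
    free_end <- c(occ$start_bp - 1, config$chr_length_bp)
    free <- tibble(s = free_start, e = free_end) |>
      filter(.data$e - .data$s + 1 > config$marker_scaffold_bp + 2)
    n_ms <- config$marker_scaffolds_per_chr
    slot_gap <- config$marker_scaffold_bp + 20000
    slots <- unlist(lapply(seq_len(nrow(free)), function(k) {
      seq(free$s[k] + 1, free$e[k] - config$marker_scaffold_bp, by = slot_gap)
    }), use.names = FALSE)
    if (length(slots) < n_ms) {
      abort("invalid configuration: not enough room for `marker_scaffolds_per_chr`.")
    }
    ms_start <- sort(slots)[round(seq(1, length(slots), length.out = n_ms))]
    ms <- tibble(start_bp = sort(ms_start),
                 length_bp = config$marker_scaffold_bp,
                 role = "marker", cluster = NA_integer_)
    ms$end_bp <- ms$start_bp + ms$length_bp - 1

    sc <- bind_rows(gs, ms) |> arrange(.data$start_bp)
    sc$id <- sprintf("scaffold%05d", scaf_counter + seq_len(nrow(sc)))
    scaf_counter <- scaf_counter + nrow(sc)
    sc$chromosome <- chr
    scaffolds[[ci]] <- sc

    # markers: near-even cM spacing, physical order matching genetic order
    m <- config$markers_per_chr
    L <- config$chr_length_cM
    cM <- sort(pmin(pmax((seq_len(m) - 0.5) * L / m +
                           runif(m, -0.25, 0.25) * L / m, 0), L))
    msc <- sc[sc$role == "marker", ]
    scaf_ix <- ceiling(seq_len(m) * nrow(msc) / m)
    off <- unlist(lapply(split(seq_len(m), scaf_ix), function(ix) {
      sort(sample.int(config$marker_scaffold_bp - 2, length(ix)))
    }), use.names = FALSE)
    markers[[ci]] <- tibble(
      id = sprintf("SSR%02d%03d", ci, seq_len(m)),
      chromosome = chr,
      true_cM = cM,
      scaffold_id = msc$id[scaf_ix],
      scaffold_offset_bp = off + 1L,
      chrom_bp = msc$start_bp[scaf_ix] + off
    )

    # genes on this chromosome's gene scaffolds
    for (k in which(sc$role %in% c("cluster", "singleton"))) {
      row <- sc[k, ]
      if (row$role == "cluster") {
        info <- clusters[clusters$cluster == row$cluster, ]
        kk <- info$size
        span <- info$span_bp
        first <- 2001
        starts_g <- round(seq(first, first + span - config$gene_length_bp,
                              length.out = kk))
      } else {
        kk <- 1
        starts_g <- 2001
      }
      genes[[length(genes) + 1]] <- tibble(
        id = sprintf("RGH%03d", gene_counter + seq_len(kk)),
        scaffold_id = row$id,
        chromosome = chr,
        start_bp = as.integer(starts_g),
        end_bp = as.integer(starts_g + config$gene_length_bp - 1),
        chrom_start_bp = row$start_bp + as.integer(starts_g) - 1L,
        chrom_end_bp = row$start_bp + as.integer(starts_g) +
          config$gene_length_bp - 2L,
        cluster_truth = if (row$role == "cluster") row$cluster else NA_integer_
      )
      gene_counter <- gene_counter + kk
    }
  }

  genes <- bind_rows(genes)
  # class labels, clade membership and NB-domain completeness
  classes <- sample(rep(names(config$rgh_class_counts),
                        config$rgh_class_counts))
  genes$class_truth <- classes
  genes$domains <- vapply(classes,
                          function(cl) paste(class_domains(cl), collapse = ","),
                          character(1))
  genes$clade_truth <- ifelse(classes %in% c("CNL", "CN"), "CNL",
                       ifelse(classes %in% c("TNL", "TN"), "TNL",
                              sample(c("CNL", "TNL"), nrow(genes),
                                     replace = TRUE)))
  incomplete <- sample(genes$id, config$n_incomplete_nb)
  genes$complete_nb <- !genes$id %in% incomplete

  supp <- config$suppression_regions %||%
    tibble(chromosome = character(), start_cM = numeric(),
           end_cM = numeric(), multiplier = numeric())

  structure(
    list(chromosomes = chroms,
         markers = bind_rows(markers),
         scaffolds = bind_rows(scaffolds) |>
           select("id", "chromosome", "start_bp", "end_bp", "length_bp",
                  "role", "cluster"),
         rgh_genes = genes,
         suppression_regions = as_tibble(supp),
         config = config),
    class = "cucumap_truth"
  )
}

#' Cross design
#'
#' @param kind `"F2"` or `"RIL"`.
#' @param n_individuals Population size (>= 2).
#' @param selfing_generations For RILs: number of selfing generations
#'   simulated at meiosis level; `Inf` (default) uses the fixation limit, in
#'   which adjacent-marker recombinant fractions follow the
#'   Haldane-Waddington relation R = 2r / (1 + 2r).
#' @param marker_fraction Fraction of truth markers genotyped in this
#'   population (a random subset; default 1).
#' @param missing_rate,genotyping_error_rate Per-call rates in \[0, 1).
#'   Errors are symmetric re-draws among the other valid codes and are
#'   applied before missingness.
#' @param seed Integer seed for the cross.
#' @return A validated design list of class `cucumap_cross_design`.
#' @export
cross_design <- function(kind = c("F2", "RIL"), n_individuals,
                         selfing_generations = Inf, marker_fraction = 1,
                         missing_rate = 0, genotyping_error_rate = 0,
                         seed = 1) {
  kind <- match.arg(kind)
  if (n_individuals < 2) abort("invalid design: `n_individuals` must be >= 2.")
  for (r in c(missing_rate, genotyping_error_rate)) {
    if (r < 0 || r >= 1) abort("invalid design: rates must lie in [0, 1).")
  }
  if (marker_fraction <= 0 || marker_fraction > 1) {
    abort("invalid design: `marker_fraction` must lie in (0, 1].")
  }
  structure(list(kind = kind, n_individuals = as.integer(n_individuals),
                 selfing_generations = selfing_generations,
                 marker_fraction = marker_fraction,
                 missing_rate = missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 seed = seed),
            class = "cucumap_cross_design")
}

# multiplier applying to a crossover point, given suppression regions
supp_multiplier <- function(x, regions) {
  m <- rep(1, length(x))
  if (nrow(regions) == 0) return(m)
  for (i in seq_len(nrow(regions))) {
    inside <- x >= regions$start_cM[i] & x <= regions$end_cM[i]
    m[inside] <- m[inside] * regions$multiplier[i]
  }
  m
}

# one recombinant gamete from a pair of haplotypes (0/1 allele vectors at
# marker positions p on a chromosome of length L cM)
meiosis_gamete <- function(h1, h2, p, L, regions) {
  n_x <- rpois(1, L / 100)
  pts <- sort(runif(n_x, 0, L))
  if (length(pts)) pts <- pts[runif(length(pts)) < supp_multiplier(pts, regions)]
  phase <- (sample(0:1, 1) + findInterval(p, pts)) %% 2
  ifelse(phase == 0, h1, h2)
}

# effective (suppression-thinned) length of interval [a, b] in cM
effective_len <- function(a, b, regions) {
  len <- b - a
  if (nrow(regions) == 0) return(len)
  for (i in seq_len(nrow(regions))) {
    ov <- max(0, min(b, regions$end_cM[i]) - max(a, regions$start_cM[i]))
    len <- len - ov * (1 - regions$multiplier[i])
  }
  len
}

#' Simulate a segregating population from a truth genome
#'
#' Meioses draw crossovers as a homogeneous Poisson process with rate
#' length_cM / 100 per chromosome (no interference, so the Haldane map
#' function is exact for the simulation), thinned inside suppression regions
#' by the region multiplier. An F2 individual is two independent F1 gametes.
#' RILs are produced by iterated meiosis-level selfing for a finite
#' `selfing_generations` (residual heterozygous calls are reported missing),
#' or by the fixation-limit Markov chain along markers when
#' `selfing_generations = Inf`. Genotyping error and missingness are applied
#' last, in that order.
#'
#' @param truth A [simulate_truth()] object.
#' @param design A [cross_design()].
#' @return A genotype table (see [as_geno()]) with attributes `truth_map`
#'   (marker, chromosome, true_cM) and `design`.
#' @export
simulate_population <- function(truth, design) {
  stopifnot(inherits(truth, "cucumap_truth"),
            inherits(design, "cucumap_cross_design"))
  if (nrow(truth$markers) < 1) abort("truth genome has no markers.")
  set.seed(design$seed)
  n <- design$n_individuals
  sup <- truth$suppression_regions
  per_chr <- split(truth$markers, truth$markers$chromosome)
  per_chr <- per_chr[unique(truth$markers$chromosome)]

  rows <- lapply(per_chr, function(mk) {
    p <- mk$true_cM
    m <- length(p)
    L <- truth$chromosomes$length_cM[truth$chromosomes$name == mk$chromosome[1]]
    regions <- sup[sup$chromosome == mk$chromosome[1], , drop = FALSE]
    if (design$kind == "F2") {
      g <- matrix(0L, n, m)
      for (i in seq_len(n)) {
        g[i, ] <- meiosis_gamete(rep(0L, m), rep(1L, m), p, L, regions) +
          meiosis_gamete(rep(0L, m), rep(1L, m), p, L, regions)
      }
      code <- c("A", "H", "B")[g + 1]
    } else if (is.finite(design$selfing_generations)) {
      g <- matrix(0L, n, m)
      for (i in seq_len(n)) {
        h1 <- rep(0L, m); h2 <- rep(1L, m)
        for (gen in seq_len(design$selfing_generations)) {
          nh1 <- meiosis_gamete(h1, h2, p, L, regions)
          nh2 <- meiosis_gamete(h1, h2, p, L, regions)
          h1 <- nh1; h2 <- nh2
        }
        g[i, ] <- h1 + h2
      }
      code <- c("A", "-", "B")[g + 1] # residual heterozygotes -> missing
    } else {
      # fixation limit: Markov chain along markers with Haldane-Waddington R
      d_eff <- vapply(seq_len(max(m - 1, 0)), function(j) {
        effective_len(p[j], p[j + 1], regions)
      }, numeric(1))
      r_adj <- 0.5 * (1 - exp(-2 * d_eff / 100))
      R <- 2 * r_adj / (1 + 2 * r_adj)
      a1 <- rbinom(n, 1, 0.5)
      sw <- matrix(rbinom(n * length(R), 1, rep(R, each = n)), n)
      g <- (a1 + cbind(0L, t(apply(sw, 1, cumsum)))[, seq_len(m), drop = FALSE]) %% 2
      code <- c("A", "B")[g + 1]
    }
    matrix(code, n, m, dimnames = list(NULL, mk$id))
  })
  calls <- t(do.call(cbind, rows)) # markers x individuals

  # symmetric genotyping error among the other valid codes
  e <- design$genotyping_error_rate
  if (e > 0) {
    valid <- if (design$kind == "F2") c("A", "H", "B") else c("A", "B")
    hit <- which(matrix(runif(length(calls)) < e, nrow(calls)) & calls != "-")
    calls[hit] <- vapply(calls[hit], function(old) {
      sample(setdiff(valid, old), 1)
    }, character(1))
  }
  if (design$missing_rate > 0) {
    calls[runif(length(calls)) < design$missing_rate] <- "-"
  }
  colnames(calls) <- sprintf("ind%03d", seq_len(n))
  if (design$marker_fraction < 1) {
    keep <- sort(sample.int(nrow(calls),
                            ceiling(design$marker_fraction * nrow(calls))))
    calls <- calls[keep, , drop = FALSE]
  }

  out <- as_geno(bind_cols(tibble(marker = rownames(calls)),
                           as_tibble(calls)),
                 population = design$kind)
  attr(out, "truth_map") <- truth$markers[, c("id", "chromosome", "true_cM")] |>
    rename(marker = "id")
  attr(out, "design") <- design
  out
}
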