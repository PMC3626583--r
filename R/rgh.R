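#' Classify an NB-LRR domain architecture
#'
#' Maps an ordered domain list onto the six-class grammar used for plant
#' resistance gene homologs: the NB domain is obligatory; a CC domain before
#' the (first) NB adds the C prefix, a TIR domain before the NB adds the T
#' prefix (mutually exclusive - both present yields `"unclassified"` with a
#' warning), and an LRR domain after the (last) NB adds the L suffix. The
#' classes are N, CN, NL, TN, TNL and CNL.
#'
#' @param domains Character vector of ordered domain labels (subset of
#'   `CC`, `TIR`, `NB`, `LRR`, `other`).
#' @return A single class string.
#' @examples
#' classify_architecture(c("CC", "NB", "LRR")) # "CNL"
#' classify_architecture("NB")                 # "N"
#' @export
classify_architecture <- function(domains) {
  if (!length(domains)) abort("empty domain list.")
  nb <- which(domains == "NB")
  if (!length(nb)) abort("no NB domain: not a resistance gene homolog.")
  has_cc <- any(domains[seq_len(min(nb) - 1)] == "CC")
  has_tir <- any(domains[seq_len(min(nb) - 1)] == "TIR")
  if (has_cc && has_tir) {
    warn("both CC and TIR precede the NB domain; architecture unclassified.")
    return("unclassified")
  }
  has_lrr <- max(nb) < length(domains) && any(domains[(max(nb) + 1):length(domains)] == "LRR")
  paste0(if (has_cc) "C" else if (has_tir) "T" else "", "N",
         if (has_lrr) "L" else "")
}

#' Classify a table of annotated genes
#'
#' @param genes Tibble with a `domains` column of comma-joined ordered
#'   domain labels (as read by [read_annotations()]).
#' @return `genes` with a `class` column added.
#' @export
classify_rgh <- function(genes) {
  genes$class <- vapply(strsplit(genes$domains, ","),
                        classify_architecture, character(1))
  genes
}

gene_position_cols <- function(genes) {
  # chromosome-level coordinates when available, else per-scaffold
  if (all(c("chromosome", "chrom_start_bp", "chrom_end_bp") %in% names(genes))) {
    list(seq = genes$chromosome, start = genes$chrom_start_bp,
         end = genes$chrom_end_bp)
  } else if (all(c("scaffold", "start", "end") %in% names(genes))) {
    list(seq = genes$scaffold, start = genes$start, end = genes$end)
  } else {
    abort("genes need chromosome- or scaffold-level coordinates.")
  }
}

#' Detect physical RGH clusters
#'
#' A cluster is a maximal run of two or more consecutive genes (per
#' chromosome, or per scaffold when unanchored) whose total span - first
#' member's start to last member's end - is strictly less than 1 Mbp.
#' Detection is a greedy left-to-right maximal extension over genes sorted
#' by start position; singletons are not clusters.
#'
#' @param genes Positioned gene tibble (columns `id` plus either
#'   `chromosome`/`chrom_start_bp`/`chrom_end_bp` or
#'   `scaffold`/`start`/`end`; `gene` accepted for `id`).
#' @param max_span_bp Strict span threshold (default 1e6).
#' @return Tibble `cluster`, `seqname`, `gene`, `start_bp`, `end_bp`,
#'   one row per clustered gene.
#' @export
detect_clusters <- function(genes, max_span_bp = 1e6) {
  if (!"id" %in% names(genes) && "gene" %in% names(genes)) {
    genes$id <- genes$gene
  }
  pos <- gene_position_cols(genes)
  d <- tibble(id = genes$id, seqname = pos$seq, start = pos$start,
              end = pos$end)
  if (anyNA(d$seqname)) {
    warn("genes without positions skipped in cluster detection.")
    d <- d[!is.na(d$seqname), ]
  }
  out <- list()
  cid <- 0L
  for (sq in unique(d$seqname)) {
    sub <- d[d$seqname == sq, ][order(d$start[d$seqname == sq]), ]
    i <- 1L
    while (i <= nrow(sub)) {
      j <- i
      while (j + 1 <= nrow(sub) &&
             sub$end[j + 1] - sub$start[i] + 1 < max_span_bp) {
        j <- j + 1L
      }
      if (j > i) {
        cid <- cid + 1L
        out[[cid]] <- tibble(cluster = cid, seqname = sq,
                             gene = sub$id[i:j], start_bp = sub$start[i:j],
                             end_bp = sub$end[i:j])
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) {
    return(tibble(cluster = integer(), seqname = character(),
                  gene = character(), start_bp = numeric(),
                  end_bp = numeric()))
  }
  bind_rows(out)
}

#' Summary statistics per RGH cluster
#'
#' Span is measured from the first member's start to the last member's end;
#' density is 100 x members / span_kb (reported rounded to one decimal);
#' the genetic span is the range of consensus-map positions of the members'
#' molecular tags when available.
#'
#' @param clusters Output of [detect_clusters()].
#' @param map_positions Optional tibble `gene`, `cM` of mapped tag
#'   positions.
#' @return Tibble `cluster`, `seqname`, `n_members`, `span_kb`,
#'   `density_per_100kb`, `genetic_span_cM`.
#' @export
cluster_stats <- function(clusters, map_positions = NULL) {
  pos <- if (is.null(map_positions)) c() else
    setNames(map_positions$cM, map_positions$gene)
  out <- clusters |>
    group_by(.data$cluster, .data$seqname) |>
    summarise(
      n_members = n(),
      span_kb = (max(.data$end_bp) - min(.data$start_bp) + 1) / 1000,
      genetic_span_cM = {
        p <- pos[.data$gene]
        p <- p[!is.na(p)]
        if (length(p) < 1) NA_real_ else max(p) - min(p)
      },
      .groups = "drop"
    )
  zero <- out$span_kb <= 0
  if (any(zero)) {
    warn("cluster with zero physical span; density reported as Inf.")
  }
  out$density_per_100kb <- ifelse(zero, Inf,
                                  round(100 * out$n_members / out$span_kb, 1))
  out[, c("cluster", "seqname", "n_members", "span_kb",
          "density_per_100kb", "genetic_span_cM")]
}

#' Extract the NB-domain peptide of a gene
#'
#' Returns the ~120-aa nucleotide-binding domain substring (P-loop to Kin3
#' motif region) given its 1-based inclusive amino-acid span. Genes lacking
#' a complete span are excluded from phylogeny; pass them as `NA` spans and
#' filter beforehand.
#'
#' @param peptide Peptide string.
#' @param start_aa,end_aa 1-based inclusive span.
#' @return The substring.
#' @export
extract_nb_domain <- function(peptide, start_aa, end_aa) {
  if (is.na(start_aa) || is.na(end_aa)) {
    abort("NB-domain span is missing; gene must be excluded from phylogeny.")
  }
  if (start_aa < 1 || end_aa > nchar(peptide) || start_aa > end_aa) {
    abort("NB-domain span lies outside the peptide.")
  }
  substr(peptide, start_aa, end_aa)
}
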