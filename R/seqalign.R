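# local alignment screen: identity (%) = matches / alignment length,
# coverage (%) = aligned query residues / query length
align_screen <- function(query, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3),
    gapOpening = 5, gapExtension = 2)
  p <- as.character(Biostrings::alignedPattern(aln))
  aligned_q <- nchar(gsub("-", "", p))
  tibble(identity = Biostrings::pid(aln, type = "PID1"),
         coverage = 100 * aligned_q / nchar(query),
         score = Biostrings::score(aln))
}

# unique k-mers of a sequence (cheap screen before alignment)
kmer_set <- function(s, k = 12) {
  if (nchar(s) < k) return(character(0))
  unique(substring(s, seq_len(nchar(s) - k + 1),
                   seq_len(nchar(s) - k + 1) + k - 1))
}

# TRUE when the two sequences share at least one exact k-mer; either
# argument may be a precomputed kmer_set() (character vector of k-mers)
shares_kmer <- function(a, b, k = 12) {
  ka <- if (length(a) > 1) a else kmer_set(a, k)
  kb <- if (length(b) > 1) b else kmer_set(b, k)
  any(!is.na(match(kb, ka)))
}

#' EST support for gene expression
#'
#' A gene counts as expressed when at least one EST contig aligns to its
#' genic sequence with >= `min_identity` percent identity and >=
#' `min_coverage` percent coverage of the gene (the query).
#'
#' @param gene_seq Gene DNA sequence (character).
#' @param ests Named character vector or `DNAStringSet` of EST contigs.
#' @param min_identity,min_coverage Thresholds in percent (defaults 95
#'   and 90).
#' @return One-row tibble: `supported`, `hit_count`, `note`.
#' @export
est_support <- function(gene_seq, ests, min_identity = 95,
                        min_coverage = 90) {
  if (inherits(ests, "XStringSet")) ests <- setNames(as.character(ests),
                                                     names(ests))
  if (!length(ests)) {
    return(tibble(supported = FALSE, hit_count = 0L, note = "no data"))
  }
  est_kmers <- lapply(ests, kmer_set)
  kg <- kmer_set(gene_seq)
  hits <- 0L
  for (i in seq_along(ests)) {
    if (!shares_kmer(kg, est_kmers[[i]])) next
    sc <- align_screen(gene_seq, ests[[i]])
    if (sc$identity >= min_identity && sc$coverage >= min_coverage) {
      hits <- hits + 1L
    }
  }
  tibble(supported = hits > 0, hit_count = hits, note = NA_character_)
}

#' EST support for a table of genes
#'
#' @param genes Tibble with `gene` (or `id`) and `sequence` columns.
#' @inheritParams est_support
#' @return `genes` with `supported` and `hit_count` columns.
#' @export
est_support_table <- function(genes, ests, min_identity = 95,
                              min_coverage = 90) {
  if (!"gene" %in% names(genes)) genes$gene <- genes$id
  res <- lapply(genes$sequence, est_support, ests = ests,
                min_identity = min_identity, min_coverage = min_coverage)
  genes$supported <- vapply(res, function(x) x$supported, logical(1))
  genes$hit_count <- vapply(res, function(x) x$hit_count, integer(1))
  genes
}

best_hit <- function(seq, others) {
  best <- NULL
  for (nm in names(others)) {
    if (!shares_kmer(seq, others[[nm]])) next
    sc <- align_screen(seq, others[[nm]])
    if (is.null(best) || sc$score > best$score) {
      best <- sc
      best$id <- nm
    }
  }
  best
}

#' Call orthologs between two gene sets
#'
#' A query gene and its best subject-genome match are orthologs when the
#' match is reciprocal-best, passes > `min_identity` percent identity and
#' > `min_coverage` percent coverage, and each sequence is single-copy in
#' its own genome (a second within-genome sequence passing the same
#' thresholds makes the gene "paralogous"). `in_synteny` marks pairs whose
#' positions fall inside a listed synteny block.
#'
#' @param query,subject Tibbles with `gene`, `sequence` and position columns
#'   `chrom`, `pos`.
#' @param blocks Optional synteny-block tibble: `q_chrom`, `q_start`,
#'   `q_end`, `s_chrom`, `s_start`, `s_end`.
#' @param min_identity,min_coverage Ortholog thresholds in percent
#'   (defaults 90 and 95).
#' @return Tibble `gene`, `ortholog` (id or NA), `status` (`ortholog`,
#'   `paralogous`, `no_hit`, `not_reciprocal`, `below_threshold`),
#'   `in_synteny`.
#' @export
call_orthologs <- function(query, subject, blocks = NULL,
                           min_identity = 90, min_coverage = 95) {
  qs <- setNames(query$sequence, query$gene)
  ss <- setNames(subject$sequence, subject$gene)
  multi_copy <- function(seqs) {
    flags <- logical(length(seqs))
    names(flags) <- names(seqs)
    for (i in seq_along(seqs)) {
      for (j in seq_along(seqs)) {
        if (i == j || (flags[i] && flags[j])) next
        if (!shares_kmer(seqs[[i]], seqs[[j]])) next
        sc <- align_screen(seqs[[i]], seqs[[j]])
        if (sc$identity > min_identity && sc$coverage > min_coverage) {
          flags[i] <- TRUE
          flags[j] <- TRUE
        }
      }
    }
    flags
  }
  q_multi <- multi_copy(qs)
  s_multi <- multi_copy(ss)

  rows <- lapply(seq_len(nrow(query)), function(i) {
    g <- query$gene[i]
    rec <- tibble(gene = g, ortholog = NA_character_, status = "no_hit",
                  in_synteny = FALSE)
    hit <- best_hit(qs[[g]], ss)
    if (is.null(hit)) return(rec)
    sc <- align_screen(qs[[g]], ss[[hit$id]])
    if (!(sc$identity > min_identity && sc$coverage > min_coverage)) {
      rec$status <- "below_threshold"
      return(rec)
    }
    back <- best_hit(ss[[hit$id]], qs)
    if (is.null(back) || back$id != g) {
      rec$status <- "not_reciprocal"
      return(rec)
    }
    if (q_multi[g] || s_multi[hit$id]) {
      rec$status <- "paralogous"
      return(rec)
    }
    rec$ortholog <- hit$id
    rec$status <- "ortholog"
    if (!is.null(blocks) && nrow(blocks)) {
      qpos <- query[i, ]
      spos <- subject[subject$gene == hit$id, ]
      rec$in_synteny <- any(
        blocks$q_chrom == qpos$chrom & qpos$pos >= blocks$q_start &
          qpos$pos <= blocks$q_end &
          blocks$s_chrom == spos$chrom & spos$pos >= blocks$s_start &
          spos$pos <= blocks$s_end)
    }
    rec
  })
  bind_rows(rows)
}
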