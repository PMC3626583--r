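random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_seq <- function(s, rate, alphabet) {
  if (rate <= 0) return(s)
  x <- strsplit(s, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  x[hit] <- vapply(x[hit], function(ch) sample(setdiff(alphabet, ch), 1),
                   character(1))
  paste(x, collapse = "")
}

#' Simulate scaffold, peptide, EST and primer sequences
#'
#' Builds the sequence layer of a truth genome: random scaffold DNA, RGH
#' peptides whose ~120-aa NB domains carry one of two divergent clade motifs
#' (a CNL-like and a TNL-like clade, diverged ~40% with ~5% within-clade
#' variation), EST contigs copied from the genic DNA of expressed genes, and
#' one planted PCR amplicon per marker (duplicated onto a second scaffold for
#' designated multi-copy markers, by appending the amplicon to that
#' scaffold).
#'
#' @param truth A [simulate_truth()] object.
#' @param est_params List: `identity` (default 1) base identity of planted
#'   ESTs, `degraded` named per-gene identity overrides, `unexpressed`
#'   gene ids with no planted EST, `n_background` random contigs.
#' @param primer_params List: `product_bp` (default 200), `primer_bp`
#'   (default 20), `multi_copy_markers` marker ids whose amplicon is planted
#'   twice.
#' @param seed Integer seed.
#' @return List with `scaffolds`, `peptides`, `ests` (`Biostrings` string
#'   sets), `primers` and `annotations` tibbles, `amplicons_truth` (planted
#'   amplicon coordinates) and `nb_truth` (aligned NB domain peptides of
#'   complete-NB genes).
#' @export
simulate_sequences <- function(truth, est_params = list(),
                               primer_params = list(), seed = 1) {
  stopifnot(inherits(truth, "cucumap_truth"))
  ep <- utils::modifyList(list(identity = 1, degraded = NULL,
                               unexpressed = character(0), n_background = 3),
                          est_params)
  pp <- utils::modifyList(list(product_bp = 200, primer_bp = 20,
                               multi_copy_markers = character(0)),
                          primer_params)
  set.seed(child_seed(seed, "sequences"))

  sc <- truth$scaffolds
  seqs <- vapply(sc$length_bp, random_dna, character(1))
  names(seqs) <- sc$id

  # peptides: two clade motifs in the NB domain
  base_nb <- list(CNL = random_aa(120), TNL = random_aa(120))
  genes <- truth$rgh_genes
  peptides <- character(nrow(genes))
  nb_start <- integer(nrow(genes)); nb_end <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    nb <- mutate_seq(base_nb[[genes$clade_truth[i]]], 0.05, AA20)
    if (genes$complete_nb[i]) {
      peptides[i] <- paste0(random_aa(20), nb, random_aa(20))
      nb_start[i] <- 21L; nb_end[i] <- 140L
    } else {
      peptides[i] <- paste0(random_aa(20), substr(nb, 1, 60))
      nb_start[i] <- NA_integer_; nb_end[i] <- NA_integer_
    }
  }
  names(peptides) <- genes$id

  # ESTs copied from genic DNA
  gene_dna <- vapply(seq_len(nrow(genes)), function(i) {
    substr(seqs[[genes$scaffold_id[i]]], genes$start_bp[i], genes$end_bp[i])
  }, character(1))
  names(gene_dna) <- genes$id
  ests <- character(0)
  for (g in genes$id) {
    if (g %in% ep$unexpressed) next
    ident <- ep$degraded[g] %||% ep$identity
    if (is.na(ident)) ident <- ep$identity
    ests[paste0("EST_", g)] <- mutate_seq(gene_dna[[g]], 1 - ident,
                                          c("A", "C", "G", "T"))
  }
  if (ep$n_background > 0) {
    bg <- vapply(rep(500, ep$n_background), random_dna, character(1))
    names(bg) <- sprintf("EST_bg%02d", seq_along(bg))
    ests <- c(ests, bg)
  }

  # primers: one planted amplicon per marker
  mk <- truth$markers
  sc_len <- setNames(sc$length_bp, sc$id)
  amp_start <- pmin(pmax(mk$scaffold_offset_bp, 1L),
                    sc_len[mk$scaffold_id] - pp$product_bp + 1L)
  amp_end <- amp_start + pp$product_bp - 1L
  fwd <- rev <- character(nrow(mk))
  for (i in seq_len(nrow(mk))) {
    s <- seqs[[mk$scaffold_id[i]]]
    fwd[i] <- substr(s, amp_start[i], amp_start[i] + pp$primer_bp - 1)
    rev[i] <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(s, amp_end[i] - pp$primer_bp + 1, amp_end[i]))))
  }
  amplicons <- tibble(marker = mk$id, scaffold_id = mk$scaffold_id,
                      start_bp = as.integer(amp_start),
                      end_bp = as.integer(amp_end), copy = 1L)
  for (m in pp$multi_copy_markers) {
    i <- match(m, mk$id)
    if (is.na(i)) abort(paste0("unknown multi-copy marker: ", m))
    # append the amplicon to a marker scaffold on another chromosome
    others <- sc$id[sc$role == "marker" & sc$chromosome != mk$chromosome[i]]
    tgt <- others[1 + (i %% length(others))]
    frag <- substr(seqs[[mk$scaffold_id[i]]], amp_start[i], amp_end[i])
    amplicons <- bind_rows(amplicons, tibble(
      marker = m, scaffold_id = tgt,
      start_bp = nchar(seqs[[tgt]]) + 1L,
      end_bp = nchar(seqs[[tgt]]) + pp$product_bp,
      copy = 2L))
    seqs[[tgt]] <- paste0(seqs[[tgt]], frag)
  }

  annotations <- tibble(
    gene = genes$id, scaffold = genes$scaffold_id,
    start = genes$start_bp, end = genes$end_bp,
    domains = genes$domains, nb_start = nb_start, nb_end = nb_end
  )

  list(
    scaffolds = Biostrings::DNAStringSet(seqs),
    peptides = Biostrings::AAStringSet(peptides),
    ests = Biostrings::DNAStringSet(ests),
    primers = tibble(marker = mk$id, fwd_seq = fwd, rev_seq = rev),
    annotations = annotations,
    amplicons_truth = amplicons,
    nb_truth = Biostrings::AAStringSet(
      setNames(substr(peptides, nb_start, nb_end), genes$id)[genes$complete_nb]
    )
  )
}

#' Write a fixture bundle to disk
#'
#' Serialises a truth genome, genotype matrices and sequence layer to plain
#' text files (TSV / FASTA) and returns a manifest of the written files.
#'
#' @param truth A [simulate_truth()] object.
#' @param matrices Named list of genotype tables.
#' @param sequences A [simulate_sequences()] list.
#' @param out_dir Output directory (created if absent).
#' @return Tibble manifest (`file`, `md5`, `bytes`) with attributes `seed`
#'   and `config_hash`.
#' @export
write_fixture_bundle <- function(truth, matrices, sequences, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  wt <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
  wt(truth$chromosomes, "truth_chromosomes.tsv")
  wt(truth$markers, "truth_markers.tsv")
  wt(truth$scaffolds |> select(-"cluster"), "truth_scaffolds.tsv")
  wt(truth$rgh_genes, "truth_rgh_genes.tsv")
  wt(truth$suppression_regions, "truth_suppression.tsv")
  for (nm in names(matrices)) {
    write_geno(matrices[[nm]], file.path(out_dir, paste0("geno_", nm, ".tsv")))
  }
  Biostrings::writeXStringSet(sequences$scaffolds,
                              file.path(out_dir, "scaffolds.fasta"))
  Biostrings::writeXStringSet(sequences$peptides,
                              file.path(out_dir, "peptides.fasta"))
  Biostrings::writeXStringSet(sequences$ests, file.path(out_dir, "ests.fasta"))
  wt(sequences$primers, "primers.tsv")
  wt(sequences$annotations, "annotations.tsv")

  files <- sort(list.files(out_dir))
  paths <- file.path(out_dir, files)
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(paths)),
                     bytes = file.size(paths))
  attr(manifest, "seed") <- truth$config$seed
  attr(manifest, "config_hash") <- rlang::hash(truth$config)
  manifest
}
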