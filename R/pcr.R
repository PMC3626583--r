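#' In silico PCR
#'
#' Scans template scaffolds on both strands for primer-pair binding sites
#' facing each other within `max_product` bp. An amplicon runs from the
#' forward primer's 5' end to the reverse primer's 5' end (1-based
#' inclusive). Each marker is labelled `"unique"` (one product genome-wide),
#' `"no hit"` (none) or `"multi-copy"` (two or more).
#'
#' @param primers Tibble `marker`, `fwd_seq`, `rev_seq` (see
#'   [read_primers()]).
#' @param scaffolds Named character vector or `DNAStringSet` of templates.
#' @param max_product Maximum product length in bp (default 2000).
#' @param max_mismatch Allowed mismatches per primer site (default 0).
#' @return List with `amplicons` (tibble `marker`, `scaffold_id`,
#'   `start_bp`, `end_bp`, `product_length`, `strand`) and `labels` (tibble
#'   `marker`, `n_products`, `label`).
#' @export
insilico_pcr <- function(primers, scaffolds, max_product = 2000,
                         max_mismatch = 0) {
  if (!inherits(scaffolds, "DNAStringSet")) {
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  }
  if (is.null(names(scaffolds))) abort("scaffolds must be named.")
  check_primer <- function(p) {
    if (nchar(p) < 15) abort("primers must be at least 15 nt long.")
    if (grepl("[^ACGTRYSWKMBDHVN]", p)) {
      abort(paste0("primer contains non-IUPAC characters: ", p))
    }
  }
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  site_starts <- function(p) {
    m <- Biostrings::vmatchPattern(p, scaffolds, max.mismatch = max_mismatch,
                                   fixed = FALSE)
    lapply(setNames(seq_along(scaffolds), names(scaffolds)), function(k) {
      m[[k]]
    })
  }
  amp <- list()
  for (i in seq_len(nrow(primers))) {
    fwd <- toupper(primers$fwd_seq[i])
    rev <- toupper(primers$rev_seq[i])
    check_primer(fwd)
    check_primer(rev)
    pair_up <- function(left, right, strand) {
      # left: 5' primer sites on the plus strand; right: 5'-facing sites
      # of the complementary primer (its reverse complement on plus)
      lm <- site_starts(left)
      rm <- site_starts(rc(right))
      rows <- lapply(names(scaffolds), function(sid) {
        ls <- Biostrings::start(lm[[sid]])
        rs <- Biostrings::end(rm[[sid]])
        if (!length(ls) || !length(rs)) return(NULL)
        grid <- expand.grid(s = ls, e = rs)
        grid <- grid[grid$e > grid$s &
                       grid$e - grid$s + 1 >= nchar(left) + nchar(right) &
                       grid$e - grid$s + 1 <= max_product, , drop = FALSE]
        if (!nrow(grid)) return(NULL)
        tibble(marker = primers$marker[i], scaffold_id = sid,
               start_bp = grid$s, end_bp = grid$e,
               product_length = grid$e - grid$s + 1, strand = strand)
      })
      bind_rows(rows)
    }
    amp[[length(amp) + 1]] <- pair_up(fwd, rev, "+")
    amp[[length(amp) + 1]] <- pair_up(rev, fwd, "-")
  }
  amplicons <- bind_rows(amp)
  if (!nrow(amplicons)) {
    amplicons <- tibble(marker = character(), scaffold_id = character(),
                        start_bp = integer(), end_bp = integer(),
                        product_length = integer(), strand = character())
  }
  amplicons <- distinct(amplicons)
  n_prod <- table(factor(amplicons$marker, levels = primers$marker))
  np <- unname(as.integer(n_prod[primers$marker]))
  labels <- tibble(
    marker = primers$marker,
    n_products = np,
    label = ifelse(np == 0, "no hit", ifelse(np == 1, "unique", "multi-copy"))
  )
  list(amplicons = amplicons, labels = labels)
}

#' Anchor scaffolds onto a consensus map
#'
#' Each scaffold is assigned the majority linkage group of its uniquely
#' amplified, mapped markers; a tied majority leaves the scaffold unanchored
#' with a warning. Coverage is 100 x anchored_bp / genome_bp.
#'
#' @param consensus Map tibble `marker`, `lg`, `cM`.
#' @param assignments Tibble `marker`, `scaffold_id` of uniquely assigned
#'   markers (for example the `"unique"`-labelled [insilico_pcr()]
#'   amplicons).
#' @param scaffold_lengths Tibble `scaffold_id`, `length_bp`.
#' @param genome_bp Genome size used for the coverage denominator (default:
#'   the sum of scaffold lengths).
#' @return An `cucumap_anchors` tibble (`scaffold_id`, `lg`, `anchored`,
#'   `n_markers`, `length_bp`) with attribute `totals` (one-row tibble:
#'   `n_scaffolds_anchored`, `anchored_bp`, `genome_bp`,
#'   `coverage_percent`).
#' @export
anchor_scaffolds <- function(consensus, assignments, scaffold_lengths,
                             genome_bp = sum(scaffold_lengths$length_bp)) {
  lg_of <- setNames(consensus$lg, consensus$marker)
  assignments <- assignments[assignments$marker %in% names(lg_of), ]
  rows <- lapply(split(assignments, assignments$scaffold_id), function(a) {
    tab <- sort(table(lg_of[a$marker]), decreasing = TRUE)
    tied <- length(tab) > 1 && tab[1] == tab[2]
    if (tied) {
      warn(paste0("scaffold ", a$scaffold_id[1],
                  " has a tied linkage-group majority; left unanchored."))
    }
    tibble(scaffold_id = a$scaffold_id[1],
           lg = if (tied) NA_character_ else names(tab)[1],
           anchored = !tied, n_markers = nrow(a))
  })
  anchored <- bind_rows(rows)
  if (!nrow(anchored)) {
    anchored <- tibble(scaffold_id = character(), lg = character(),
                       anchored = logical(), n_markers = integer())
  }
  out <- scaffold_lengths |>
    left_join(anchored, by = "scaffold_id") |>
    mutate(anchored = !is.na(.data$anchored) & .data$anchored,
           n_markers = ifelse(is.na(.data$n_markers), 0L, .data$n_markers))
  totals <- tibble(
    n_scaffolds_anchored = sum(out$anchored),
    anchored_bp = sum(out$length_bp[out$anchored]),
    genome_bp = genome_bp,
    coverage_percent = 100 * sum(out$length_bp[out$anchored]) / genome_bp
  )
  structure(out, totals = totals,
            class = c("cucumap_anchors", class(out)))
}

#' Genetic-physical colinearity per linkage group
#'
#' Spearman rank correlation between marker genetic positions (cM) and
#' their physical order: anchored scaffolds ordered along the linkage group
#' by their markers' median cM, markers within a scaffold by bp, with
#' scaffold orientation inferred from the sign of the within-scaffold
#' cM-vs-bp trend (reversed scaffolds are flipped and flagged).
#'
#' @param consensus Map tibble `marker`, `lg`, `cM`.
#' @param positions Tibble `marker`, `scaffold_id`, `start_bp` (physical
#'   marker positions, e.g. unique amplicons).
#' @return Tibble `lg`, `n_markers`, `spearman_r`, `n_scaffolds_reversed`.
#' @export
colinearity_check <- function(consensus, positions) {
  d <- consensus |>
    left_join(positions, by = "marker") |>
    filter(!is.na(.data$scaffold_id))
  rows <- lapply(split(d, d$lg), function(sub) {
    if (nrow(sub) < 2) {
      return(tibble(lg = sub$lg[1], n_markers = nrow(sub),
                    spearman_r = NA_real_, n_scaffolds_reversed = 0L))
    }
    n_rev <- 0L
    per_scaf <- lapply(split(sub, sub$scaffold_id), function(s) {
      orient <- 1
      if (nrow(s) > 1) {
        tr <- suppressWarnings(cor(s$cM, s$start_bp, method = "spearman"))
        if (!is.na(tr) && tr < 0) {
          orient <- -1
          n_rev <<- n_rev + 1L
        }
      }
      s$phys <- orient * s$start_bp
      s$scaf_cM <- stats::median(s$cM)
      s
    })
    sub2 <- bind_rows(per_scaf)
    phys_rank <- rank(order(order(sub2$scaf_cM, sub2$phys)))
    tibble(lg = sub$lg[1], n_markers = nrow(sub2),
           spearman_r = suppressWarnings(
             cor(rank(sub2$cM), phys_rank, method = "spearman")),
           n_scaffolds_reversed = n_rev)
  })
  bind_rows(rows)
}
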