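test_that("in silico PCR recovers planted amplicons with exact coordinates", {
  tr <- small_truth(seed = 27)
  sq <- simulate_sequences(tr, primer_params = list(
    multi_copy_markers = "SSR02003"), seed = 28)
  pcr <- insilico_pcr(sq$primers, sq$scaffolds)
  tru <- sq$amplicons_truth
  uniq <- setdiff(tru$marker, "SSR02003")
  for (m in uniq) {
    a <- pcr$amplicons[pcr$amplicons$marker == m, ]
    t1 <- tru[tru$marker == m & tru$copy == 1, ]
    expect_equal(nrow(a), 1)
    expect_equal(a$start_bp, t1$start_bp)
    expect_equal(a$end_bp, t1$end_bp)
    expect_equal(a$scaffold_id, t1$scaffold_id)
  }
  expect_true(all(pcr$labels$label[pcr$labels$marker %in% uniq] == "unique"))
  expect_equal(pcr$labels$label[pcr$labels$marker == "SSR02003"],
               "multi-copy")
})

test_that("primers facing away from each other give no product", {
  scaf <- c(s1 = paste(rep("ACGT", 250), collapse = ""))
  tmpl <- paste0(strrep("A", 100), "GATTACAGATTACAGATTA",
                 strrep("C", 200), "TTGGCCAATTGGCCAATTG", strrep("G", 100))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- "GATTACAGATTACAGATTA"
  rev <- "TTGGCCAATTGGCCAATTG" # facing away: rev given as plus-strand seq
  pr_away <- tibble::tibble(marker = "m1", fwd_seq = fwd, rev_seq = rev)
  out <- insilico_pcr(pr_away, c(s1 = tmpl))
  expect_equal(out$labels$label, "no hit")
  # the correctly facing pair amplifies
  pr_ok <- tibble::tibble(marker = "m1", fwd_seq = fwd, rev_seq = rc(rev))
  out2 <- insilico_pcr(pr_ok, c(s1 = tmpl))
  expect_equal(out2$labels$label, "unique")
})

test_that("no false amplicons arise on random sequence at zero mismatches", {
  set.seed(61)
  for (i in 1:100) {
    scaf <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
    amp_start <- sample(500:3000, 1)
    fwd <- substr(scaf, amp_start, amp_start + 19)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(scaf, amp_start + 180, amp_start + 199))))
    out <- insilico_pcr(tibble::tibble(marker = "m", fwd_seq = fwd,
                                       rev_seq = rev), c(s = scaf))
    expect_equal(out$labels$n_products, 1L)
    expect_equal(out$amplicons$start_bp, amp_start)
    expect_equal(out$amplicons$end_bp, amp_start + 199)
  }
})

test_that("primer validation rejects short and non-IUPAC input", {
  expect_error(insilico_pcr(tibble::tibble(marker = "m", fwd_seq = "ACGT",
                                           rev_seq = strrep("A", 20)),
                            c(s = strrep("A", 100))), "15")
  expect_error(insilico_pcr(tibble::tibble(marker = "m",
                                           fwd_seq = strrep("Q", 20),
                                           rev_seq = strrep("A", 20)),
                            c(s = strrep("A", 100))), "IUPAC")
})

test_that("scaffold anchoring uses marker majorities and reports coverage", {
  cons <- tibble::tibble(marker = c("m1", "m2", "m3", "m4"),
                         lg = c("LG1", "LG1", "LG2", "LG2"), cM = 1:4)
  asg <- tibble::tibble(marker = c("m1", "m2", "m3", "m4"),
                        scaffold_id = c("s1", "s1", "s1", "s2"))
  lens <- tibble::tibble(scaffold_id = c("s1", "s2", "s3"),
                         length_bp = c(1000, 2000, 3000))
  a <- anchor_scaffolds(cons, asg, lens, genome_bp = 6000)
  expect_equal(a$lg[a$scaffold_id == "s1"], "LG1") # 2 vs 1 majority
  expect_equal(a$lg[a$scaffold_id == "s2"], "LG2")
  expect_false(a$anchored[a$scaffold_id == "s3"])
  tot <- glance(a)
  expect_equal(tot$anchored_bp, 3000)
  expect_equal(tot$coverage_percent, 50)
  # a tied majority warns and unanchors
  asg2 <- tibble::tibble(marker = c("m1", "m3"), scaffold_id = "s1")
  expect_warning(a2 <- anchor_scaffolds(cons, asg2, lens), "tied")
  expect_false(a2$anchored[a2$scaffold_id == "s1"])
  # no assigned markers: zero coverage
  a3 <- anchor_scaffolds(cons, asg2[0, ], lens)
  expect_equal(glance(a3)$coverage_percent, 0)
})

test_that("anchoring coverage is monotone as scaffolds are added", {
  cons <- tibble::tibble(marker = sprintf("m%d", 1:6),
                         lg = rep("LG1", 6), cM = 1:6)
  lens <- tibble::tibble(scaffold_id = sprintf("s%d", 1:3),
                         length_bp = c(100, 200, 300))
  cov <- numeric(3)
  for (k in 1:3) {
    asg <- tibble::tibble(marker = sprintf("m%d", 1:k),
                          scaffold_id = sprintf("s%d", 1:k))
    cov[k] <- glance(anchor_scaffolds(cons, asg, lens,
                                      genome_bp = 600))$coverage_percent
  }
  expect_true(all(diff(cov) >= 0))
  expect_true(all(cov >= 0 & cov <= 100))
})

test_that("colinearity statistics match constructed rank arithmetic", {
  # perfectly colinear single scaffold
  cons <- tibble::tibble(marker = sprintf("m%02d", 1:10), lg = "LG1",
                         cM = seq(0, 45, by = 5))
  pos <- tibble::tibble(marker = cons$marker, scaffold_id = "s1",
                        start_bp = seq(1000, 10000, by = 1000))
  expect_equal(colinearity_check(cons, pos)$spearman_r, 1)
  # one adjacent swap among 10: r = 1 - 6*2/990
  pos2 <- pos
  pos2$start_bp[5:6] <- pos2$start_bp[6:5]
  expect_equal(colinearity_check(cons, pos2)$spearman_r, 1 - 12 / 990,
               tolerance = 1e-10)
  # a physically reversed scaffold is flipped and flagged
  pos3 <- pos
  pos3$start_bp <- rev(pos3$start_bp)
  out <- colinearity_check(cons, pos3)
  expect_equal(abs(out$spearman_r), 1)
  expect_equal(out$n_scaffolds_reversed, 1L)
  # fewer than two positioned markers is undefined
  out2 <- colinearity_check(cons[1, ], pos[1, ])
  expect_true(is.na(out2$spearman_r))
})

test_that("an error-free simulated fixture is perfectly colinear", {
  tr <- small_truth(seed = 29)
  sq <- simulate_sequences(tr, seed = 30)
  pcr <- insilico_pcr(sq$primers, sq$scaffolds)
  uniq <- pcr$amplicons[pcr$amplicons$marker %in%
                          pcr$labels$marker[pcr$labels$label == "unique"], ]
  truth_map <- tr$markers[, c("id", "chromosome", "true_cM")] |>
    dplyr::rename(marker = "id", lg = "chromosome", cM = "true_cM")
  col <- colinearity_check(truth_map, uniq)
  expect_equal(col$spearman_r, rep(1, nrow(col)))
})
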