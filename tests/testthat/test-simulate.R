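test_that("truth generation is deterministic and well-ordered", {
  t1 <- small_truth(seed = 7)
  t2 <- small_truth(seed = 7)
  expect_identical(rlang::hash(t1), rlang::hash(t2))
  for (chr in unique(t1$markers$chromosome)) {
    cM <- t1$markers$true_cM[t1$markers$chromosome == chr]
    expect_true(all(diff(cM) >= 0))
    expect_true(all(cM >= 0 & cM <= 100))
  }
  # scaffolds non-overlapping per chromosome
  for (chr in unique(t1$scaffolds$chromosome)) {
    s <- t1$scaffolds[t1$scaffolds$chromosome == chr, ]
    s <- s[order(s$start_bp), ]
    expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
  }
  # genes inside their scaffolds
  j <- match(t1$rgh_genes$scaffold_id, t1$scaffolds$id)
  expect_true(all(t1$rgh_genes$end_bp <= t1$scaffolds$length_bp[j]))
  expect_true(all(t1$rgh_genes$start_bp >= 1))
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_truth_config(n_chr = 0), "n_chr")
  expect_error(sim_truth_config(rgh_cluster_sizes = c(1, 3),
                                rgh_cluster_span_kb = c(1, 2),
                                rgh_cluster_chr = c(1, 1)),
               "rgh_cluster_sizes")
  expect_error(cross_design("F2", 1), "n_individuals")
  expect_error(cross_design("F2", 10, missing_rate = 1.2), "rates")
})

test_that("planted clusters are recovered exactly by the detector", {
  tr <- simulate_truth(sim_truth_config(seed = 3))
  cl <- detect_clusters(tr$rgh_genes)
  expect_equal(length(unique(cl$cluster)), 9)
  expect_equal(nrow(cl), 52)
  # membership matches the planted cluster sizes
  sizes <- sort(as.integer(table(cl$cluster)))
  expect_equal(sizes, sort(c(2, 11, 3, 4, 2, 7, 5, 12, 6)))
})

test_that("coincident markers show zero observed recombination", {
  tr <- small_truth(markers_per_chr = 2)
  tr$markers$true_cM <- c(50, 50, 20, 80)
  pop <- simulate_population(tr, cross_design("F2", 60, seed = 2))
  rf <- pairwise_rf(pop)
  same <- rf[rf$marker_a == "SSR01001" & rf$marker_b == "SSR01002", ]
  expect_equal(same$r_hat, 0)
})

test_that("markers on different chromosomes are unlinked", {
  tr <- small_truth(markers_per_chr = 1)
  pop <- simulate_population(tr, cross_design("F2", 2000, seed = 4))
  rf <- pairwise_rf(pop)
  # binomial oracle: 3 s.e. of 0.5 at 2n gametes
  se <- sqrt(0.25 / (2 * 2000))
  expect_lt(abs(rf$r_hat - 0.5), 3 * se + 1e-9)
})

test_that("F2 EM recovers the simulated meiotic r within 3 s.e.", {
  tr <- small_truth(markers_per_chr = 2)
  tr$markers$true_cM <- c(40, 50, 40, 50) # 10 cM spacing
  r_true <- cm_to_rf(10, "haldane") # the simulator draws Poisson crossovers
  pop <- simulate_population(tr, cross_design("F2", 5000, seed = 8))
  rf <- pairwise_rf(pop)
  est <- rf$r_hat[rf$marker_a == "SSR01001" & rf$marker_b == "SSR01002"]
  se <- sqrt(r_true * (1 - r_true) / (2 * 5000))
  expect_lt(abs(est - r_true), 3 * se)
})

test_that("expected crossover count per gamete tracks map length", {
  tr <- small_truth(markers_per_chr = 20)
  set.seed(1)
  n_gam <- 1200
  # recombination events between chromosome ends approximate length/100
  counts <- replicate(n_gam, {
    g <- cucumap:::meiosis_gamete(rep(0L, 2), rep(1L, 2), c(0, 100), 100,
                                  tibble::tibble(chromosome = character(),
                                                 start_cM = numeric(),
                                                 end_cM = numeric(),
                                                 multiplier = numeric()))
    g[1] != g[2]
  })
  # P(recombinant across 100 cM) = Haldane r for d = 100
  p <- cm_to_rf(100, "haldane")
  expect_lt(abs(mean(counts) - p), 3 * sqrt(p * (1 - p) / n_gam))
})

test_that("full suppression forces zero recombination between flanking markers", {
  sup <- tibble::tibble(chromosome = "chr1", start_cM = 0, end_cM = 100,
                        multiplier = 0)
  tr <- small_truth(markers_per_chr = 5, suppression_regions = sup)
  pop <- simulate_population(tr, cross_design("F2", 200, seed = 3))
  rf <- pairwise_rf(pop)
  chr1 <- grepl("^SSR01", rf$marker_a) & grepl("^SSR01", rf$marker_b)
  expect_true(all(rf$r_hat[chr1] == 0))
  chr2 <- grepl("^SSR02", rf$marker_a) & grepl("^SSR02", rf$marker_b)
  expect_true(any(rf$r_hat[chr2] > 0))
})

test_that("RIL populations are fully homozygous at the fixation limit", {
  tr <- small_truth()
  pop <- simulate_population(tr, cross_design("RIL", 50, seed = 9))
  expect_true(all(as.matrix(pop[, -1]) %in% c("A", "B")))
  # finite-generation selfing reaches near-fixation with H reported missing
  pop8 <- simulate_population(tr, cross_design("RIL", 50,
                                               selfing_generations = 8,
                                               seed = 9))
  calls <- as.matrix(pop8[, -1])
  expect_true(all(calls %in% c("A", "B", "-")))
  expect_lt(mean(calls == "-"), 0.03)
})

test_that("error and missing rates are applied at the configured levels", {
  tr <- small_truth(markers_per_chr = 20)
  pop <- simulate_population(tr, cross_design("F2", 300, seed = 10,
                                              missing_rate = 0.1))
  miss <- mean(as.matrix(pop[, -1]) == "-")
  expect_lt(abs(miss - 0.1), 0.01)
})

test_that("sequence layer plants ESTs, primers and clade motifs as configured", {
  tr <- small_truth()
  sq <- simulate_sequences(
    tr,
    est_params = list(unexpressed = "RGH001",
                      degraded = c(RGH002 = 0.90)),
    primer_params = list(multi_copy_markers = "SSR01001"), seed = 2)
  expect_false(any(names(sq$ests) == "EST_RGH001"))
  # planted exact EST supports its gene; 90%-identity EST fails the screen
  g3 <- tr$rgh_genes[tr$rgh_genes$id == "RGH003", ]
  dna3 <- substr(as.character(sq$scaffolds[[g3$scaffold_id]]),
                 g3$start_bp, g3$end_bp)
  expect_true(est_support(dna3, sq$ests)$supported)
  g2 <- tr$rgh_genes[tr$rgh_genes$id == "RGH002", ]
  dna2 <- substr(as.character(sq$scaffolds[[g2$scaffold_id]]),
                 g2$start_bp, g2$end_bp)
  expect_false(est_support(dna2, sq$ests)$supported)
  # multi-copy marker has two planted amplicons
  expect_equal(sum(sq$amplicons_truth$marker == "SSR01001"), 2)
})

test_that("fixture bundles round-trip and hash identically for a fixed seed", {
  tr <- small_truth(seed = 11)
  pop <- simulate_population(tr, cross_design("F2", 20, seed = 1))
  sq <- simulate_sequences(tr, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(tr, list(f2 = pop), sq, d1)
  m2 <- write_fixture_bundle(tr, list(f2 = pop), sq, d2)
  expect_gte(nrow(m1), 6)
  expect_identical(m1$md5, m2$md5)
  expect_identical(attr(m1, "config_hash"), attr(m2, "config_hash"))
  # round-trip
  g <- read_geno(file.path(d1, "geno_f2.tsv"), "F2")
  expect_equal(tibble::as_tibble(g), tibble::as_tibble(pop),
               ignore_attr = TRUE)
  sc <- Biostrings::readDNAStringSet(file.path(d1, "scaffolds.fasta"))
  expect_equal(as.character(sc), as.character(sq$scaffolds))
  ann <- read_annotations(file.path(d1, "annotations.tsv"))
  expect_equal(ann$gene, sq$annotations$gene)
  pr <- read_primers(file.path(d1, "primers.tsv"))
  expect_equal(pr$fwd_seq, sq$primers$fwd_seq)
})
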