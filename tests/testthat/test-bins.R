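# O(n^2) interval-cover oracle for the greedy bin scan
brute_force_bins <- function(cM, width = 1) {
  cM <- sort(cM)
  bins <- integer(length(cM))
  b <- 0L
  i <- 1
  while (i <= length(cM)) {
    b <- b + 1L
    members <- which(cM >= cM[i] & cM <= cM[i] + width)
    members <- members[members >= i]
    bins[members] <- b
    i <- max(members) + 1
  }
  bins
}

test_that("bins follow the 1-cM anchored scan", {
  m <- tibble::tibble(marker = letters[1:4], lg = "LG1",
                      cM = c(0, 0.4, 0.9, 2))
  b <- build_bins(m)
  expect_equal(length(unique(b$bin)), 2)
  expect_equal(b$bin[1:3], rep(b$bin[1], 3))
  expect_equal(b$start_cM[b$marker == "d"], 2)
  # coincident loci fall in a single bin
  m2 <- tibble::tibble(marker = letters[1:5], lg = "LG1", cM = rep(3.2, 5))
  expect_equal(length(unique(build_bins(m2)$bin)), 1)
})

test_that("bin widths never exceed 1 cM and bins partition the map", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    m <- tibble::tibble(marker = sprintf("m%03d", 1:n), lg = "LG1",
                        cM = sort(runif(n, 0, 30)))
    b <- build_bins(m)
    expect_equal(sort(b$marker), sort(m$marker))
    expect_true(all(b$end_cM - b$start_cM <= 1 + 1e-9))
    oracle <- brute_force_bins(m$cM)
    got <- as.integer(factor(b$bin, levels = unique(b$bin)))
    expect_equal(got, oracle)
  }
})

test_that("representative selection prefers bridges then completeness", {
  m <- tibble::tibble(marker = c("shared1", "priv1", "priv2"), lg = "LG1",
                      cM = c(0, 0.2, 5))
  b <- build_bins(m, map_name = "A")
  sh <- tibble::tibble(marker = "shared1", n_shared = 2L)
  out <- select_representatives(b, sh)
  expect_true(out$is_representative[out$marker == "shared1"])
  expect_false(out$is_representative[out$marker == "priv1"])
  # with no shared marker, the lowest-missing marker wins
  sh0 <- tibble::tibble(marker = character(), n_shared = integer())
  mc <- tibble::tibble(marker = c("shared1", "priv1", "priv2"),
                       n_missing = c(5L, 1L, 0L))
  out2 <- select_representatives(b, sh0, mc)
  expect_true(out2$is_representative[out2$marker == "priv1"])
  expect_true(out2$is_representative[out2$marker == "priv2"])
})

test_that("exclusion regions suppress representatives with a warning", {
  m <- tibble::tibble(marker = c("a", "b"), lg = "LG1", cM = c(0, 0.5))
  b <- build_bins(m, map_name = "A")
  ex <- tibble::tibble(map = "A", lg = "LG1", start_cM = 0, end_cM = 1)
  expect_warning(out <- select_representatives(
    b, tibble::tibble(marker = character(), n_shared = integer()),
    exclusions = ex), "excluded")
  expect_false(any(out$is_representative))
})

test_that("chromosome conflicts resolve by scaffold, then vote, then reference", {
  asg <- tibble::tibble(
    map = rep(c("A", "B", "C"), each = 3),
    marker = rep(c("m1", "m2", "m3"), 3),
    lg = c("LG2", "LG1", "LG1",   # map A (m1 misplaced on LG2... truth LG2)
           "LG5", "LG1", "LG2",
           "LG2", "LG1", "LG1"),
    cM = 0)
  # m1: scaffold sc1 whose mates all map to LG2 -> rule 1
  ms <- tibble::tibble(marker = c("m1", "x1", "x2", "x3"),
                       scaffold = "sc1")
  asg2 <- dplyr::bind_rows(asg, tibble::tibble(
    map = "A", marker = c("x1", "x2", "x3"), lg = "LG2", cM = 1))
  out <- resolve_chromosome_conflicts(asg2, ms, reference_map = "A")
  expect_equal(out$resolution[out$marker == "m1"], "LG2")
  expect_equal(out$rule_applied[out$marker == "m1"], "scaffold_majority")
  # m2: identical everywhere -> unanimous
  expect_equal(out$rule_applied[out$marker == "m2"], "unanimous")
  # m3: no scaffold, majority LG1 -> map_majority
  expect_equal(out$resolution[out$marker == "m3"], "LG1")
  expect_equal(out$rule_applied[out$marker == "m3"], "map_majority")
  # full tie falls to the reference map
  tie <- tibble::tibble(map = c("A", "B"), marker = "t1",
                        lg = c("LG1", "LG2"), cM = 0)
  out2 <- resolve_chromosome_conflicts(tie, reference_map = "B")
  expect_equal(out2$resolution, "LG2")
  expect_equal(out2$rule_applied, "reference_map")
  # unresolvable: no scaffold, tie, no reference
  out3 <- resolve_chromosome_conflicts(tie)
  expect_true(is.na(out3$resolution))
  expect_equal(out3$rule_applied, "dropped")
})

test_that("LOD-weighted pooling follows the weighted-mean arithmetic", {
  t1 <- tibble::tibble(marker_a = "a", marker_b = "b", r_hat = 0.1, lod = 10)
  t2 <- tibble::tibble(marker_a = "a", marker_b = "b", r_hat = 0.2, lod = 5)
  pooled <- cucumap:::pool_rf(list(p1 = t1, p2 = t2), c("a", "b"))
  expect_equal(pooled$r_hat, 2 / 15)
  expect_equal(pooled$lod, 15)
  # pooling identical estimates is a fixed point
  pooled2 <- cucumap:::pool_rf(list(p1 = t1, p2 = t1), c("a", "b"))
  expect_equal(pooled2$r_hat, 0.1)
})

test_that("integrating a map with itself reproduces its representative order", {
  tr <- small_truth(markers_per_chr = 12, seed = 81)
  pop <- simulate_population(tr, cross_design("F2", 150, seed = 82))
  cm <- align_linkage_groups(build_component_map(pop, name = "A"),
                             attr(pop, "truth_map"))
  cons <- integrate_maps(list(A = cm, B = cm),
                         geno = list(A = pop, B = pop))
  skel <- attr(cons, "skeleton")
  for (lg in unique(skel$lg)) {
    mine <- skel$marker[skel$lg == lg]
    ref <- cm$marker[cm$lg == lg]
    ref <- ref[ref %in% mine]
    expect_true(identical(mine, ref) || identical(mine, rev(ref)))
  }
  # every marker appears exactly once in the consensus
  expect_equal(anyDuplicated(cons$marker), 0)
  expect_equal(sort(cons$marker), sort(cm$marker))
})

test_that("residual refill preserves bin offsets and monotonicity", {
  skel <- structure(
    tibble::tibble(marker = c("r1", "r2"), lg = "LG1", cM = c(0, 10)),
    map_function = "kosambi")
  bins <- tibble::tibble(
    map = "A", lg = "LG1",
    bin = c("LG1:1", "LG1:1", "LG1:2"),
    start_cM = c(2, 2, 12), end_cM = c(2.3, 2.3, 12),
    marker = c("r1", "q1", "r2"), cM = c(2, 2.3, 12),
    is_representative = c(TRUE, FALSE, TRUE))
  cons <- refill_residuals(skel, bins)
  q <- cons[cons$marker == "q1", ]
  expect_equal(q$cM, 0.3) # 0 + (2.3 - 2.0)
  expect_false(q$is_skeleton)
  expect_true(all(diff(cons$cM[cons$lg == "LG1"]) >= 0))
})

test_that("residual positions stay within their bin's consensus span", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(8:25, 1)
    cm <- tibble::tibble(marker = sprintf("m%02d", 1:n), lg = "LG1",
                         cM = sort(runif(n, 0, 20)))
    b <- build_bins(cm, map_name = "A")
    b <- select_representatives(
      b, tibble::tibble(marker = character(), n_shared = integer()))
    skel <- structure(
      tibble::tibble(marker = b$marker[b$is_representative], lg = "LG1",
                     cM = b$cM[b$is_representative] -
                       min(b$cM[b$is_representative])),
      map_function = "kosambi")
    cons <- refill_residuals(skel, b)
    shift <- min(b$cM[b$is_representative])
    for (k in which(!cons$is_skeleton)) {
      bb <- b[b$marker == cons$marker[k], ]
      expect_gte(cons$cM[k], bb$start_cM - shift - 1e-9)
      expect_lte(cons$cM[k], bb$end_cM - shift + 1e-9)
    }
  }
})

test_that("order concordance matches the closed-form Spearman values", {
  mk <- sprintf("m%d", 1:4)
  mx <- tibble::tibble(marker = mk, lg = "LG1", cM = 1:4)
  expect_equal(order_concordance(mx, mx)$spearman_r, 1)
  rev_map <- tibble::tibble(marker = rev(mk), lg = "LG1", cM = 1:4)
  expect_equal(order_concordance(mx, rev_map)$spearman_r, -1)
  swap <- tibble::tibble(marker = mk[c(1, 3, 2, 4)], lg = "LG1", cM = 1:4)
  expect_equal(order_concordance(mx, swap)$spearman_r, 0.8)
  # fewer than two shared markers is undefined
  other <- tibble::tibble(marker = c("m1", "z9"), lg = "LG1", cM = 1:2)
  expect_true(is.na(order_concordance(mx, other)$spearman_r))
})
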