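# small truth genome used across tests (2 chromosomes, light RGH layer)
small_truth <- function(seed = 5, markers_per_chr = 10, ...) {
  simulate_truth(sim_truth_config(
    n_chr = 2, markers_per_chr = markers_per_chr,
    marker_scaffolds_per_chr = 4,
    rgh_cluster_sizes = c(2, 3), rgh_cluster_span_kb = c(100, 200),
    rgh_cluster_chr = c(1, 2), rgh_singletons_per_chr = c(1, 1),
    rgh_class_counts = c(CNL = 3, TNL = 2, NL = 1, N = 1),
    n_incomplete_nb = 1, seed = seed, ...))
}

# genotype table from a plain character matrix (markers x individuals)
geno_from_matrix <- function(m, population = "F2") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("M%02d", seq_len(nrow(m)))
  as_geno(dplyr::bind_cols(tibble::tibble(marker = rownames(m)),
                           tibble::as_tibble(m, .name_repair = "minimal") |>
                             rlang::set_names(sprintf("i%03d", seq_len(ncol(m))))),
          population)
}

# multinomial F2 two-locus class probabilities at recombination fraction r
f2_class_probs <- function(r) {
  c(AA = (1 - r)^2 / 4, AH = r * (1 - r) / 2, AB = r^2 / 4,
    HA = r * (1 - r) / 2, HH = ((1 - r)^2 + r^2) / 2, HB = r * (1 - r) / 2,
    BA = r^2 / 4, BH = r * (1 - r) / 2, BB = (1 - r)^2 / 4)
}

# draw a simulated F2 marker pair directly from the class distribution
sim_f2_pair <- function(n, r) {
  cls <- sample(names(f2_class_probs(r)), n, replace = TRUE,
                prob = f2_class_probs(r))
  list(a = substr(cls, 1, 1), b = substr(cls, 2, 2))
}

# independent grid-search oracle for the F2 recombination fraction MLE
grid_rf_f2 <- function(a, b, step = 1e-4) {
  keep <- a != "-" & b != "-"
  cls <- paste0(a[keep], b[keep])
  counts <- table(factor(cls, levels = names(f2_class_probs(0.1))))
  grid <- seq(0, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    p <- f2_class_probs(r)
    sum(counts * log(pmax(p, 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}

# brute-force SARF minimum over all permutations (n <= 8)
brute_force_order <- function(markers, rf) {
  n <- length(markers)
  rmat <- matrix(0.5, n, n, dimnames = list(markers, markers))
  ia <- match(rf$marker_a, markers); ib <- match(rf$marker_b, markers)
  ok <- !is.na(ia) & !is.na(ib)
  rmat[cbind(ia, ib)[ok, , drop = FALSE]] <- rf$r_hat[ok]
  rmat[cbind(ib, ia)[ok, , drop = FALSE]] <- rf$r_hat[ok]
  perms <- gtools_permutations(n)
  best <- Inf; best_p <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    if (p[1] > p[n]) next # orientation symmetry
    s <- sum(rmat[cbind(p[-n], p[-1])])
    if (s < best - 1e-12) { best <- s; best_p <- p }
  }
  list(order = markers[best_p], sarf = best)
}

# all permutations of 1..n (no extra deps)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- matrix(setdiff(seq_len(n), i)[sub], nrow(sub))
  }
  out
}

sarf_of <- function(ord, rf) {
  key <- paste(pmin(rf$marker_a, rf$marker_b), pmax(rf$marker_a, rf$marker_b))
  rl <- stats::setNames(rf$r_hat, key)
  k <- paste(pmin(ord[-length(ord)], ord[-1]), pmax(ord[-length(ord)], ord[-1]))
  v <- rl[k]
  v[is.na(v)] <- 0.5
  sum(v)
}

# O(n^2) all-windows brute force for maximal <1 Mbp runs
brute_force_clusters <- function(start, end, max_span = 1e6) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  n <- length(start)
  runs <- list()
  i <- 1
  while (i <= n) {
    jmax <- i
    for (j in i:n) {
      if (end[j] - start[i] + 1 < max_span) jmax <- j else break
    }
    if (jmax > i) {
      runs[[length(runs) + 1]] <- o[i:jmax]
      i <- jmax + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

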