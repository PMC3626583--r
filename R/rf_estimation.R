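#' Pairwise recombination fractions and LOD scores
#'
#' Estimates the meiotic recombination fraction r and its LOD score for every
#' marker pair of a genotype table.
#'
#' For codominant F2 data the maximum-likelihood r is found by EM over the
#' nine two-locus genotype classes: every class implies a fixed number of
#' recombinant gametes except the double heterozygote, which mixes the two
#' phase configurations; its expected recombinant-gamete count at the current
#' estimate is 2r^2 / ((1-r)^2 + r^2). Iteration starts at r = 0.25, is
#' clamped to \[1e-6, 0.4999\] to avoid boundary degeneracy, and stops when
#' |delta r| < 1e-8 (at most 1000 iterations).
#'
#' For RILs at fixation the observed fraction R of recombinant homozygote
#' pairs is converted to meiotic r by the Haldane-Waddington relation for
#' selfed lines, r = R / (2 (1 - R)), capped at 0.5.
#'
#' LOD = log10 L(r_hat) - log10 L(0.5); it is 0 exactly when r_hat = 0.5.
#'
#' @param geno A genotype table (see [as_geno()]).
#' @param population `"F2"` or `"RIL"`; defaults to the table's attribute.
#' @return A tibble with one row per unordered marker pair: `marker_a`,
#'   `marker_b`, `r_hat`, `lod`, `n_informative`, `population`. For RIL data
#'   the observed recombinant fraction is returned as `R_obs`.
#' @export
pairwise_rf <- function(geno, population = NULL) {
  population <- population %||% geno_population(geno)
  m <- geno_int(geno)
  if (nrow(m) < 2) abort("need at least two markers.")
  est <- rf_core(m, population)
  ix <- which(upper.tri(est$r), arr.ind = TRUE)
  out <- tibble(
    marker_a = rownames(m)[ix[, 1]],
    marker_b = rownames(m)[ix[, 2]],
    r_hat = est$r[ix],
    lod = est$lod[ix],
    n_informative = est$n[ix],
    population = population
  )
  if (population == "RIL") out$R_obs <- est$R[ix]
  out
}

#' Recombination fraction for a single marker pair
#'
#' @param col_a,col_b Genotype call vectors (codes `A`, `H`, `B`, `-`).
#' @param population `"F2"` or `"RIL"`.
#' @inherit pairwise_rf details
#' @return One-row tibble as in [pairwise_rf()].
#' @examples
#' # 1 recombinant homozygote pair out of 3 informative RILs:
#' # R = 1/3, r = R / (2 (1 - R)) = 0.25
#' estimate_rf(c("A", "A", "B"), c("A", "B", "B"), "RIL")$r_hat
#' @export
estimate_rf <- function(col_a, col_b, population = c("F2", "RIL")) {
  population <- match.arg(population)
  calls <- rbind(a = as.character(col_a), b = as.character(col_b))
  bad <- setdiff(unique(as.vector(calls)), c("A", "H", "B", "-"))
  if (length(bad)) {
    abort(paste0("invalid genotype codes: ", paste(bad, collapse = ", ")))
  }
  if (population == "RIL" && any(calls == "H")) {
    warn("heterozygous calls in RIL data treated as missing.")
    calls[calls == "H"] <- "-"
  }
  m <- matrix(c(A = 0L, H = 1L, B = 2L, `-` = NA_integer_)[calls],
              nrow = 2, dimnames = list(c("a", "b"), NULL))
  est <- rf_core(m, population)
  if (est$n[1, 2] == 0) abort("no individuals informative for the pair.")
  out <- tibble(r_hat = est$r[1, 2], lod = est$lod[1, 2],
                n_informative = est$n[1, 2], population = population)
  if (population == "RIL") out$R_obs <- est$R[1, 2]
  out
}

# vectorised estimation over all pairs of an integer genotype matrix
rf_core <- function(m, population) {
  miss <- is.na(m)
  ind <- function(code) {
    x <- (m == code) & !miss
    storage.mode(x) <- "double"
    x
  }
  if (population == "F2") {
    IA <- ind(0L); IH <- ind(1L); IB <- ind(2L)
    nAA <- IA %*% t(IA); nAH <- IA %*% t(IH); nAB <- IA %*% t(IB)
    nHA <- IH %*% t(IA); nHH <- IH %*% t(IH); nHB <- IH %*% t(IB)
    nBA <- IB %*% t(IA); nBH <- IB %*% t(IH); nBB <- IB %*% t(IB)
    n <- nAA + nAH + nAB + nHA + nHH + nHB + nBA + nBH + nBB
    k_fixed <- nAH + nHA + nHB + nBH + 2 * (nAB + nBA)
    r <- matrix(0.25, nrow(m), nrow(m))
    ok <- n > 0
    for (it in seq_len(1000)) {
      w <- 2 * r^2 / ((1 - r)^2 + r^2)
      r_new <- ifelse(ok, (k_fixed + nHH * w) / (2 * n), r)
      r_new <- pmin(pmax(r_new, 1e-6), 0.4999)
      if (max(abs(r_new - r)) < 1e-8) {
        r <- r_new
        break
      }
      r <- r_new
    }
    ll <- function(r) {
      xlogy(nAA + nBB, (1 - r)^2 / 4) + xlogy(nAB + nBA, r^2 / 4) +
        xlogy(nAH + nHA + nHB + nBH, r * (1 - r) / 2) +
        xlogy(nHH, ((1 - r)^2 + r^2) / 2)
    }
    lod <- pmax((ll(r) - ll(matrix(0.5, nrow(m), nrow(m)))) / log(10), 0)
    r[r <= 1e-6] <- 0
    snap <- r >= 0.4999
    r[snap] <- 0.5
    lod[snap] <- 0
    r[!ok] <- NA_real_
    lod[!ok] <- NA_real_
    list(r = r, lod = lod, n = n)
  } else {
    IA <- ind(0L); IB <- ind(2L)
    nAA <- IA %*% t(IA); nAB <- IA %*% t(IB)
    nBA <- IB %*% t(IA); nBB <- IB %*% t(IB)
    n <- nAA + nAB + nBA + nBB
    k <- nAB + nBA
    R <- ifelse(n > 0, k / n, NA_real_)
    r <- ifelse(R >= 0.5, 0.5, R / (2 * (1 - R)))
    Rs <- pmin(R, 0.5)
    lod <- pmax((xlogy(k, Rs) + xlogy(n - k, 1 - Rs) - n * log(0.5)) / log(10), 0)
    lod[!is.na(R) & R >= 0.5] <- 0
    list(r = r, lod = lod, n = n, R = R)
  }
}
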