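#' Map functions: recombination fraction to genetic distance
#'
#' Convert meiotic recombination fractions to additive map distances in
#' centiMorgans and back. The Kosambi function assumes partial crossover
#' interference, Haldane assumes none (crossovers as a Poisson process).
#'
#' Kosambi: d = 25 * log((1 + 2r) / (1 - 2r)).
#' Haldane: d = -50 * log(1 - 2r).
#' Both are strictly increasing on r in \[0, 0.5) and map r = 0 to d = 0;
#' `cm_to_rf()` is the exact inverse (round-trip error < 1e-10).
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @param d Map distance(s) in cM, >= 0.
#' @param map_function `"kosambi"` (default) or `"haldane"`.
#' @return Numeric vector of distances (cM) or recombination fractions.
#' @examples
#' rf_to_cm(0.2, "kosambi") # 21.18 cM
#' rf_to_cm(0.2, "haldane") # 25.54 cM
#' cm_to_rf(rf_to_cm(0.3))  # 0.3
#' @export
rf_to_cm <- function(r, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    abort("`r` must lie in [0, 0.5).")
  }
  switch(map_function,
    kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
    haldane = -50 * log(1 - 2 * r)
  )
}

#' @rdname rf_to_cm
#' @export
cm_to_rf <- function(d, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(!is.finite(d)) || any(d < 0)) {
    abort("`d` must be a non-negative map distance in cM.")
  }
  switch(map_function,
    kosambi = 0.5 * tanh(d / 50),
    haldane = 0.5 * (1 - exp(-d / 50))
  )
}
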