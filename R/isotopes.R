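## Aggregated isotopologue distribution of n atoms of one element.
## Distributions are kept per nominal-mass shift k (0, +1, +2, ...) as a
## probability p[k] and the mean exact-mass shift m[k] within the bin.
.element_distribution <- function(element, n, max_shift) {
  key <- paste0(element, n, "_", max_shift)
  hit <- .eldist_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .element_distribution_impl(element, n, max_shift)
  .eldist_cache[[key]] <- out
  out
}

.eldist_cache <- new.env(parent = emptyenv())

.element_distribution_impl <- function(element, n, max_shift) {
  iso <- .isotopes[[element]]
  shifts <- round(iso$mass - iso$mass[1])
  p1 <- numeric(max_shift + 1L)
  m1 <- numeric(max_shift + 1L)
  for (i in seq_along(iso$mass)) {
    k <- shifts[i] + 1L
    if (k > max_shift + 1L) next
    p1[k] <- p1[k] + iso$abundance[i]
    m1[k] <- iso$mass[i] - iso$mass[1]
  }
  acc <- list(p = c(1, numeric(max_shift)), m = numeric(max_shift + 1L))
  base <- list(p = p1, m = m1)
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- .convolve_dist(acc, base, max_shift)
    n <- n %/% 2L
    if (n > 0L) base <- .convolve_dist(base, base, max_shift)
  }
  acc
}

.convolve_dist <- function(a, b, max_shift) {
  p <- numeric(max_shift + 1L)
  msum <- numeric(max_shift + 1L)
  for (i in seq_len(max_shift + 1L)) {
    if (a$p[i] == 0) next
    jmax <- max_shift + 2L - i
    pij <- a$p[i] * b$p[seq_len(jmax)]
    k <- i + seq_len(jmax) - 1L
    p[k] <- p[k] + pij
    msum[k] <- msum[k] + pij * (a$m[i] + b$m[seq_len(jmax)])
  }
  m <- ifelse(p > 0, msum / p, 0)
  list(p = p, m = m)
}

#' Theoretical isotope pattern of a glycan composition
#'
#' Computes the relative abundances of the first `n_peaks` isotopologue peaks
#' (A, A+1, A+2, ...) of the singly sodiated ion from the full elemental
#' formula of the composition (residues plus the reducing-end water; sodium is
#' monoisotopic). Per-element isotopologue distributions are convolved exactly
#' and the result is renormalized to sum to 1 over the requested peaks.
#'
#' @param composition A composition in any form accepted by
#'   [theoretical_mz()] (single composition).
#' @param n_peaks Number of isotopologue peaks (>= 2; default 4).
#' @return A tibble with columns `peak` (0-based isotopologue index), `mz`
#'   (abundance-weighted m/z of the isotopologue) and `abundance`
#'   (non-negative, summing to 1).
#' @examples
#' isotope_pattern("H3N4")
#' @export
isotope_pattern <- function(composition, n_peaks = 4L) {
  fast <- .iso_pattern_fast(composition, n_peaks)
  tibble::tibble(peak = seq_along(fast$mz) - 1L, mz = fast$mz,
                 abundance = fast$abundance)
}

.iso_cache <- new.env(parent = emptyenv())

## Tibble-free memoized core; the hot loops of the simulator and the
## processing pipeline call this directly.
.iso_pattern_fast <- function(composition, n_peaks) {
  if (is.character(composition) && length(composition) == 1L) {
    key <- paste0(composition, "#", n_peaks)
    hit <- .iso_cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- .isotope_pattern_impl(composition, n_peaks)
    .iso_cache[[key]] <- out
    return(out)
  }
  .isotope_pattern_impl(composition, n_peaks)
}

.isotope_pattern_impl <- function(composition, n_peaks) {
  stopifnot(n_peaks >= 2L)
  counts <- composition_counts(composition)
  if (nrow(counts) != 1L) stop("isotope_pattern() expects a single composition")
  if (sum(counts) < 1L) stop("empty composition: total residue count must be >= 1")
  formula <- c(C = 0, H = 2, N = 0, O = 1)  # reducing-end water
  for (res in names(.residue_formulas)) {
    i <- match(res, c("Hex", "HexNAc", "Fuc", "ENeuAc", "LNeuAc"))
    formula <- formula + counts[1, i] * .residue_formulas[[res]][c("C", "H", "N", "O")]
  }
  max_shift <- n_peaks - 1L
  dist <- list(p = c(1, numeric(max_shift)), m = numeric(max_shift + 1L))
  for (el in names(.isotopes)) {
    if (formula[[el]] > 0) {
      dist <- .convolve_dist(dist, .element_distribution(el, formula[[el]], max_shift),
                             max_shift)
    }
  }
  mono <- theoretical_mz(counts)
  list(mz = mono + dist$m, abundance = dist$p / sum(dist$p))
}
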