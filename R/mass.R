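#' Theoretical m/z of a sodiated glycan composition
#'
#' Computes the monoisotopic m/z of the singly sodiated ion \[M+Na\]+ of a
#' free-reducing-end glycan: the sum of dehydrated residue masses, plus one
#' water for the reducing end, plus the sodium cation mass.
#'
#' @param composition A composition string (`"H3N4"`), a
#'   [glycan_composition()], a character vector of strings, or a counts
#'   matrix/data.frame with columns `hex`, `hexnac`, `fuc`, `eneuac`, `lneuac`.
#' @return Numeric vector of m/z values in Da.
#' @examples
#' theoretical_mz("H3N4")    # 1339.476
#' theoretical_mz("H3N4F1")  # 1485.534
#' @export
theoretical_mz <- function(composition) {
  m <- composition_counts(composition)
  if (any(rowSums(m) < 1L)) stop("empty composition: total residue count must be >= 1")
  rmass <- .residue_masses[c("Hex", "HexNAc", "Fuc", "ENeuAc", "LNeuAc")]
  as.numeric(m %*% rmass) + mass_water() + mass_sodium_cation()
}

#' Signed mass error in parts per million
#'
#' @param observed_mz,theoretical_mz Positive m/z values (vectorized).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(observed_mz <= 0) || any(theoretical_mz <= 0)) {
    stop("m/z values must be positive")
  }
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Default composition-enumeration bounds
#'
#' Count ranges spanning the N-glycan space probed by the assignment step:
#' chitobiose-core glycans up to large polyantennary/poly-LacNAc species.
#'
#' @param hex,hexnac,fuc,eneuac,lneuac Length-2 integer ranges `c(min, max)`.
#' @return A named list of ranges, class `enum_bounds`.
#' @export
enum_bounds <- function(hex = c(0L, 12L), hexnac = c(2L, 10L), fuc = c(0L, 5L),
                        eneuac = c(0L, 4L), lneuac = c(0L, 4L)) {
  b <- list(hex = hex, hexnac = hexnac, fuc = fuc, eneuac = eneuac, lneuac = lneuac)
  for (nm in names(b)) {
    r <- b[[nm]]
    if (length(r) != 2L || any(r < 0) || r[1] > r[2]) {
      stop("invalid bound for ", nm, ": expected c(min, max) with 0 <= min <= max")
    }
    b[[nm]] <- as.integer(r)
  }
  structure(b, class = "enum_bounds")
}

## Cache of enumerated composition tables, keyed by bounds + filter flag.
## Enumeration over the default bounds is ~18k rows; computing it once per
## session keeps per-peak candidate lookup O(log n).
.enum_cache <- new.env(parent = emptyenv())

#' Full table of candidate compositions within bounds
#'
#' Expands every residue-count combination within `bounds`, optionally applies
#' the biosynthetic plausibility filter (chitobiose core: `hexnac >= 2`;
#' sialic acids limited by antenna capacity: `eneuac + lneuac <=
#' max(hexnac - 2, 0)`; `fuc <= hexnac`), and attaches the theoretical
#' sodiated m/z, sorted ascending.
#'
#' @param bounds An [enum_bounds()] object.
#' @param biosynthetic_filter Apply the plausibility filter (default `TRUE`).
#' @return A tibble with count columns, `composition` and `mz`.
#' @export
composition_table <- function(bounds = enum_bounds(), biosynthetic_filter = TRUE) {
  key <- paste(c(unlist(bounds), biosynthetic_filter), collapse = "_")
  hit <- .enum_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- expand.grid(
    hex = seq.int(bounds$hex[1], bounds$hex[2]),
    hexnac = seq.int(bounds$hexnac[1], bounds$hexnac[2]),
    fuc = seq.int(bounds$fuc[1], bounds$fuc[2]),
    eneuac = seq.int(bounds$eneuac[1], bounds$eneuac[2]),
    lneuac = seq.int(bounds$lneuac[1], bounds$lneuac[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[rowSums(grid) >= 1L, , drop = FALSE]
  if (biosynthetic_filter) {
    keep <- grid$hexnac >= 2L &
      (grid$eneuac + grid$lneuac) <= pmax(grid$hexnac - 2L, 0L) &
      grid$fuc <= grid$hexnac
    grid <- grid[keep, , drop = FALSE]
  }
  mz <- theoretical_mz(grid)
  ord <- order(mz)
  grid <- grid[ord, , drop = FALSE]
  out <- tibble::as_tibble(grid)
  out$composition <- format_composition_counts(grid)
  out$mz <- mz[ord]
  out$n_residues <- as.integer(rowSums(grid))
  .enum_cache[[key]] <- out
  out
}

#' Enumerate candidate compositions for an observed m/z
#'
#' Returns every composition within `bounds` whose theoretical sodiated m/z
#' lies within `tol_ppm` parts per million of `mz`. Candidates are ordered by
#' increasing absolute ppm error, ties broken by fewer total residues, so the
#' first row is the single "most probable" assignment.
#'
#' @param mz Observed m/z (scalar, > 0).
#' @param tol_ppm Matching tolerance in ppm (default 20).
#' @param bounds An [enum_bounds()] object.
#' @param biosynthetic_filter Apply the plausibility filter (default `TRUE`).
#' @return A tibble of candidates with columns `composition`, count columns,
#'   `mz` (theoretical), `ppm` (signed error of the observation), and
#'   `in_window` flagging candidates inside the 1000-5000 m/z working window.
#'   Zero rows is a valid result.
#' @examples
#' enumerate_compositions(1339.476)
#' @export
enumerate_compositions <- function(mz, tol_ppm = 20, bounds = enum_bounds(),
                                   biosynthetic_filter = TRUE) {
  stopifnot(length(mz) == 1L, mz > 0, tol_ppm > 0)
  tab <- composition_table(bounds, biosynthetic_filter)
  tol_da <- mz * tol_ppm * 1e-6
  lo <- findInterval(mz - tol_da, tab$mz) + 1L
  hi <- findInterval(mz + tol_da, tab$mz)
  if (hi < lo) {
    out <- tab[0, , drop = FALSE]
    out$ppm <- numeric(0)
    out$in_window <- logical(0)
    return(out[, c("composition", .residue_order, "mz", "ppm", "in_window")])
  }
  out <- tab[lo:hi, , drop = FALSE]
  out$ppm <- ppm_error(mz, out$mz)
  out$in_window <- out$mz >= 1000 & out$mz <= 5000
  n_res <- rowSums(out[, .residue_order])
  out <- out[order(abs(out$ppm), n_res), , drop = FALSE]
  out[, c("composition", .residue_order, "mz", "ppm", "in_window")]
}

## Fast internal candidate lookup: indices into a composition_table(),
## ordered by |ppm| then total residue count. Avoids per-call tibble
## construction in the per-peak hot loop of process_spectrum().
.match_compositions <- function(mz, tol_ppm, tab) {
  tol_da <- mz * tol_ppm * 1e-6
  lo <- findInterval(mz - tol_da, tab$mz) + 1L
  hi <- findInterval(mz + tol_da, tab$mz)
  if (hi < lo) return(integer(0))
  idx <- lo:hi
  ppm <- (mz - tab$mz[idx]) / tab$mz[idx] * 1e6
  idx[order(abs(ppm), tab$n_residues[idx])]
}

#' Interpret neutral losses between a precursor and its fragments
#'
#' For each fragment m/z, reports every residue class whose residue mass
#' matches the precursor-fragment difference within `tol_da`; a loss matching
#' several classes is reported once per class.
#'
#' @param precursor_mz Precursor m/z.
#' @param fragment_mzs Numeric vector of fragment m/z values (may be empty).
#' @param tol_da Absolute matching tolerance in Da.
#' @return A tibble with columns `fragment_mz`, `loss_da`, `residue`,
#'   `residue_mass`, `delta_da`.
#' @examples
#' interpret_losses(1809.504, 1663.420, tol_da = 0.1)  # fucose loss
#' @export
interpret_losses <- function(precursor_mz, fragment_mzs, tol_da = 0.1) {
  stopifnot(tol_da > 0)
  empty <- tibble::tibble(fragment_mz = numeric(0), loss_da = numeric(0),
                          residue = character(0), residue_mass = numeric(0),
                          delta_da = numeric(0))
  if (length(fragment_mzs) == 0L) return(empty)
  rows <- lapply(fragment_mzs, function(f) {
    loss <- precursor_mz - f
    hit <- abs(.residue_masses - loss) <= tol_da
    if (!any(hit)) return(NULL)
    tibble::tibble(fragment_mz = f, loss_da = loss,
                   residue = names(.residue_masses)[hit],
                   residue_mass = unname(.residue_masses[hit]),
                   delta_da = loss - unname(.residue_masses[hit]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}
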