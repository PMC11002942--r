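.residue_order <- c("hex", "hexnac", "fuc", "eneuac", "lneuac")
.residue_letters <- c(hex = "H", hexnac = "N", fuc = "F", eneuac = "E", lneuac = "L")

#' Glycan composition
#'
#' A glycan composition counts residue classes, not linkages: hexoses (H),
#' N-acetylhexosamines (N), deoxyhexoses/fucoses (F), ethyl-esterified
#' NeuAc (E, marking alpha-2,6 sialylation) and lactonized NeuAc (L, marking
#' alpha-2,3 sialylation). The canonical text form is `"H5N4F1E1L1"`;
#' zero counts of F, E and L are omitted on output while H and N are always
#' written (e.g. `"H5N2"`).
#'
#' @param hex,hexnac,fuc,eneuac,lneuac Non-negative integer residue counts.
#' @return An object of class `glycan_composition` (a named integer vector).
#' @examples
#' glycan_composition(5, 4, fuc = 1)
#' parse_composition("H5N4F1")
#' @export
glycan_composition <- function(hex, hexnac, fuc = 0L, eneuac = 0L, lneuac = 0L) {
  counts <- c(hex = hex, hexnac = hexnac, fuc = fuc, eneuac = eneuac, lneuac = lneuac)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("residue counts must be non-negative integers")
  }
  counts <- as.integer(round(counts))
  names(counts) <- .residue_order
  if (sum(counts) < 1L) stop("empty composition: total residue count must be >= 1")
  structure(counts, class = "glycan_composition")
}

#' @rdname glycan_composition
#' @param x A composition string such as `"H5N4F1E2L1"` (for
#'   `parse_composition`) or a `glycan_composition` (for `format`/`print`).
#' @export
parse_composition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- trimws(x)
  if (!grepl("^([HNFEL][0-9]+)+$", s)) {
    stop("cannot parse composition string: '", x, "'")
  }
  pieces <- regmatches(s, gregexpr("[HNFEL][0-9]+", s))[[1]]
  letters_seen <- substr(pieces, 1L, 1L)
  if (anyDuplicated(letters_seen)) stop("duplicated residue letter in '", x, "'")
  counts <- stats::setNames(rep(0L, 5L), .residue_order)
  idx <- match(letters_seen, .residue_letters)
  counts[idx] <- as.integer(substring(pieces, 2L))
  glycan_composition(counts[1], counts[2], counts[3], counts[4], counts[5])
}

#' @rdname glycan_composition
#' @param ... Ignored.
#' @export
format.glycan_composition <- function(x, ...) {
  format_composition_counts(matrix(unclass(x), nrow = 1,
                                   dimnames = list(NULL, .residue_order)))
}

#' @rdname glycan_composition
#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition>", format(x), "\n")
  invisible(x)
}

## Vectorized canonical formatter over a counts matrix (columns hex..lneuac).
format_composition_counts <- function(m) {
  m <- as.matrix(m)
  out <- paste0("H", m[, "hex"], "N", m[, "hexnac"])
  for (res in c("fuc", "eneuac", "lneuac")) {
    has <- m[, res] > 0
    out[has] <- paste0(out[has], .residue_letters[[res]], m[has, res])
  }
  out
}

## Coerce compositions in any accepted form (string, glycan_composition,
## counts matrix/data.frame) to an n x 5 integer count matrix.
composition_counts <- function(x) {
  if (inherits(x, "glycan_composition")) {
    m <- matrix(unclass(x), nrow = 1)
  } else if (is.character(x)) {
    m <- do.call(rbind, lapply(x, function(s) unclass(parse_composition(s))))
  } else if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(as.data.frame(x)[, .residue_order, drop = FALSE])
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, function(ci) composition_counts(ci)))
  } else {
    stop("cannot interpret object of class '", class(x)[1], "' as glycan composition(s)")
  }
  storage.mode(m) <- "integer"
  colnames(m) <- .residue_order
  m
}
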