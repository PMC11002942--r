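#' @keywords internal
"_PACKAGE"

## IUPAC 2021 atomic monoisotopic masses (Da) and isotopic abundances.
## Electron mass needed because the reported ion is the sodium *cation* adduct.
.atomic <- list(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928,
  electron = 0.00054857990946
)

## Isotope ladders per element: exact masses and natural abundances.
## Used by isotope_pattern(); sodium is monoisotopic and contributes nothing.
.isotopes <- list(
  C = list(mass = c(12.0, 13.0033548378), abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250319, 2.0141017780), abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740052, 15.0001088984), abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
           abundance = c(0.99757, 0.00038, 0.00205))
)

## Residue (dehydrated monomer) elemental formulas. The two sialic acid
## variants encode the linkage-specific derivatization chemistry:
## alpha(2,6)-NeuAc is ethyl-esterified (+C2H4 on the free acid residue,
## C11H17NO8), alpha(2,3)-NeuAc forms a lactone (-H2O).
.residue_formulas <- list(
  Hex    = c(C = 6,  H = 10, N = 0, O = 5),
  HexNAc = c(C = 8,  H = 13, N = 1, O = 5),
  Fuc    = c(C = 6,  H = 10, N = 0, O = 4),
  ENeuAc = c(C = 13, H = 21, N = 1, O = 8),
  LNeuAc = c(C = 11, H = 15, N = 1, O = 7)
)

.formula_mass <- function(formula) {
  sum(formula * unlist(.atomic[names(formula)]))
}

.residue_masses <- vapply(.residue_formulas, .formula_mass, numeric(1))

#' Monoisotopic mass of water and of the sodium cation
#'
#' The free reducing end contributes one water; ionization as \[M+Na\]+ adds
#' one sodium cation (sodium atom minus one electron).
#' @return Mass in Da.
#' @export
mass_water <- function() .formula_mass(c(H = 2, O = 1))

#' @rdname mass_water
#' @export
mass_sodium_cation <- function() .atomic$Na - .atomic$electron

#' Monoisotopic residue mass of a glycan building block
#'
#' Residue masses are dehydrated monomer masses computed from elemental
#' formulas: Hex C6H10O5, HexNAc C8H13NO5, Fuc C6H10O4, ethyl-esterified
#' NeuAc (alpha-2,6 linkage marker) C13H21NO8 and lactonized NeuAc
#' (alpha-2,3 linkage marker) C11H15NO7.
#'
#' @param residue Character vector of residue class labels among
#'   `"Hex"`, `"HexNAc"`, `"Fuc"`, `"ENeuAc"`, `"LNeuAc"`.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' residue_mass("Fuc")              # 146.0579
#' residue_mass(c("ENeuAc", "LNeuAc"))
#' @export
residue_mass <- function(residue) {
  bad <- setdiff(residue, names(.residue_masses))
  if (length(bad) > 0L) {
    stop("unknown residue class: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(names(.residue_masses), collapse = ", "), ")")
  }
  unname(.residue_masses[residue])
}

#' Residue mass table
#'
#' @param file Optional path; when given, the table is also written as
#'   tab-separated text.
#' @return A tibble with columns `residue`, `formula`, `mass`.
#' @export
residue_mass_table <- function(file = NULL) {
  fmt <- vapply(.residue_formulas, function(f) {
    f <- f[f > 0]
    paste0(names(f), f, collapse = "")
  }, character(1))
  tab <- tibble::tibble(
    residue = names(.residue_masses),
    formula = unname(fmt),
    mass = unname(.residue_masses)
  )
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}
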