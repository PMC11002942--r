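#' SILAC isotope incorporation rate
#'
#' `incorporation (%) = (1 - 1 / (mean_ratio + 1)) * 100`, where `mean_ratio`
#' is the mean heavy:light ratio of a fully labeled reference run.
#'
#' @param mean_ratio Mean heavy:light ratio (>= 0, vectorized).
#' @return Incorporation in percent, in \[0, 100).
#' @examples
#' incorporation_rate(1)  # 50
#' @export
incorporation_rate <- function(mean_ratio) {
  if (any(mean_ratio < 0)) stop("mean_ratio must be non-negative")
  (1 - 1 / (mean_ratio + 1)) * 100
}

#' Correct a SILAC ratio for arginine-to-proline interconversion
#'
#' Metabolic conversion of labeled arginine into proline deflates observed
#' heavy:light ratios of proline-containing peptides. The corrected ratio is
#' `r_c = r_o / (1 - p)^n` with `p` the interconversion fraction and `n` the
#' number of prolines in the peptide.
#'
#' @param r_o Observed heavy:light ratio(s), > 0.
#' @param p Interconversion fraction in \[0, 1) (default 0.077, i.e. 7.7%).
#' @param n Proline count(s), non-negative integer.
#' @return Corrected ratio(s) `r_c >= r_o`.
#' @examples
#' correct_ratio(2, p = 0.077, n = 2)
#' @export
correct_ratio <- function(r_o, p = 0.077, n) {
  if (any(r_o <= 0)) stop("observed ratio must be positive")
  if (any(p < 0) || any(p >= 1)) stop("interconversion fraction p must be in [0, 1)")
  if (any(n < 0) || any(n != round(n))) stop("proline count must be a non-negative integer")
  r_o / (1 - p)^n
}

#' Protein-level SILAC quantification from corrected peptide ratios
#'
#' The protein ratio is the median of its (corrected) peptide ratios; the
#' log2 fold-change is `log2(median)`; a protein is selected when
#' `|log2 fold-change| > lfc_threshold` (strict).
#'
#' @param ratios Corrected peptide ratios for one protein (>= 1, positive).
#' @param lfc_threshold Selection threshold on |log2 fold-change|
#'   (default 1).
#' @return A list with `median_ratio`, `log2_fc`, `selected`, `n_peptides`.
#' @export
protein_ratio <- function(ratios, lfc_threshold = 1) {
  if (length(ratios) == 0L) stop("empty peptide ratio set")
  if (any(ratios <= 0)) stop("peptide ratios must be positive")
  med <- stats::median(ratios)
  lfc <- log2(med)
  list(median_ratio = med, log2_fc = lfc,
       selected = abs(lfc) > lfc_threshold, n_peptides = length(ratios))
}

#' Quantify a SILAC experiment from a peptide-level table
#'
#' Applies the identification filter (proteins with at least two unique
#' peptides), corrects each peptide ratio for arginine-to-proline
#' interconversion, takes the median per protein, and flags proteins with
#' `|log2 fold-change| > lfc_threshold`.
#'
#' @param peptides A data frame with columns `protein`, `peptide`, `ratio`
#'   (observed heavy:light, > 0), `prolines` (integer >= 0) and `unique`
#'   (logical: peptide unique to the protein).
#' @param p Arginine-to-proline interconversion fraction (default 0.077).
#' @param lfc_threshold Fold-change selection threshold in log2 units
#'   (default 1).
#' @return A tibble with one row per identified protein: `protein`,
#'   `n_peptides`, `n_unique`, `median_ratio`, `log2_fc`, `selected`.
#'   Summary counts (`n_proteins_input`, `n_identified`, `n_selected`) are
#'   attached as attribute `"summary"`.
#' @export
quantify_experiment <- function(peptides, p = 0.077, lfc_threshold = 1) {
  required <- c("protein", "peptide", "ratio", "prolines", "unique")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols) > 0L) {
    stop("peptide table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(is.na(peptides$ratio) | peptides$ratio <= 0 |
                 is.na(peptides$prolines) | peptides$prolines < 0 |
                 peptides$prolines != round(peptides$prolines))
  if (length(bad) > 0L) {
    stop("malformed peptide rows: ", paste(bad, collapse = ", "))
  }
  if (nrow(peptides) == 0L) {
    out <- tibble::tibble(protein = character(0), n_peptides = integer(0),
                          n_unique = integer(0), median_ratio = numeric(0),
                          log2_fc = numeric(0), selected = logical(0))
    attr(out, "summary") <- c(n_proteins_input = 0L, n_identified = 0L,
                              n_selected = 0L)
    return(out)
  }
  peptides$r_c <- correct_ratio(peptides$ratio, p, peptides$prolines)
  prot <- split(peptides, peptides$protein)
  n_unique <- vapply(prot, function(d) sum(as.logical(d$unique)), integer(1))
  identified <- names(prot)[n_unique >= 2L]
  rows <- lapply(identified, function(id) {
    d <- prot[[id]]
    pr <- protein_ratio(d$r_c, lfc_threshold)
    tibble::tibble(protein = id, n_peptides = nrow(d),
                   n_unique = sum(as.logical(d$unique)),
                   median_ratio = pr$median_ratio, log2_fc = pr$log2_fc,
                   selected = pr$selected)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    tibble::tibble(protein = character(0), n_peptides = integer(0),
                   n_unique = integer(0), median_ratio = numeric(0),
                   log2_fc = numeric(0), selected = logical(0))
  attr(out, "summary") <- c(n_proteins_input = length(prot),
                            n_identified = length(identified),
                            n_selected = sum(out$selected))
  out
}
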