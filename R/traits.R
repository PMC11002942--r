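#' Derived-trait classification rules
#'
#' The rule set driving [classify_composition()]. Defaults encode standard
#' N-glycan conventions on the chitobiose core (two HexNAc, three mannoses):
#'
#' * paucimannosidic: `hexnac == 2`, `hex <= pauci_max_hex` (3), no sialic acids;
#' * high-mannose: `hexnac == 2`, `hm_min_hex <= hex <= hm_max_hex` (5-9),
#'   no fucose, no sialic acids;
#' * hybrid: `hexnac == 3` and `hex >= hybrid_min_hex` (5);
#' * complex: `hexnac >= 4`, or `hexnac == 3` with `hex <= 4`;
#' * antennarity: base antenna count `A = min(hexnac - 2, 4)`; the
#'   polyantennary flag is set exactly when `hex > poly_hex` (7) **and**
#'   `hexnac > poly_hexnac` (6), marking probable poly-LacNAc elongation;
#'   a composition with `A >= 3` antennas whose hexose count also fits
#'   `A - 1` antennas plus one LacNAc repeat (`hex >= A + 2`) receives the
#'   adjacent-lower label as well (e.g. H6N5 is consistent with both a
#'   triantennary glycan and a diantennary glycan carrying a LacNAc repeat).
#'
#' All thresholds are data, not code, so alternative conventions can be
#' tested by passing a modified rule set.
#'
#' @param pauci_max_hex,hm_min_hex,hm_max_hex,hybrid_min_hex,poly_hex,poly_hexnac
#'   Integer thresholds, see above.
#' @return A list of class `trait_rules`.
#' @export
trait_rules <- function(pauci_max_hex = 3L, hm_min_hex = 5L, hm_max_hex = 9L,
                        hybrid_min_hex = 5L, poly_hex = 7L, poly_hexnac = 6L) {
  structure(list(pauci_max_hex = pauci_max_hex, hm_min_hex = hm_min_hex,
                 hm_max_hex = hm_max_hex, hybrid_min_hex = hybrid_min_hex,
                 poly_hex = poly_hex, poly_hexnac = poly_hexnac),
            class = "trait_rules")
}

#' Read / write a trait rule set as a YAML config file
#'
#' The classification thresholds are data, not code; storing them in a small
#' YAML file lets alternative conventions be used without changing the
#' package.
#'
#' @param file Path to the YAML file.
#' @param rules A [trait_rules()] object.
#' @return `read_trait_rules` returns a `trait_rules` object;
#'   `write_trait_rules` returns `file` invisibly.
#' @export
read_trait_rules <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read rule config files")
  }
  vals <- yaml::read_yaml(file)
  known <- names(formals(trait_rules))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown trait rule field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(trait_rules, vals)
}

#' @rdname read_trait_rules
#' @export
write_trait_rules <- function(rules, file) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write rule config files")
  }
  yaml::write_yaml(unclass(rules), file)
  invisible(file)
}

.antennarity_levels <- c("mono", "di", "tri", "tetra", "poly")

#' Classify a glycan composition into derived-trait flags
#'
#' Deterministic, purely compositional classification: glycan type
#' (paucimannosidic / high-mannose / hybrid / complex / unclassified),
#' fucosylation (none / mono / multi), linkage-specific sialylation
#' (alpha-2,3 via lactonized NeuAc, alpha-2,6 via ethyl-esterified NeuAc,
#' mixed when both), a sialyl-Lewis-x candidate flag (co-occurrence of
#' fucose and alpha-2,3-NeuAc — a compositional proxy, not a structural
#' call), the hexose/HexNAc ratio class, and the set of antennarity labels
#' consistent with the composition (see [trait_rules()]).
#'
#' @param composition A single composition (string or [glycan_composition()]).
#' @param rules A [trait_rules()] object.
#' @return A list of class `trait_flags`: `type`, `fucosylation`,
#'   `sialylation` (character vector among `"a23"`, `"a26"`, `"mixed"`),
#'   `slex_candidate`, `hn_class` (`"H>N"`, `"H=N"`, `"H<N"`),
#'   `antennarity` (character vector of consistent labels), `poly`.
#' @examples
#' classify_composition("H3N4F1")  # complex, monofucosylated, diantennary
#' classify_composition("H8N7")    # polyantennary
#' @export
classify_composition <- function(composition, rules = trait_rules()) {
  m <- composition_counts(composition)
  if (nrow(m) != 1L) stop("classify_composition() expects a single composition")
  h <- m[1, "hex"]; n <- m[1, "hexnac"]; f <- m[1, "fuc"]
  e <- m[1, "eneuac"]; l <- m[1, "lneuac"]
  sial <- e + l

  type <- if (n == 2L && h <= rules$pauci_max_hex && sial == 0L) {
    "paucimannosidic"
  } else if (n == 2L && h >= rules$hm_min_hex && h <= rules$hm_max_hex &&
             f == 0L && sial == 0L) {
    "high_mannose"
  } else if (n == 3L && h >= rules$hybrid_min_hex) {
    "hybrid"
  } else if (n >= 4L || (n == 3L && h <= 4L)) {
    "complex"
  } else {
    "unclassified"
  }

  fucosylation <- if (f == 0L) "none" else if (f == 1L) "mono" else "multi"
  sialylation <- c(if (l >= 1L) "a23", if (e >= 1L) "a26",
                   if (l >= 1L && e >= 1L) "mixed")
  hn_class <- if (h > n) "H>N" else if (h == n) "H=N" else "H<N"

  poly <- h > rules$poly_hex && n > rules$poly_hexnac
  antennarity <- character(0)
  if (type %in% c("complex", "hybrid")) {
    if (poly) {
      antennarity <- "poly"
    } else {
      a <- min(n - 2L, 4L)
      if (a >= 1L) {
        antennarity <- .antennarity_levels[a]
        ## also consistent with (a-1) antennas + one LacNAc repeat
        if (a >= 3L && h >= a + 2L) {
          antennarity <- c(.antennarity_levels[a - 1L], antennarity)
        }
      }
    }
  }

  structure(list(type = type, fucosylation = fucosylation,
                 sialylation = sialylation,
                 slex_candidate = f >= 1L && l >= 1L,
                 hn_class = hn_class, antennarity = antennarity, poly = poly),
            class = "trait_flags")
}

#' @export
print.trait_flags <- function(x, ...) {
  cat("<trait_flags>", x$type, "|", x$fucosylation, "fucosylation |",
      if (length(x$sialylation)) paste(x$sialylation, collapse = "+") else "asialo",
      "|", x$hn_class, "|",
      if (length(x$antennarity)) paste(x$antennarity, collapse = "/") else "no antenna",
      "\n")
  invisible(x)
}

#' Names of all derived-trait groups
#' @return Character vector of trait-table column names.
#' @export
trait_names <- function() {
  c("paucimannosidic", "high_mannose", "complex", "hybrid", "unclassified",
    "monofucosylation", "multifucosylation", "total_fucosylation",
    "a23_sialylation", "a26_sialylation", "mixed_sialylation",
    "total_sialylation", "slex",
    "hex_gt_hexnac", "hex_eq_hexnac", "hex_lt_hexnac",
    "ant_mono", "ant_di", "ant_di_tri", "ant_tri", "ant_tri_tetra",
    "ant_tetra", "ant_tetra_poly", "ant_poly")
}

## Membership of one peak (its candidate composition set) in each trait
## group. A peak contributes fully to every group that at least one of its
## candidates belongs to; for antennarity, the union of labels over all
## candidates is mapped to the exact or intermediate (adjacent-pair) group.
.member_cache <- new.env(parent = emptyenv())

.peak_memberships <- function(candidates, rules) {
  key <- paste(c(candidates, "|", unlist(rules)), collapse = ",")
  hit <- .member_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .peak_memberships_impl(candidates, rules)
  .member_cache[[key]] <- out
  out
}

.peak_memberships_impl <- function(candidates, rules) {
  flags <- lapply(candidates, classify_composition, rules = rules)
  member <- stats::setNames(rep(FALSE, length(trait_names())), trait_names())
  types <- unique(vapply(flags, `[[`, character(1), "type"))
  member[intersect(types, c("paucimannosidic", "high_mannose", "complex",
                            "hybrid", "unclassified"))] <- TRUE
  fuc <- vapply(flags, `[[`, character(1), "fucosylation")
  member["monofucosylation"] <- any(fuc == "mono")
  member["multifucosylation"] <- any(fuc == "multi")
  member["total_fucosylation"] <- any(fuc != "none")
  sial <- unlist(lapply(flags, `[[`, "sialylation"))
  member["a23_sialylation"] <- "a23" %in% sial
  member["a26_sialylation"] <- "a26" %in% sial
  member["mixed_sialylation"] <- "mixed" %in% sial
  member["total_sialylation"] <- length(sial) > 0
  member["slex"] <- any(vapply(flags, `[[`, logical(1), "slex_candidate"))
  hn <- vapply(flags, `[[`, character(1), "hn_class")
  member["hex_gt_hexnac"] <- any(hn == "H>N")
  member["hex_eq_hexnac"] <- any(hn == "H=N")
  member["hex_lt_hexnac"] <- any(hn == "H<N")
  ant <- unique(unlist(lapply(flags, `[[`, "antennarity")))
  ant <- .antennarity_levels[sort(match(ant, .antennarity_levels))]
  key <- paste(ant, collapse = "/")
  ant_group <- switch(key,
    "mono" = "ant_mono", "di" = "ant_di", "di/tri" = "ant_di_tri",
    "tri" = "ant_tri", "tri/tetra" = "ant_tri_tetra", "tetra" = "ant_tetra",
    "tetra/poly" = "ant_tetra_poly", "poly" = "ant_poly", NULL)
  if (!is.null(ant_group)) member[ant_group] <- TRUE
  member
}

#' Aggregate normalized peak percentages into a derived-trait table
#'
#' Each trait group's value is the sum of the normalized percentages of all
#' kept peaks having at least one candidate composition in that group. A
#' peak whose candidates span two type groups contributes fully to both
#' (which is why trait sums can exceed 100% — the signature of nonunivocal
#' assignments). For antennarity, the union of labels over a peak's
#' candidates is mapped to the exact group (`ant_di`, ...) or, when it spans
#' exactly two adjacent classes, to the intermediate group (`ant_di_tri`,
#' `ant_tri_tetra`, `ant_tetra_poly`).
#'
#' @param peaks A data frame of annotated peaks with columns `percent`
#'   (normalized, kept peaks summing to 100), `candidates` (semicolon-joined
#'   composition strings) and optionally `kept` (only kept rows are used).
#' @param rules A [trait_rules()] object.
#' @return A one-row tibble with one column per [trait_names()] entry.
#' @export
aggregate_traits <- function(peaks, rules = trait_rules()) {
  if ("kept" %in% names(peaks)) peaks <- peaks[peaks$kept, , drop = FALSE]
  if (nrow(peaks) == 0L) stop("no kept peaks to aggregate")
  if (!all(c("percent", "candidates") %in% names(peaks))) {
    stop("peaks must have columns 'percent' and 'candidates'")
  }
  if (abs(sum(peaks$percent) - 100) > 1e-6) {
    stop("peak percentages are not normalized (sum = ",
         format(sum(peaks$percent)), ", expected 100)")
  }
  acc <- stats::setNames(numeric(length(trait_names())), trait_names())
  for (i in seq_len(nrow(peaks))) {
    cand <- strsplit(peaks$candidates[i], ";", fixed = TRUE)[[1]]
    member <- .peak_memberships(cand, rules)
    acc <- acc + member * peaks$percent[i]
  }
  tibble::as_tibble(as.list(acc))
}

#' Trait table computed directly from a ground-truth profile
#'
#' Applies the trait calculus to the exact species fractions of a
#' [make_profile()] object (no spectra involved); useful as the ground truth
#' against which pipeline output is compared.
#'
#' @param profile A `glycan_profile`.
#' @param rules A [trait_rules()] object.
#' @return A one-row tibble as in [aggregate_traits()].
#' @export
profile_traits <- function(profile, rules = trait_rules()) {
  peaks <- tibble::tibble(percent = profile$fraction * 100,
                          candidates = profile$composition)
  aggregate_traits(peaks, rules)
}
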