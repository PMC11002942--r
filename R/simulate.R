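## Ground-truth composition profiles for the two simulated cell populations.
## Fractions are percentages of total glycan signal; each preset sums to 100.
## The knockdown preset differs from the control ("NTC-like") preset by the
## programmed trait shifts: complex type +10 points, monofucosylation -8,
## multifucosylation +5, alpha(2,6)-sialylation +6, high-mannose -10.
.profile_presets <- function() {
  ntc <- c(
    ## paucimannosidic
    H3N2F1 = 1,
    ## high-mannose
    H5N2 = 8, H6N2 = 7, H7N2 = 6, H8N2 = 7, H9N2 = 6,
    ## hybrid
    H5N3 = 5, H6N3 = 4, H5N3L1 = 5, H6N3E1 = 5,
    ## complex, non-fucosylated
    H3N4 = 2, H4N4 = 2, H5N4 = 3, H6N5 = 1,
    ## complex, monofucosylated
    H3N4F1 = 2, H4N4F1 = 3, H5N4F1 = 12, H5N4F1E1 = 4, H5N4F1L1 = 3,
    ## complex, multifucosylated
    H5N4F2 = 6, H6N5F2 = 4, H5N4F2L1 = 4
  )
  kd <- ntc
  kd["H5N4F1"] <- 4                      # monofucosylation -8
  kd["H5N4F2"] <- 11                     # multifucosylation +5
  kd[c("H7N2", "H8N2", "H9N2")] <- 3     # high-mannose -10
  kd["H5N4"] <- 10                       # complex +7
  kd <- c(kd, H5N4E1 = 6)                # complex +3, alpha(2,6) +6
  list(ntc_like = ntc, knockdown_like = kd)
}

#' Ground-truth abundance profile for simulation
#'
#' A profile is a set of glycan compositions with relative abundance
#' fractions summing to 1. Two presets emulate the two arms of a
#' knockdown-vs-control cell-line comparison: `"knockdown_like"` differs from
#' `"ntc_like"` by a +10 percentage-point shift into complex-type glycans
#' (taken from high-mannose), a -8 point drop in monofucosylation, a +5 point
#' rise in multifucosylation and a +6 point rise in alpha(2,6)-sialylation.
#'
#' @param spec Either a preset name (`"ntc_like"`, `"knockdown_like"`) or a
#'   named numeric vector of abundances with composition strings as names.
#' @return A tibble with columns `composition`, `fraction` (summing to 1),
#'   and theoretical `mz`; class `glycan_profile`.
#' @examples
#' make_profile("ntc_like")
#' make_profile(c(H5N2 = 0.5, H5N4 = 0.5))
#' @export
make_profile <- function(spec = "ntc_like") {
  if (is.character(spec) && length(spec) == 1L) {
    presets <- .profile_presets()
    if (!spec %in% names(presets)) {
      stop("unknown preset '", spec, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    ab <- presets[[spec]]
  } else if (is.numeric(spec) && !is.null(names(spec))) {
    ab <- spec
  } else {
    stop("spec must be a preset name or a named numeric vector of abundances")
  }
  if (any(ab < 0)) stop("abundances must be non-negative")
  if (sum(ab) <= 0) stop("all-zero abundance profile")
  if (anyDuplicated(names(ab))) stop("duplicated composition in profile")
  comps <- vapply(names(ab), function(s) format(parse_composition(s)), character(1))
  out <- tibble::tibble(
    composition = unname(comps),
    fraction = unname(ab / sum(ab)),
    mz = theoretical_mz(names(ab))
  )
  class(out) <- c("glycan_profile", class(out))
  out
}

#' Simulation design for a replicated MALDI-TOF cohort
#'
#' Parameters of the synthetic-spectrum generator, mirroring a design of
#' `n_bio` biological extracts each deposited `n_tech` times. Technical
#' replicates share the biological abundance draw and differ only in noise
#' and calibration drift.
#'
#' @param n_bio Biological replicates per group (default 3).
#' @param n_tech Technical replicates per biological extract (default 4).
#' @param drift_ppm Systematic calibration drift applied to every spectrum
#'   (ppm, default 8; constant in m/z).
#' @param drift_jitter_ppm SD of the per-spectrum random drift component
#'   (default 2 ppm).
#' @param peak_sigma Gaussian peak width sigma in Da (default 0.05).
#' @param baseline_level SD of additive white baseline noise (default 5,
#'   arbitrary intensity units).
#' @param baseline_wander Amplitude of the slowly varying baseline offset
#'   (default 10).
#' @param bio_sigma Log-normal sigma of the per-species biological abundance
#'   variability (default 0.15, calibrated so the dominant derived traits
#'   show a within-group biological SD of about 2 percentage points,
#'   with smaller traits proportionally tighter, mirroring the replicate
#'   SDs reported for real cell-line cohorts).
#' @param total_area Total glycan signal area per spectrum (default 2e4).
#' @param mz_range Acquisition window (default 1000-5000 m/z).
#' @param grid_step m/z grid spacing in Da (default 0.02).
#' @param n_isotopes Isotopologue peaks simulated per species (default 4).
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_bio = 3L, n_tech = 4L, drift_ppm = 8,
                       drift_jitter_ppm = 2, peak_sigma = 0.05,
                       baseline_level = 5, baseline_wander = 10,
                       bio_sigma = 0.15, total_area = 2e4,
                       mz_range = c(1000, 5000), grid_step = 0.02,
                       n_isotopes = 4L) {
  stopifnot(n_bio >= 1L, n_tech >= 1L, peak_sigma >= 0, baseline_level >= 0,
            baseline_wander >= 0, bio_sigma >= 0, total_area > 0,
            length(mz_range) == 2L, mz_range[1] < mz_range[2], grid_step > 0,
            n_isotopes >= 2L)
  structure(list(n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 drift_ppm = drift_ppm, drift_jitter_ppm = drift_jitter_ppm,
                 peak_sigma = peak_sigma, baseline_level = baseline_level,
                 baseline_wander = baseline_wander, bio_sigma = bio_sigma,
                 total_area = total_area, mz_range = mz_range,
                 grid_step = grid_step, n_isotopes = as.integer(n_isotopes)),
            class = "sim_design")
}

## Deterministic 31-bit sub-seed from the master seed and replicate indices,
## so any single spectrum can be regenerated in isolation.
derive_seed <- function(master_seed, group, bio, tech = 0L) {
  gi <- sum(utf8ToInt(as.character(group)))
  s <- (as.double(master_seed) %% 2147483647) +
    7919 * gi + 104729 * bio + 1299709 * tech
  as.integer(s %% 2147483647)
}

## Per-species log-normal abundance factors for one biological extract.
.bio_factors <- function(profile, design, master_seed, group, bio) {
  seed <- derive_seed(master_seed, group, bio, tech = 0L)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed(exp(stats::rnorm(nrow(profile), 0, design$bio_sigma)))
}

#' Simulate one MALDI-TOF-like spectrum
#'
#' Each profile species contributes a Gaussian isotopic envelope (abundances
#' from [isotope_pattern()]) centered at its theoretical sodiated m/z shifted
#' by the design's calibration drift. Species abundances are perturbed
#' log-normally per biological replicate (shared across technical
#' replicates); white noise and a slowly varying offset form the baseline.
#' The result is fully determined by `(seed, group, bio, tech)`.
#'
#' @param profile A [make_profile()] object.
#' @param design A [sim_design()] object.
#' @param bio,tech Replicate indices within the design.
#' @param group Group label (enters the derived seed).
#' @param seed Master seed (integer).
#' @return A list of class `glyco_spectrum` with elements `mz`, `intensity`
#'   and `meta` (provenance: group, bio, tech, seed, drift actually applied).
#' @export
simulate_spectrum <- function(profile, design = sim_design(), bio = 1L,
                              tech = 1L, group = "a", seed = 1L) {
  stopifnot(inherits(design, "sim_design"),
            bio >= 1L, bio <= design$n_bio, tech >= 1L, tech <= design$n_tech)
  bio_fac <- .bio_factors(profile, design, seed, group, bio)
  tech_seed <- derive_seed(seed, group, bio, tech)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(tech_seed)

  grid <- seq(design$mz_range[1], design$mz_range[2], by = design$grid_step)
  n <- length(grid)
  intensity <- numeric(n)
  drift <- design$drift_ppm + stats::rnorm(1, 0, design$drift_jitter_ppm)

  areas <- profile$fraction * bio_fac * design$total_area
  sig <- design$peak_sigma
  for (i in seq_len(nrow(profile))) {
    pat <- .iso_pattern_fast(profile$composition[i], design$n_isotopes)
    centers <- pat$mz * (1 + drift * 1e-6)
    for (k in seq_along(pat$mz)) {
      ctr <- centers[k]
      if (ctr < grid[1] || ctr > grid[n]) next
      lo <- max(1L, ceiling((ctr - 6 * sig - grid[1]) / design$grid_step) + 1L)
      hi <- min(n, floor((ctr + 6 * sig - grid[1]) / design$grid_step) + 1L)
      if (hi < lo) next
      idx <- lo:hi
      intensity[idx] <- intensity[idx] +
        areas[i] * pat$abundance[k] * stats::dnorm(grid[idx], ctr, sig)
    }
  }

  if (design$baseline_wander > 0) {
    phase <- stats::runif(2, 0, 2 * pi)
    wander <- design$baseline_wander *
      (1 + 0.5 * sin(2 * pi * grid / 1500 + phase[1]) +
         0.3 * sin(2 * pi * grid / 400 + phase[2]))
    intensity <- intensity + wander
  }
  if (design$baseline_level > 0) {
    intensity <- intensity + stats::rnorm(n, 0, design$baseline_level)
  }
  intensity <- pmax(intensity, 0)

  structure(list(mz = grid, intensity = intensity,
                 meta = list(group = group, bio = as.integer(bio),
                             tech = as.integer(tech), seed = as.integer(seed),
                             sub_seed = tech_seed, drift_ppm = drift)),
            class = "glyco_spectrum")
}

#' @export
print.glyco_spectrum <- function(x, ...) {
  cat(sprintf("<glyco_spectrum> %d points, m/z %.1f-%.1f, group=%s bio=%d tech=%d\n",
              length(x$mz), min(x$mz), max(x$mz),
              x$meta$group, x$meta$bio, x$meta$tech))
  invisible(x)
}

#' Simulate a two-group replicated cohort
#'
#' Generates `n_bio * n_tech` spectra per group with sub-seeds derived
#' deterministically from the master seed.
#'
#' @param profile_a,profile_b Profiles for the two groups (see
#'   [make_profile()]).
#' @param design A [sim_design()].
#' @param seed Master seed.
#' @param groups Labels for the two groups.
#' @return A list with `spectra` (list of `glyco_spectrum`) and `manifest`
#'   (tibble: index, group, bio, tech, sub_seed).
#' @export
simulate_cohort <- function(profile_a, profile_b, design = sim_design(),
                            seed = 1L, groups = c("a", "b")) {
  stopifnot(length(groups) == 2L)
  profiles <- list(profile_a, profile_b)
  spectra <- list()
  rows <- list()
  i <- 0L
  for (g in 1:2) {
    for (bio in seq_len(design$n_bio)) {
      for (tech in seq_len(design$n_tech)) {
        i <- i + 1L
        sp <- simulate_spectrum(profiles[[g]], design, bio, tech,
                                group = groups[g], seed = seed)
        spectra[[i]] <- sp
        rows[[i]] <- tibble::tibble(index = i, group = groups[g],
                                    bio = bio, tech = tech,
                                    sub_seed = sp$meta$sub_seed)
      }
    }
  }
  list(spectra = spectra, manifest = do.call(rbind, rows))
}
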