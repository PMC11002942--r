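#' Quality-control thresholds for annotated peaks
#'
#' Defaults follow the screening rule used throughout: an isotopic-fit score
#' of at least 0.95, a signal-to-noise ratio strictly greater than 2, and an
#' absolute mass error within the +/-20 ppm shift window.
#'
#' @param min_isotopic_score Minimum isotopic-fit score in \[0,1\].
#' @param min_sn Signal-to-noise threshold (comparison is strict, `> min_sn`).
#' @param max_abs_ppm Maximum absolute ppm error (inclusive).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_isotopic_score = 0.95, min_sn = 2, max_abs_ppm = 20) {
  stopifnot(min_isotopic_score >= 0, min_isotopic_score <= 1,
            min_sn > 0, max_abs_ppm > 0)
  structure(list(min_isotopic_score = min_isotopic_score, min_sn = min_sn,
                 max_abs_ppm = max_abs_ppm), class = "qc_thresholds")
}

#' Default internal calibrant compositions
#'
#' Univocal, consistently intense glycans spanning the lower working range,
#' used as internal standards for recalibration.
#' @return Character vector of composition strings.
#' @export
default_calibrants <- function() {
  c("H5N2", "H6N2", "H7N2", "H5N4", "H5N4F1", "H5N4F2", "H6N5F2")
}

## Coarse running-median baseline and running-MAD noise over the full
## spectrum (window ~10 Da, wide relative to peak width so peaks do not pull
## the estimates up). Used to nominate apex candidates; per-peak statistics
## for QC use the local annulus instead.
.coarse_baseline <- function(mz, intensity, window_da = 10) {
  step <- mz[2] - mz[1]
  k <- max(3L, as.integer(round(window_da / step)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(intensity) %% 2L == 1L) length(intensity) else length(intensity) - 1L)
  baseline <- stats::runmed(intensity, k, endrule = "constant")
  dev <- abs(intensity - baseline)
  noise <- 1.4826 * stats::runmed(dev, k, endrule = "constant")
  list(baseline = baseline, noise = noise)
}

## Local-maximum apex candidates above baseline + k * noise, de-clustered so
## that no two apexes lie within min_sep Da (highest wins).
.find_apexes <- function(mz, intensity, baseline, noise, k = 3, min_sep = 0.3) {
  n <- length(intensity)
  if (n < 3L) return(integer(0))
  is_max <- c(FALSE, intensity[2:(n - 1)] > intensity[1:(n - 2)] &
                intensity[2:(n - 1)] >= intensity[3:n], FALSE)
  cand <- which(is_max & (intensity - baseline) > k * pmax(noise, 1e-12))
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(intensity[cand], decreasing = TRUE)]
  out <- integer(0)
  for (i in ord) {
    if (length(out) > 0L && any(abs(mz[out] - mz[i]) < min_sep)) next
    out <- c(out, i)
  }
  sort(out)
}

#' Integrate one peak above a locally estimated baseline
#'
#' The baseline is the median intensity in a +/-`annulus_da` neighborhood of
#' the window (window itself excluded); the noise is the MAD of the same
#' points. The area is the trapezoidal integral of the baseline-subtracted
#' intensity over the window; S/N is the apex height above baseline divided
#' by the noise.
#'
#' @param spectrum A `glyco_spectrum` (or list with `mz`, `intensity`).
#' @param window Length-2 numeric, m/z limits of the peak window.
#' @param annulus_da Half-width of the background annulus (default 5 Da).
#' @return A list with `area`, `sn`, `baseline`, `noise`, `apex_mz`,
#'   `apex_height`.
#' @export
integrate_peak <- function(spectrum, window, annulus_da = 5) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  mz <- spectrum$mz; y <- spectrum$intensity
  if (window[1] < mz[1] || window[2] > mz[length(mz)]) {
    stop("window [", window[1], ", ", window[2], "] outside spectrum range")
  }
  in_win <- mz >= window[1] & mz <= window[2]
  if (!any(in_win)) stop("empty peak window")
  in_ann <- mz >= window[1] - annulus_da & mz <= window[2] + annulus_da & !in_win
  if (!any(in_ann)) in_ann <- !in_win
  baseline <- stats::median(y[in_ann])
  noise <- stats::mad(y[in_ann])
  yw <- y[in_win] - baseline
  xw <- mz[in_win]
  area <- if (length(xw) > 1L) sum(diff(xw) * (yw[-1] + yw[-length(yw)]) / 2) else 0
  apex_i <- which.max(y[in_win])
  height <- yw[apex_i]
  sn <- if (noise > 0) height / noise else if (height > 0) Inf else 0
  list(area = max(area, 0), sn = max(sn, 0),
       baseline = baseline, noise = noise,
       apex_mz = xw[apex_i], apex_height = height)
}

#' Isotopic-fit score between an observed and a theoretical envelope
#'
#' Cosine similarity between the observed isotopologue areas and the
#' theoretical pattern, both normalized to sum 1; 1 means identical shape,
#' 0 means orthogonal.
#'
#' @param observed Numeric vector of observed isotopologue areas (>= 2
#'   values; negative values are clamped to 0).
#' @param theoretical Either a numeric abundance vector of the same length or
#'   a composition (the pattern is computed with [isotope_pattern()]).
#' @return Score in \[0, 1\].
#' @export
isotopic_fit_score <- function(observed, theoretical) {
  if (length(observed) < 2L) stop("need at least 2 observed isotopologue areas")
  obs <- pmax(observed, 0)
  if (sum(obs) <= 0) stop("all-zero observed envelope")
  if (!is.numeric(theoretical)) {
    theoretical <- isotope_pattern(theoretical, length(obs))$abundance
  }
  stopifnot(length(theoretical) == length(obs))
  obs <- obs / sum(obs)
  theo <- theoretical / sum(theoretical)
  s <- sum(obs * theo) / sqrt(sum(obs^2) * sum(theo^2))
  min(max(s, 0), 1)
}

#' Internal recalibration against univocal calibrant glycans
#'
#' Matches observed peak m/z values to the theoretical m/z of the calibrant
#' compositions within a coarse pre-tolerance, fits a drift model (constant
#' ppm offset by default, or linear in m/z) by least squares on the ppm
#' residuals, and returns the model together with corrected m/z values.
#'
#' @param mz_observed Numeric vector of observed peak m/z values.
#' @param calibrants Character vector of calibrant composition strings
#'   (>= 3 must match).
#' @param pre_tol_ppm Coarse matching tolerance (default 50 ppm).
#' @param model `"constant"` or `"linear"`.
#' @return A list of class `calibration_model` with elements `model`, `coef`,
#'   `calibrants` (tibble: composition, mz_theoretical, mz_observed,
#'   ppm_before, ppm_after) and `mz_corrected` (full input vector corrected).
#' @export
recalibrate <- function(mz_observed, calibrants = default_calibrants(),
                        pre_tol_ppm = 50, model = c("constant", "linear")) {
  model <- match.arg(model)
  stopifnot(length(mz_observed) > 0, pre_tol_ppm > 0)
  theo <- theoretical_mz(calibrants)
  nearest <- vapply(theo, function(m) {
    i <- which.min(abs(mz_observed - m))
    if (abs(ppm_error(mz_observed[i], m)) <= pre_tol_ppm) i else NA_integer_
  }, integer(1))
  ok <- !is.na(nearest)
  if (sum(ok) < 3L) {
    stop("only ", sum(ok), " of ", length(calibrants),
         " calibrants matched within ", pre_tol_ppm,
         " ppm; at least 3 are required")
  }
  obs <- mz_observed[nearest[ok]]
  th <- theo[ok]
  ppm <- ppm_error(obs, th)
  coef <- if (model == "constant") {
    c(intercept = mean(ppm), slope = 0)
  } else {
    fit <- stats::lm(ppm ~ th)
    c(intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]))
  }
  predict_drift <- function(mz) coef[["intercept"]] + coef[["slope"]] * mz
  correct <- function(mz) mz / (1 + predict_drift(mz) * 1e-6)
  out <- structure(list(
    model = model, coef = coef,
    calibrants = tibble::tibble(
      composition = calibrants[ok], mz_theoretical = th, mz_observed = obs,
      ppm_before = ppm, ppm_after = ppm_error(correct(obs), th)
    ),
    mz_corrected = correct(mz_observed)
  ), class = "calibration_model")
  out
}

#' Apply (or invert) a fitted calibration model
#'
#' @param model A `calibration_model`.
#' @param mz m/z values to transform.
#' @param invert If `TRUE`, maps corrected m/z back to observed space.
#' @return Transformed m/z vector.
#' @export
apply_calibration <- function(model, mz, invert = FALSE) {
  drift <- model$coef[["intercept"]] + model$coef[["slope"]] * mz
  if (invert) mz * (1 + drift * 1e-6) else mz / (1 + drift * 1e-6)
}

#' QC filtering of annotated peaks
#'
#' A peak is kept iff its isotopic-fit score is at least the score threshold,
#' its S/N is strictly greater than the S/N threshold, and its absolute ppm
#' error is within the shift window. Rejections list every failed criterion.
#'
#' @param peaks A data frame with columns `isotopic_score`, `sn` and `ppm`.
#' @param thresholds A [qc_thresholds()] object.
#' @return The input with logical column `kept` and character column
#'   `reasons` (empty string when kept).
#' @export
qc_filter <- function(peaks, thresholds = qc_thresholds()) {
  stopifnot(all(c("isotopic_score", "sn", "ppm") %in% names(peaks)))
  score_ok <- !is.na(peaks$isotopic_score) &
    peaks$isotopic_score >= thresholds$min_isotopic_score
  sn_ok <- !is.na(peaks$sn) & peaks$sn > thresholds$min_sn
  ppm_ok <- !is.na(peaks$ppm) & abs(peaks$ppm) <= thresholds$max_abs_ppm
  reasons <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    r <- c(if (!score_ok[i]) "isotopic_score", if (!sn_ok[i]) "sn",
           if (!ppm_ok[i]) "ppm")
    reasons[i] <- paste(r, collapse = ";")
  }
  peaks$kept <- score_ok & sn_ok & ppm_ok
  peaks$reasons <- reasons
  peaks
}

#' Total-signal normalization
#'
#' Expresses each kept peak's area as a percentage of the summed areas:
#' `area / sum(areas) * 100`.
#'
#' @param areas Numeric vector of non-negative areas with positive sum.
#' @return Percentages summing to 100.
#' @export
normalize_tic <- function(areas) {
  if (length(areas) == 0L) stop("no kept peaks to normalize")
  if (any(areas < 0)) stop("areas must be non-negative")
  total <- sum(areas)
  if (total <= 0) stop("total area is zero; nothing to normalize")
  areas / total * 100
}

#' Process one spectrum into an annotated, QC-filtered, normalized peak table
#'
#' The full per-spectrum pipeline: apex picking above a coarse baseline,
#' suppression of isotopologue apexes, internal recalibration against the
#' calibrant glycans, per-peak integration (area, S/N) over the isotopic
#' envelope, candidate composition assignment within `tol_ppm`, isotopic-fit
#' scoring, QC filtering, and total-signal normalization of the kept peaks.
#'
#' @param spectrum A `glyco_spectrum` or a list with `mz` and `intensity`.
#' @param calibrants Calibrant composition strings (default
#'   [default_calibrants()]).
#' @param thresholds [qc_thresholds()].
#' @param tol_ppm Candidate-assignment tolerance (default 20 ppm).
#' @param bounds [enum_bounds()] for enumeration.
#' @param int_halfwidth Integration half-width per isotopologue window in Da
#'   (default 0.15).
#' @param n_isotopes Isotopologue windows integrated per peak (default 4).
#' @return A tibble with one row per apex: `mz_observed`, `mz_corrected`,
#'   `area`, `sn`, `isotopic_score`, `ppm`, `composition` (best candidate),
#'   `candidates` (semicolon-joined), `n_candidates`, `kept`, `reasons`,
#'   `percent` (NA for rejected peaks). The calibration model is attached as
#'   attribute `"calibration"`.
#' @export
process_spectrum <- function(spectrum, calibrants = default_calibrants(),
                             thresholds = qc_thresholds(), tol_ppm = 20,
                             bounds = enum_bounds(), int_halfwidth = 0.15,
                             n_isotopes = 4L) {
  mz <- spectrum$mz; y <- spectrum$intensity
  cb <- .coarse_baseline(mz, y)
  apex <- .find_apexes(mz, y, cb$baseline, cb$noise)
  if (length(apex) == 0L) stop("no peaks found above the noise level")

  ## suppress apexes that sit one isotope spacing above a taller apex
  iso_spacing <- 1.00336
  heights <- y[apex] - cb$baseline[apex]
  is_isotopologue <- vapply(seq_along(apex), function(i) {
    d <- mz[apex[i]] - mz[apex]
    any(abs(d - iso_spacing) < 0.08 & heights > 0.55 * heights[i])
  }, logical(1))
  apex <- apex[!is_isotopologue]

  ## refine each apex by log-parabolic (Gaussian) interpolation of the three
  ## grid points around the local maximum; exact for a Gaussian peak on a
  ## flat baseline, and reduces the grid-quantization error (up to half a
  ## grid step) to well below 1 ppm
  step0 <- mz[2] - mz[1]
  mz_apex <- vapply(apex, function(j) {
    if (j <= 1L || j >= length(mz)) return(mz[j])
    yy <- y[c(j - 1L, j, j + 1L)] - cb$baseline[c(j - 1L, j, j + 1L)]
    if (any(yy <= 0)) return(mz[j])
    ly <- log(yy)
    denom <- ly[1] - 2 * ly[2] + ly[3]
    if (denom >= 0) return(mz[j])
    delta <- 0.5 * (ly[1] - ly[3]) / denom
    if (abs(delta) > 1) return(mz[j])
    mz[j] + delta * step0
  }, numeric(1))

  cal <- recalibrate(mz_apex, calibrants)
  mz_obs <- mz_apex
  mz_cor <- cal$mz_corrected

  n <- length(apex)
  area <- sn <- score <- ppmv <- rep(NA_real_, n)
  best <- cands <- rep(NA_character_, n)
  ncand <- integer(n)
  step <- mz[2] - mz[1]
  npts <- length(mz)
  ## index window on the uniform grid: [center - hw, center + hw]
  idx_window <- function(center, hw) {
    lo <- max(1L, as.integer(ceiling((center - hw - mz[1]) / step)) + 1L)
    hi <- min(npts, as.integer(floor((center + hw - mz[1]) / step)) + 1L)
    if (hi < lo) NULL else lo:hi
  }
  trapz <- function(idx, baseline) {
    yw <- y[idx] - baseline
    step * sum((yw[-1] + yw[-length(yw)]) / 2)
  }
  annulus_hw <- 5
  tab <- composition_table(bounds)
  for (i in seq_len(n)) {
    hit_idx <- .match_compositions(mz_cor[i], tol_ppm, tab)
    ncand[i] <- length(hit_idx)
    win <- idx_window(mz_obs[i], int_halfwidth)
    if (length(hit_idx) == 0L) {
      ## no candidate composition: the peak can never be kept, so the cheap
      ## coarse baseline/noise estimate is sufficient for reporting
      baseline <- cb$baseline[apex[i]]
      noise <- cb$noise[apex[i]]
      sn[i] <- if (noise > 0) (max(y[win]) - baseline) / noise else Inf
      area[i] <- max(trapz(win, baseline), 0)
      next
    }
    ## local baseline/noise from the +/-5 Da annulus, peak window excluded
    ann <- idx_window(mz_obs[i], annulus_hw)
    ann <- setdiff(ann, win)
    baseline <- stats::median(y[ann])
    noise <- stats::mad(y[ann])
    height <- max(y[win]) - baseline
    sn[i] <- if (noise > 0) height / noise else Inf
    best[i] <- tab$composition[hit_idx[1]]
    cands[i] <- paste(tab$composition[hit_idx], collapse = ";")
    ppmv[i] <- ppm_error(mz_cor[i], tab$mz[hit_idx[1]])
    pat <- .iso_pattern_fast(best[i], n_isotopes)
    offsets <- pat$mz - pat$mz[1]
    env_areas <- vapply(offsets, function(off) {
      w <- idx_window(mz_obs[i] + off, int_halfwidth)
      if (is.null(w)) return(0)
      trapz(w, baseline)
    }, numeric(1))
    area[i] <- max(sum(env_areas), 0)
    score[i] <- tryCatch(isotopic_fit_score(env_areas, pat$abundance),
                         error = function(e) 0)
  }

  out <- tibble::tibble(
    mz_observed = mz_obs, mz_corrected = mz_cor, area = area, sn = sn,
    isotopic_score = score, ppm = ppmv, composition = best,
    candidates = cands, n_candidates = ncand
  )
  out <- qc_filter(out, thresholds)
  out$reasons[out$n_candidates == 0L & !out$kept] <-
    paste0("no_candidate;", out$reasons[out$n_candidates == 0L & !out$kept])
  out$percent <- NA_real_
  if (any(out$kept)) out$percent[out$kept] <- normalize_tic(out$area[out$kept])
  attr(out, "calibration") <- cal
  out
}
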