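#' Average technical replicates within biological replicates
#'
#' Technical replicates are averaged (arithmetic mean) within each
#' (group, biological replicate) cell; biological replicates remain separate
#' as the statistical unit, so downstream tests never see technical
#' pseudo-replication.
#'
#' @param trait_tables A data frame with columns `group`, `bio`, `tech` and
#'   one numeric column per trait.
#' @return A tibble with one row per (group, bio) and the averaged trait
#'   columns.
#' @export
average_replicates <- function(trait_tables) {
  stopifnot(all(c("group", "bio") %in% names(trait_tables)))
  value_cols <- setdiff(names(trait_tables), c("group", "bio", "tech", "index"))
  cells <- unique(trait_tables[, c("group", "bio")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trait_tables[trait_tables$group == cells$group[i] &
                          trait_tables$bio == cells$bio[i], value_cols,
                        drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("biological replicate (group=", cells$group[i], ", bio=",
           cells$bio[i], ") has no surviving technical spectra")
    }
    cbind(cells[i, ], as.data.frame(as.list(colMeans(sub))))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' PCA score screening with a Hotelling T-squared 95% ellipse
#'
#' Mean-centered PCA of the sample-by-signal matrix; Hotelling's T-squared is
#' computed on the first two score components and compared with the
#' F-distribution-based critical value at level `alpha`. Samples beyond the
#' ellipse are listed for exclusion.
#'
#' @param x Numeric matrix or data frame, samples in rows (>= 3), signals in
#'   columns (>= 2).
#' @param alpha Significance level of the ellipse (default 0.05).
#' @return A list of class `outlier_screen`: `scores` (first two components),
#'   `explained_variance` (fractions per component), `t2` (per sample),
#'   `t2_critical`, `excluded` (row indices), `alpha`.
#' @export
pca_hotelling_screen <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples for outlier screening, got ", n)
  if (ncol(x) < 2L) stop("need at least 2 signals")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  s2 <- apply(scores, 2, stats::var)
  s2 <- pmax(s2, .Machine$double.eps)
  t2 <- rowSums(sweep(scores^2, 2, s2, "/"))
  ## in-model critical value (screening the samples the model was built on),
  ## not the more conservative prediction form for future samples
  crit <- (k * (n - 1)) / (n - k) * stats::qf(1 - alpha, k, n - k)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, explained_variance = ev, t2 = t2,
                 t2_critical = crit, excluded = which(t2 > crit),
                 alpha = alpha), class = "outlier_screen")
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf("<outlier_screen> %d samples, T2 crit %.2f (alpha %.2f), %d excluded\n",
              length(x$t2), x$t2_critical, x$alpha, length(x$excluded)))
  invisible(x)
}

.signif_flag <- function(p) {
  ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))
}

#' Compare derived traits between two groups of biological replicates
#'
#' Two-sample, two-sided Student's t-test (pooled variance by default; Welch
#' as option) per trait column, with the significance convention
#' `*` for p <= 0.05 and `**` for p <= 0.01. Degenerate traits with zero
#' variance in both groups and equal means are reported as p = 1.
#'
#' @param reference,test Data frames of per-biological-replicate trait values
#'   (>= 2 rows each); non-trait columns `group`, `bio`, `tech`, `index` are
#'   ignored.
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance Student's t-test.
#' @return A tibble with columns `trait`, `mean_ref`, `sd_ref`, `mean_test`,
#'   `sd_test`, `delta` (test - reference), `t`, `p`, `flag`.
#' @export
compare_groups <- function(reference, test, welch = FALSE) {
  drop <- c("group", "bio", "tech", "index")
  ref <- as.data.frame(reference)[, setdiff(names(reference), drop), drop = FALSE]
  tst <- as.data.frame(test)[, setdiff(names(test), drop), drop = FALSE]
  stopifnot(identical(names(ref), names(tst)))
  if (nrow(ref) < 2L || nrow(tst) < 2L) {
    stop("need at least 2 biological replicates per group")
  }
  rows <- lapply(names(ref), function(tr) {
    a <- ref[[tr]]; b <- tst[[tr]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tstat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(b) - mean(a))
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      ht <- stats::t.test(b, a, var.equal = !welch)
      tstat <- unname(ht$statistic)
      p <- ht$p.value
    }
    tibble::tibble(trait = tr, mean_ref = mean(a), sd_ref = stats::sd(a),
                   mean_test = mean(b), sd_test = stats::sd(b),
                   delta = mean(b) - mean(a), t = tstat, p = p,
                   flag = .signif_flag(p))
  })
  do.call(rbind, rows)
}

#' Run the full two-group pipeline on a synthetic cohort
#'
#' Convenience driver: simulates a two-group cohort, processes every
#' spectrum (recalibration, QC, normalization), aggregates derived traits,
#' optionally screens technical spectra with the PCA/Hotelling ellipse,
#' averages technical into biological replicates, and compares the groups.
#'
#' @param profile_a,profile_b Group profiles ([make_profile()]).
#' @param design A [sim_design()].
#' @param seed Master seed.
#' @param rules [trait_rules()].
#' @param thresholds [qc_thresholds()].
#' @param calibrants Calibrant compositions.
#' @param screen Apply the Hotelling screen (within each group) to
#'   per-spectrum normalized signals and drop flagged spectra before
#'   averaging (default `FALSE`).
#' @return A list with `traits` (per-spectrum trait table with design
#'   labels), `biological` (averaged per biological replicate), `comparison`
#'   (from [compare_groups()], group a as reference), and `screen` (a list of
#'   per-group `outlier_screen` objects, or `NULL`).
#' @export
run_cohort_pipeline <- function(profile_a, profile_b, design = sim_design(),
                                seed = 1L, rules = trait_rules(),
                                thresholds = qc_thresholds(),
                                calibrants = default_calibrants(),
                                screen = FALSE) {
  cohort <- simulate_cohort(profile_a, profile_b, design, seed)
  peak_tables <- lapply(cohort$spectra, process_spectrum,
                        calibrants = calibrants, thresholds = thresholds)
  trait_rows <- lapply(seq_along(peak_tables), function(i) {
    tr <- aggregate_traits(peak_tables[[i]], rules)
    cbind(cohort$manifest[i, c("group", "bio", "tech")], tr)
  })
  traits <- tibble::as_tibble(do.call(rbind, trait_rows))

  ## screening is per group: between-group separation is biological signal,
  ## not an outlying replicate
  screen_res <- NULL
  if (screen) {
    sig <- .signal_matrix(peak_tables)
    grp <- cohort$manifest$group
    screen_res <- lapply(unique(grp), function(g) {
      idx <- which(grp == g)
      scr <- pca_hotelling_screen(sig[idx, , drop = FALSE])
      scr$sample_index <- idx
      scr
    })
    names(screen_res) <- unique(grp)
    drop_idx <- unlist(lapply(screen_res, function(s) s$sample_index[s$excluded]))
    if (length(drop_idx) > 0L) traits <- traits[-drop_idx, , drop = FALSE]
  }

  biological <- average_replicates(traits)
  groups <- unique(biological$group)
  comparison <- compare_groups(
    biological[biological$group == groups[1], , drop = FALSE],
    biological[biological$group == groups[2], , drop = FALSE]
  )
  list(traits = traits, biological = biological, comparison = comparison,
       screen = screen_res)
}

## Spectra x signals matrix of normalized percentages on the union of kept
## compositions (absent signals as 0 for the multivariate screen).
.signal_matrix <- function(peak_tables) {
  kept <- lapply(peak_tables, function(p) p[p$kept, c("composition", "percent")])
  all_comp <- sort(unique(unlist(lapply(kept, function(k) k$composition))))
  m <- matrix(0, nrow = length(kept), ncol = length(all_comp),
              dimnames = list(NULL, all_comp))
  for (i in seq_along(kept)) {
    m[i, kept[[i]]$composition] <- kept[[i]]$percent
  }
  m
}
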