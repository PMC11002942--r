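# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (nested loops instead of the sorted-table lookup,
# atom-by-atom convolution instead of exponentiation-by-squaring, closed-form
# t statistics instead of t.test).

# Brute-force composition enumeration: nested loops over all count tuples.
brute_force_enumeration <- function(mz, tol_ppm, bounds, biosynthetic = TRUE) {
  found <- character(0)
  for (h in bounds$hex[1]:bounds$hex[2])
    for (n in bounds$hexnac[1]:bounds$hexnac[2])
      for (f in bounds$fuc[1]:bounds$fuc[2])
        for (e in bounds$eneuac[1]:bounds$eneuac[2])
          for (l in bounds$lneuac[1]:bounds$lneuac[2]) {
            if (h + n + f + e + l < 1) next
            if (biosynthetic) {
              if (n < 2) next
              if (e + l > max(n - 2, 0)) next
              if (f > n) next
            }
            th <- residue_mass("Hex") * h + residue_mass("HexNAc") * n +
              residue_mass("Fuc") * f + residue_mass("ENeuAc") * e +
              residue_mass("LNeuAc") * l + mass_water() + mass_sodium_cation()
            if (abs((mz - th) / th * 1e6) <= tol_ppm) {
              s <- paste0("H", h, "N", n,
                          if (f > 0) paste0("F", f) else "",
                          if (e > 0) paste0("E", e) else "",
                          if (l > 0) paste0("L", l) else "")
              found <- c(found, s)
            }
          }
  sort(found)
}

# Naive isotope-distribution oracle: convolve the full spectrum one atom at a
# time on the nominal-mass lattice (probabilities only).
naive_isotope_abundances <- function(formula, n_peaks) {
  atom_dist <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205)
  )
  p <- 1
  for (el in names(atom_dist)) {
    n_at <- formula[[el]]
    if (is.null(n_at) || n_at == 0) next
    for (i in seq_len(n_at)) {
      p <- convolve(p, rev(atom_dist[[el]]), type = "open")
      if (length(p) > n_peaks + 4) p <- p[seq_len(n_peaks + 4)]
    }
  }
  p <- p[seq_len(n_peaks)]
  p / sum(p)
}

# Elemental formula (C, H, N, O) of a composition string plus reducing-end water.
formula_of <- function(comp) {
  counts <- sapply(c("H", "N", "F", "E", "L"), function(ltr) {
    m <- regmatches(comp, regexpr(paste0(ltr, "[0-9]+"), comp))
    if (length(m) == 0) 0L else as.integer(substring(m, 2))
  })
  res <- rbind(
    H = c(C = 6, H = 10, N = 0, O = 5),
    N = c(C = 8, H = 13, N = 1, O = 5),
    F = c(C = 6, H = 10, N = 0, O = 4),
    E = c(C = 13, H = 21, N = 1, O = 8),
    L = c(C = 11, H = 15, N = 1, O = 7)
  )
  as.list(colSums(res * counts) + c(C = 0, H = 2, N = 0, O = 1))
}

# Closed-form pooled-variance two-sample t-test.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), na + nb - 2)
  list(t = t, p = p)
}

# Small noise-free design for fast deterministic end-to-end checks;
# overrides win over the quiet defaults.
quiet_design <- function(...) {
  args <- utils::modifyList(
    list(drift_ppm = 0, drift_jitter_ppm = 0, baseline_level = 0,
         baseline_wander = 0, bio_sigma = 0),
    list(...)
  )
  do.call(sim_design, args)
}
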