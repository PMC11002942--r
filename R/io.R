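#' Write / read a spectrum as two-column delimited text
#'
#' Spectra are stored as tab-separated `mz`, `intensity` columns preceded by
#' `#`-prefixed header comments carrying provenance (group, replicate
#' indices, seed).
#'
#' @param spectrum A `glyco_spectrum`.
#' @param file Path to write to / read from.
#' @return `write_spectrum` returns `file` invisibly; `read_spectrum`
#'   returns a `glyco_spectrum`.
#' @export
write_spectrum <- function(spectrum, file) {
  meta <- spectrum$meta
  hdr <- character(0)
  if (!is.null(meta)) {
    hdr <- vapply(names(meta), function(k) {
      sprintf("# %s=%s", k, format(meta[[k]], digits = 15))
    }, character(1))
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("mz\tintensity", con)
  utils::write.table(
    data.frame(mz = spectrum$mz, intensity = signif(spectrum$intensity, 9)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(file)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(file) {
  lines <- readLines(file)
  is_comment <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_comment]) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) {
      v <- type.convert(kv[2], as.is = TRUE)
      meta[[kv[1]]] <- v
    }
  }
  body <- lines[!is_comment]
  if (length(body) > 0L && grepl("^mz\\b", body[1])) body <- body[-1]
  dat <- utils::read.table(text = body, sep = "\t", col.names = c("mz", "intensity"))
  if (is.unsorted(dat$mz, strictly = TRUE)) {
    stop("spectrum m/z values must be strictly increasing in ", file)
  }
  structure(list(mz = dat$mz, intensity = dat$intensity, meta = meta),
            class = "glyco_spectrum")
}

#' Write a simulated cohort to disk
#'
#' Writes one spectrum file per replicate plus a tab-separated manifest
#' (`file`, `group`, `bio`, `tech`, `sub_seed`).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with a `file` column) invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  man$file <- sprintf("spectrum_%s_b%d_t%d.tsv", man$group, man$bio, man$tech)
  for (i in seq_len(nrow(man))) {
    write_spectrum(cohort$spectra[[i]], file.path(dir, man$file[i]))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' Read a pre-picked peak list
#'
#' Accepts delimited text with at least columns `mz` and `area`; optional
#' columns `sn`, `isotopic_score` are carried through.
#'
#' @param file Path to a delimited file (tab or comma separated).
#' @return A tibble of peaks.
#' @export
read_peak_list <- function(file) {
  first <- readLines(file, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  dat <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("mz", "area") %in% names(dat))) {
    stop("peak list must have columns 'mz' and 'area': ", file)
  }
  tibble::as_tibble(dat)
}

#' Write an annotated peak table or trait/comparison table
#'
#' @param x A data frame (annotated peaks, trait table, cohort comparison).
#' @param file Output path; tab-separated with a header row.
#' @return `file`, invisibly.
#' @export
write_table_tsv <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a SILAC peptide table
#'
#' Delimited text with columns `protein`, `peptide`, `ratio`, `prolines`,
#' `unique`.
#'
#' @param file Path to the table.
#' @return A tibble suitable for [quantify_experiment()].
#' @export
read_peptide_table <- function(file) {
  first <- readLines(file, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  dat <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("protein", "peptide", "ratio", "prolines", "unique")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols) > 0L) {
    stop("peptide table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  dat$unique <- as.logical(dat$unique)
  tibble::as_tibble(dat)
}
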