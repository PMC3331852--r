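#' Construct a centroided MS/MS spectrum
#'
#' @param spectrum_id Character identifier.
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Integer precursor charge.
#' @param mz,intensity Parallel numeric vectors of peak positions (Th) and
#'   intensities (arbitrary units, non-negative). Peaks are stored sorted
#'   ascending by m/z.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, precursor_charge,
                     mz, intensity) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1,
            all(intensity >= 0), precursor_charge >= 1)
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 mz = mz[o], intensity = intensity[o]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  precursor %.4f (%d+)  %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$precursor_charge,
              length(x$mz)))
  invisible(x)
}

bin_sqrt_intensities <- function(s, bin_width) {
  bins <- floor(s$mz / bin_width)
  v <- tapply(sqrt(s$intensity), bins, sum)
  v
}

#' Spectral similarity (normalized dot product)
#'
#' Cosine similarity of square-root intensities aggregated onto m/z bins of
#' fixed width. 1 for identical spectra, 0 for spectra sharing no bin.
#' Symmetric and invariant to uniform intensity scaling.
#'
#' @param a,b [spectrum()] objects.
#' @param bin_width Bin width in Th.
#' @return Score in `[0, 1]`.
#' @export
spectrum_similarity <- function(a, b, bin_width = 0.05) {
  va <- bin_sqrt_intensities(a, bin_width)
  vb <- bin_sqrt_intensities(b, bin_width)
  keys <- union(names(va), names(vb))
  xa <- rep(0, length(keys)); names(xa) <- keys
  xb <- xa
  xa[names(va)] <- va
  xb[names(vb)] <- vb
  na <- sqrt(sum(xa^2)); nb <- sqrt(sum(xb^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(0, sum(xa * xb) / (na * nb)))
}

#' Select the representative spectrum of a replicate cluster
#'
#' Returns the index of the spectrum whose mean similarity to all other
#' cluster members is highest — the spectrum that is, on average, most like
#' the others. A singleton cluster returns itself. Exact ties are broken by
#' the lexicographically smallest `spectrum_id`, so builds are
#' deterministic.
#'
#' @param spectra Non-empty list of [spectrum()] objects.
#' @param bin_width Similarity bin width in Th.
#' @return Integer index into `spectra`.
#' @export
select_representative <- function(spectra, bin_width = 0.05) {
  n <- length(spectra)
  if (n == 0) stop("empty spectrum list")
  if (n == 1) return(1L)
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      sim[i, j] <- sim[j, i] <- spectrum_similarity(spectra[[i]],
                                                    spectra[[j]], bin_width)
    }
  }
  mean_sim <- (rowSums(sim) - 1) / (n - 1)
  best <- which(mean_sim >= max(mean_sim) - 1e-12)
  ids <- vapply(spectra[best], `[[`, character(1), "spectrum_id")
  best[order(ids)[1]]
}

#' Build a spectral library from filtered identifications and spectra
#'
#' Groups retained identifications by peptide ion
#' (sequence, charge, modification state), selects a representative spectrum
#' per ion, and records the replicate count. Every record's `spectrum_id`
#' must resolve in `spectra`.
#'
#' @param records Retained target [id_records()].
#' @param spectra List of [spectrum()] objects (named by id, or the ids are
#'   taken from the objects).
#' @param metadata Optional provenance list (filter config, FDR report, ...)
#'   stored with the library.
#' @return An object of class `"spectral_library"`: a list with `entries`
#'   (each holding `key`, `sequence`, `charge`, `mod_key`, `representative`,
#'   `copy_count`, `best_confidence`) and `metadata`.
#' @export
build_library <- function(records, spectra, metadata = list()) {
  ids <- vapply(spectra, `[[`, character(1), "spectrum_id")
  names(spectra) <- ids
  missing <- setdiff(records$spectrum_id, ids)
  if (length(missing))
    stop("dangling spectrum reference(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  keys <- ion_keys(records)
  entries <- lapply(split(seq_len(nrow(records)), keys), function(idx) {
    reps <- spectra[records$spectrum_id[idx]]
    sel <- select_representative(unname(reps))
    list(key = keys[idx[1]],
         sequence = records$sequence[idx[1]],
         charge = records$charge[idx[1]],
         mod_key = mod_key(records$modifications[[idx[1]]]),
         representative = reps[[sel]],
         copy_count = length(idx),
         best_confidence = max(records$confidence[idx]))
  })
  metadata$build_time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  structure(list(entries = sort_entries(entries), metadata = metadata),
            class = "spectral_library")
}

sort_entries <- function(entries) {
  if (length(entries)) entries[order(names(entries))] else entries
}

#' @export
print.spectral_library <- function(x, ...) {
  seqs <- unique(vapply(x$entries, `[[`, character(1), "sequence"))
  cat(sprintf("<spectral_library> %d peptide ions, %d unique sequences\n",
              length(x$entries), length(seqs)))
  invisible(x)
}

#' Number of peptide-ion entries / unique sequences in a library
#'
#' @param library A `spectral_library`.
#' @return Named integer vector with `ions` and `sequences`.
#' @export
library_counts <- function(library) {
  c(ions = length(library$entries),
    sequences = length(unique(vapply(library$entries, `[[`,
                                     character(1), "sequence"))))
}

#' Look up a library entry by sequence and charge
#'
#' @param library A `spectral_library`.
#' @param sequence Peptide sequence.
#' @param charge Precursor charge.
#' @return The matching entry, or `NULL`.
#' @export
library_entry <- function(library, sequence, charge) {
  for (e in library$entries)
    if (e$sequence == sequence && e$charge == charge) return(e)
  NULL
}
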