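#' Filter configuration for library inclusion
#'
#' Defaults implement the inclusion rules used when building a high-confidence
#' native-peptide library: search confidence at least 0.95; observed precursor
#' neutral mass within 0.2 Da of the theoretical monoisotopic mass or of the
#' isotope-cluster peak one or two 13C up; and no modifications other than
#' oxidation and pyroglutamate on N-terminal Glu/Gln.
#'
#' @param min_confidence Minimum search-engine confidence (probability).
#' @param mass_tolerance Neutral-mass tolerance in Da.
#' @param isotope_errors Integer 13C-offset errors tolerated on the observed
#'   mass (no negative offsets).
#' @param allowed_modifications Character vector of permitted modification
#'   names (see [MOD_DELTAS]).
#' @param decoy_prefix Protein-accession prefix marking decoy hits.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_confidence = 0.95,
                          mass_tolerance = 0.2,
                          isotope_errors = 0:2,
                          allowed_modifications = names(MOD_DELTAS),
                          decoy_prefix = "DECOY_") {
  stopifnot(mass_tolerance > 0, all(isotope_errors >= 0),
            min_confidence >= 0, min_confidence <= 1)
  structure(list(min_confidence = min_confidence,
                 mass_tolerance = mass_tolerance,
                 isotope_errors = as.integer(isotope_errors),
                 allowed_modifications = allowed_modifications,
                 decoy_prefix = decoy_prefix),
            class = "filter_config")
}

empty_records <- function() {
  data.frame(spectrum_id = character(), sequence = character(),
             charge = integer(), confidence = numeric(),
             observed_neutral_mass = numeric(), is_decoy = logical(),
             proteins = character(), modifications = I(list()),
             stringsAsFactors = FALSE)
}

#' Construct a normalized identification-record table
#'
#' One row per peptide-spectrum match. `modifications` is a list column; each
#' element is `NULL` or a data.frame with `position`, `mass_delta`, `name`.
#'
#' @param spectrum_id,sequence,charge,confidence,observed_neutral_mass,is_decoy,proteins
#'   Parallel vectors, one element per match.
#' @param modifications List of per-record modification tables (or `NULL`s).
#' @return A data.frame of class `"id_records"`.
#' @export
id_records <- function(spectrum_id, sequence, charge, confidence,
                       observed_neutral_mass, is_decoy = FALSE,
                       proteins = "", modifications = NULL) {
  n <- length(spectrum_id)
  if (is.null(modifications)) modifications <- vector("list", n)
  stopifnot(all(confidence >= 0 & confidence <= 1),
            all(observed_neutral_mass > 0))
  out <- data.frame(spectrum_id = as.character(spectrum_id),
                    sequence = as.character(sequence),
                    charge = as.integer(charge),
                    confidence = as.numeric(confidence),
                    observed_neutral_mass = as.numeric(observed_neutral_mass),
                    is_decoy = rep_len(as.logical(is_decoy), n),
                    proteins = rep_len(as.character(proteins), n),
                    stringsAsFactors = FALSE)
  out$modifications <- modifications
  class(out) <- c("id_records", class(out))
  out
}

record_peptide <- function(sequence, modifications = NULL) {
  peptide(sequence, modifications = modifications)
}

#' Theoretical neutral mass of each identification
#'
#' @param records An [id_records()] table.
#' @return Numeric vector of monoisotopic masses (Da).
#' @export
theoretical_masses <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    monoisotopic_mass(record_peptide(records$sequence[i],
                                     records$modifications[[i]]))
  }, numeric(1))
}

#' Apply library-inclusion filters to identification records
#'
#' A record is retained iff its confidence passes, its observed neutral mass
#' lies within tolerance of the theoretical mass for at least one permitted
#' 13C isotope offset, and all of its modifications are whitelisted
#' (pyroglutamate only at residue 1). Decoy records passing the same rules
#' are routed to FDR estimation, never to the library. Rejections carry the
#' first failing rule, tested in the order confidence, mass, modification.
#'
#' @param records An [id_records()] table.
#' @param config A [filter_config()].
#' @return List with elements `retained` (target records), `decoys`
#'   (decoy records passing the same filters) and `rejected` (a data.frame
#'   with `spectrum_id`, `sequence`, `is_decoy`, `reason`).
#' @export
filter_identifications <- function(records, config = filter_config()) {
  if (nrow(records) == 0)
    return(list(retained = records, decoys = records,
                rejected = data.frame(spectrum_id = character(),
                                      sequence = character(),
                                      is_decoy = logical(),
                                      reason = character())))
  theo <- theoretical_masses(records)
  reason <- rep(NA_character_, nrow(records))
  conf_ok <- records$confidence >= config$min_confidence
  reason[!conf_ok] <- "confidence"
  mass_err <- vapply(seq_len(nrow(records)), function(i) {
    min(abs(records$observed_neutral_mass[i] - theo[i] -
              config$isotope_errors * MASS_CONSTANTS$d13C))
  }, numeric(1))
  mass_ok <- mass_err <= config$mass_tolerance
  reason[is.na(reason) & !mass_ok] <- "mass"
  mod_ok <- vapply(seq_len(nrow(records)), function(i) {
    m <- records$modifications[[i]]
    if (is.null(m) || nrow(m) == 0) return(TRUE)
    if (!all(m$name %in% config$allowed_modifications)) return(FALSE)
    pyro <- grepl("^pyro-glu", m$name)
    all(m$position[pyro] %in% c(0L, 1L))
  }, logical(1))
  reason[is.na(reason) & !mod_ok] <- "modification"
  pass <- is.na(reason)
  rejected <- data.frame(spectrum_id = records$spectrum_id[!pass],
                         sequence = records$sequence[!pass],
                         is_decoy = records$is_decoy[!pass],
                         reason = reason[!pass],
                         stringsAsFactors = FALSE)
  list(retained = records[pass & !records$is_decoy, , drop = FALSE],
       decoys   = records[pass & records$is_decoy, , drop = FALSE],
       rejected = rejected)
}

mod_key <- function(m) {
  if (is.null(m) || nrow(m) == 0) return("")
  m <- m[order(m$position), , drop = FALSE]
  paste(sprintf("%d:%+.4f", m$position, m$mass_delta), collapse = ",")
}

#' Ion keys for identification records
#'
#' A peptide ion is a distinct (sequence, charge, modification state).
#'
#' @param records An [id_records()] table.
#' @return Character vector of keys.
#' @export
ion_keys <- function(records) {
  mods <- vapply(records$modifications, mod_key, character(1))
  sprintf("%s/%d%s", records$sequence, records$charge,
          ifelse(nzchar(mods), paste0("[", mods, "]"), ""))
}

#' Collapse identifications to the spectrum, ion and peptide levels
#'
#' Spectra are individual matches; ions are distinct
#' (sequence, charge, modification state); peptides are distinct sequences.
#' An ion or peptide is counted as decoy iff all supporting records are
#' decoy.
#'
#' @param records An [id_records()] table.
#' @return List of data.frames `spectra`, `ions`, `peptides`, each with a
#'   `key` and an `is_decoy` column.
#' @export
collapse_levels <- function(records) {
  collapse_one <- function(keys) {
    if (length(keys) == 0)
      return(data.frame(key = character(), is_decoy = logical()))
    dec <- tapply(records$is_decoy, keys, all)
    data.frame(key = names(dec), is_decoy = as.logical(dec),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(spectra = data.frame(key = records$spectrum_id,
                            is_decoy = records$is_decoy,
                            stringsAsFactors = FALSE),
       ions = collapse_one(ion_keys(records)),
       peptides = collapse_one(records$sequence))
}

#' Estimate spectrum-, ion- and peptide-level FDR from target-decoy counts
#'
#' At each level the estimate is `decoy_count / target_count`, capped at 1.
#' With zero targets at a level the FDR is undefined (`NA`) and flagged.
#'
#' @param records An [id_records()] table containing both target and decoy
#'   matches that survived the inclusion filters.
#' @return A data.frame of class `"fdr_report"` with columns `level`,
#'   `target_count`, `decoy_count`, `fdr`.
#' @export
estimate_fdr <- function(records) {
  lv <- collapse_levels(records)
  rows <- lapply(c("spectra", "ions", "peptides"), function(nm) {
    d <- sum(lv[[nm]]$is_decoy)
    t <- sum(!lv[[nm]]$is_decoy)
    data.frame(level = sub("s$|^spectra$", "", c(spectra = "spectrum",
                                                 ions = "ion",
                                                 peptides = "peptide")[[nm]]),
               target_count = t, decoy_count = d,
               fdr = if (t == 0) NA_real_ else min(1, d / t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$fdr))
    attr(out, "undefined_levels") <- out$level[is.na(out$fdr)]
  class(out) <- c("fdr_report", class(out))
  out
}

#' Write an FDR report as JSON
#'
#' @param report An `fdr_report` from [estimate_fdr()].
#' @param path Output file path.
#' @export
write_fdr_json <- function(report, path) {
  x <- lapply(seq_len(nrow(report)), function(i)
    list(target_count = report$target_count[i],
         decoy_count = report$decoy_count[i],
         fdr = report$fdr[i]))
  names(x) <- report$level
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
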