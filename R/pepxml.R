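# pepXML subset reader/writer.
#
# The dialect covers the elements this pipeline needs:
#   msms_pipeline_analysis > msms_run_summary > spectrum_query
#     attributes: spectrum, assumed_charge, precursor_neutral_mass
#   spectrum_query > search_result > search_hit
#     attributes: peptide, protein
#   search_hit > alternative_protein (attribute: protein)
#   search_hit > modification_info > mod_aminoacid_mass
#     attributes: position, mass (modified residue mass, pepXML convention),
#                 massdiff, description (non-standard, the modification name)
#   search_hit > analysis_result > peptideprophet_result
#     attribute: probability (used as the identification confidence)

#' Read identification records from a pepXML file
#'
#' Parses the documented pepXML subset into a normalized [id_records()]
#' table. Matches missing a required attribute are skipped with a warning
#' giving the skip count. The decoy flag is set when any protein accession
#' carries the decoy prefix.
#'
#' @param path Path to a pepXML file.
#' @param decoy_prefix Accession prefix marking decoy proteins.
#' @return An [id_records()] table.
#' @export
read_pepxml <- function(path, decoy_prefix = "DECOY_") {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  queries <- xml2::xml_find_all(doc, ".//spectrum_query")
  skipped <- 0L
  rows <- list()
  for (q in queries) {
    spectrum <- xml2::xml_attr(q, "spectrum")
    charge <- xml2::xml_attr(q, "assumed_charge")
    pmass <- xml2::xml_attr(q, "precursor_neutral_mass")
    hit <- xml2::xml_find_first(q, ".//search_hit")
    if (is.na(spectrum) || is.na(charge) || is.na(pmass) ||
        inherits(hit, "xml_missing")) {
      skipped <- skipped + 1L
      next
    }
    pepseq <- xml2::xml_attr(hit, "peptide")
    prot <- xml2::xml_attr(hit, "protein")
    if (is.na(pepseq) || is.na(prot)) {
      skipped <- skipped + 1L
      next
    }
    alt <- xml2::xml_attr(xml2::xml_find_all(hit, "alternative_protein"),
                          "protein")
    prob <- xml2::xml_attr(
      xml2::xml_find_first(hit, ".//peptideprophet_result"), "probability")
    if (is.na(prob)) {
      skipped <- skipped + 1L
      next
    }
    mods <- xml2::xml_find_all(hit, "modification_info/mod_aminoacid_mass")
    modtab <- NULL
    if (length(mods)) {
      modtab <- data.frame(
        position = as.integer(xml2::xml_attr(mods, "position")),
        mass_delta = as.numeric(xml2::xml_attr(mods, "massdiff")),
        name = xml2::xml_attr(mods, "description"),
        stringsAsFactors = FALSE)
    }
    prots <- c(prot, alt)
    rows[[length(rows) + 1L]] <- list(
      spectrum_id = spectrum, sequence = pepseq,
      charge = as.integer(charge), confidence = as.numeric(prob),
      observed_neutral_mass = as.numeric(pmass),
      is_decoy = any(startsWith(prots, decoy_prefix)),
      proteins = paste(prots, collapse = ";"),
      modifications = modtab)
  }
  if (skipped > 0)
    warning(sprintf("skipped %d match(es) with missing required attributes",
                    skipped))
  if (length(rows) == 0) {
    out <- empty_records()
    class(out) <- c("id_records", class(out))
    return(out)
  }
  id_records(
    spectrum_id = vapply(rows, `[[`, character(1), "spectrum_id"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    charge = vapply(rows, `[[`, integer(1), "charge"),
    confidence = vapply(rows, `[[`, numeric(1), "confidence"),
    observed_neutral_mass = vapply(rows, `[[`, numeric(1),
                                   "observed_neutral_mass"),
    is_decoy = vapply(rows, `[[`, logical(1), "is_decoy"),
    proteins = vapply(rows, `[[`, character(1), "proteins"),
    modifications = lapply(rows, `[[`, "modifications"))
}

#' Write identification records as pepXML
#'
#' Emits the same subset [read_pepxml()] consumes, so that
#' `read_pepxml(write_pepxml(r))` round-trips.
#'
#' @param records An [id_records()] table.
#' @param path Output file path.
#' @export
write_pepxml <- function(records, path) {
  doc <- xml2::xml_new_root("msms_pipeline_analysis")
  run <- xml2::xml_add_child(doc, "msms_run_summary")
  for (i in seq_len(nrow(records))) {
    q <- xml2::xml_add_child(run, "spectrum_query",
      spectrum = records$spectrum_id[i],
      assumed_charge = as.character(records$charge[i]),
      precursor_neutral_mass = sprintf("%.6f",
                                       records$observed_neutral_mass[i]))
    res <- xml2::xml_add_child(q, "search_result")
    prots <- strsplit(records$proteins[i], ";", fixed = TRUE)[[1]]
    if (length(prots) == 0) prots <- ""
    hit <- xml2::xml_add_child(res, "search_hit",
                               peptide = records$sequence[i],
                               protein = prots[1])
    for (p in prots[-1])
      xml2::xml_add_child(hit, "alternative_protein", protein = p)
    m <- records$modifications[[i]]
    if (!is.null(m) && nrow(m) > 0) {
      mi <- xml2::xml_add_child(hit, "modification_info")
      res_mass <- MASS_CONSTANTS$residues
      for (j in seq_len(nrow(m))) {
        pos <- m$position[j]
        base <- if (pos >= 1 && pos <= nchar(records$sequence[i]))
          unname(res_mass[substr(records$sequence[i], pos, pos)]) else 0
        xml2::xml_add_child(mi, "mod_aminoacid_mass",
                            position = as.character(pos),
                            mass = sprintf("%.6f", base + m$mass_delta[j]),
                            massdiff = sprintf("%.6f", m$mass_delta[j]),
                            description = m$name[j])
      }
    }
    ar <- xml2::xml_add_child(hit, "analysis_result",
                              analysis = "peptideprophet")
    xml2::xml_add_child(ar, "peptideprophet_result",
                        probability = sprintf("%.6f", records$confidence[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
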