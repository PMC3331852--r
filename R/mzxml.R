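# Minimal mzXML export of centroided MS2 spectra (base64 network-order
# 32-bit floats, uncompressed, no index), plus an mzR-backed reader. The
# writer exists so simulated spectra can be handed to external library
# builders; the reader lets real mzXML acquisitions enter the pipeline.

#' Write MS2 spectra as mzXML
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(spectra, path) {
  doc <- xml2::xml_new_root(
    "mzXML",
    "xmlns" = "http://sashimi.sourceforge.net/schema_revision/mzXML_3.2")
  run <- xml2::xml_add_child(doc, "msRun",
                             scanCount = as.character(length(spectra)))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    scan <- xml2::xml_add_child(run, "scan",
      num = as.character(i), msLevel = "2",
      peaksCount = as.character(length(s$mz)),
      lowMz = sprintf("%.6f", min(s$mz)),
      highMz = sprintf("%.6f", max(s$mz)))
    pm <- xml2::xml_add_child(scan, "precursorMz",
      precursorCharge = as.character(s$precursor_charge),
      precursorIntensity = "0")
    xml2::xml_text(pm) <- sprintf("%.6f", s$precursor_mz)
    interleaved <- as.numeric(rbind(s$mz, s$intensity))
    b64 <- jsonlite::base64_enc(writeBin(interleaved, raw(), size = 4,
                                         endian = "big"))
    pk <- xml2::xml_add_child(scan, "peaks",
      precision = "32", byteOrder = "network",
      contentType = "m/z-int", compressionType = "none",
      compressedLen = "0")
    xml2::xml_text(pk) <- gsub("\n", "", b64)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read MS2 spectra from an mzXML file
#'
#' Uses the Bioconductor `mzR` backend. Spectrum ids are
#' `"scan=<num>"` unless ids are supplied.
#'
#' @param path Path to an mzXML file.
#' @param ids Optional character vector of spectrum ids, one per scan.
#' @return List of [spectrum()] objects.
#' @export
read_mzxml <- function(path, ids = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzXML requires the 'mzR' package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  out <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    pk <- mzR::peaks(h, i)
    id <- if (!is.null(ids)) ids[i] else sprintf("scan=%d", hdr$acquisitionNum[i])
    out[[i]] <- spectrum(id,
                         precursor_mz = hdr$precursorMZ[i],
                         precursor_charge = max(1L, hdr$precursorCharge[i]),
                         mz = pk[, 1], intensity = pk[, 2])
  }
  out
}
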