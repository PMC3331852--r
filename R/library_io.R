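# Spectral-library file formats: blib (BiblioSpec SQLite) and msp (NIST
# text). The blib writer follows the public BiblioSpec convention: LibInfo,
# RefSpectra and RefSpectraPeaks tables, peak arrays stored as
# zlib-compressed little-endian double (m/z) and float (intensity) blobs;
# when compression does not shrink an array it is stored raw, and the reader
# distinguishes the two by blob length.

#' Write a spectral library to file
#'
#' @param library A `spectral_library`.
#' @param path Output path.
#' @param format `"blib"` or `"msp"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, format = c("blib", "msp")) {
  format <- match.arg(format)
  switch(format, blib = write_blib(library, path),
         msp = write_msp(library, path))
}

#' Read a spectral library from file
#'
#' @param path Input path.
#' @param format `"blib"` or `"msp"`.
#' @return A `spectral_library`.
#' @export
read_library <- function(path, format = c("blib", "msp")) {
  format <- match.arg(format)
  switch(format, blib = read_blib(path), msp = read_msp(path))
}

compress_or_raw <- function(raw_bytes) {
  z <- memCompress(raw_bytes, type = "gzip")
  if (length(z) < length(raw_bytes)) z else raw_bytes
}

#' @rdname write_library
#' @export
write_blib <- function(library, path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "CREATE TABLE LibInfo (libLSID TEXT, createTime TEXT,
                       numSpecs INTEGER, majorVersion INTEGER,
                       minorVersion INTEGER)")
  DBI::dbExecute(con, "CREATE TABLE RefSpectra (id INTEGER PRIMARY KEY,
                       peptideSeq TEXT, peptideModSeq TEXT,
                       precursorCharge INTEGER, precursorMZ REAL,
                       copies INTEGER, numPeaks INTEGER,
                       bestConfidence REAL, spectrumID TEXT)")
  DBI::dbExecute(con, "CREATE TABLE RefSpectraPeaks (RefSpectraID INTEGER,
                       peakMZ BLOB, peakIntensity BLOB)")
  DBI::dbExecute(con,
    "INSERT INTO LibInfo VALUES (:l, :t, :n, 1, 0)",
    params = list(l = "urn:lsid:nativemrm:spectral_library",
                  t = library$metadata$build_time %||% "",
                  n = length(library$entries)))
  i <- 0L
  for (e in library$entries) {
    i <- i + 1L
    s <- e$representative
    DBI::dbExecute(con,
      "INSERT INTO RefSpectra VALUES (:id, :seq, :mseq, :z, :mz, :c, :np, :bc, :sid)",
      params = list(id = i, seq = e$sequence,
                    mseq = paste0(e$sequence,
                                  if (nzchar(e$mod_key)) paste0("[", e$mod_key, "]") else ""),
                    z = e$charge, mz = s$precursor_mz, c = e$copy_count,
                    np = length(s$mz), bc = e$best_confidence,
                    sid = s$spectrum_id))
    DBI::dbExecute(con,
      "INSERT INTO RefSpectraPeaks VALUES (:id, :mz, :int)",
      params = list(id = i,
                    mz = list(compress_or_raw(writeBin(as.double(s$mz),
                      raw(), size = 8, endian = "little"))),
                    int = list(compress_or_raw(writeBin(as.double(s$intensity),
                      raw(), size = 4, endian = "little")))))
  }
  invisible(path)
}

decode_blob <- function(blob, n, size) {
  if (length(blob) != n * size)
    blob <- memDecompress(blob, type = "gzip")
  if (length(blob) != n * size)
    stop(sprintf("corrupt peak blob: %d bytes for %d values of size %d",
                 length(blob), n, size))
  readBin(blob, "double", n = n, size = size, endian = "little")
}

#' @rdname read_library
#' @export
read_blib <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  need <- c("LibInfo", "RefSpectra", "RefSpectraPeaks")
  if (!all(need %in% tabs))
    stop("not a blib library, missing table(s): ",
         paste(setdiff(need, tabs), collapse = ", "))
  info <- DBI::dbReadTable(con, "LibInfo")
  ref <- DBI::dbReadTable(con, "RefSpectra")
  entries <- list()
  for (i in seq_len(nrow(ref))) {
    pk <- DBI::dbGetQuery(con,
      "SELECT peakMZ, peakIntensity FROM RefSpectraPeaks WHERE RefSpectraID = ?",
      params = list(ref$id[i]))
    if (nrow(pk) != 1)
      stop("corrupt library: RefSpectraPeaks record missing for spectrum id ",
           ref$id[i])
    mz <- decode_blob(pk$peakMZ[[1]], ref$numPeaks[i], 8)
    inten <- decode_blob(pk$peakIntensity[[1]], ref$numPeaks[i], 4)
    sid <- if ("spectrumID" %in% names(ref)) ref$spectrumID[i]
           else as.character(ref$id[i])
    sp <- spectrum(sid, ref$precursorMZ[i], ref$precursorCharge[i], mz, inten)
    mk <- sub("^.*\\[(.*)\\]$", "\\1", ref$peptideModSeq[i])
    if (mk == ref$peptideModSeq[i]) mk <- ""
    key <- sprintf("%s/%d%s", ref$peptideSeq[i], ref$precursorCharge[i],
                   if (nzchar(mk)) paste0("[", mk, "]") else "")
    entries[[key]] <- list(key = key, sequence = ref$peptideSeq[i],
                           charge = ref$precursorCharge[i], mod_key = mk,
                           representative = sp,
                           copy_count = ref$copies[i],
                           best_confidence =
                             if ("bestConfidence" %in% names(ref))
                               ref$bestConfidence[i] else NA_real_)
  }
  structure(list(entries = sort_entries(entries),
                 metadata = list(libLSID = info$libLSID[1],
                                 build_time = info$createTime[1])),
            class = "spectral_library")
}

#' @rdname write_library
#' @export
write_msp <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in library$entries) {
    s <- e$representative
    writeLines(c(
      sprintf("Name: %s/%d", e$sequence, e$charge),
      sprintf("Comment: Parent=%.6f Mods=%s Copies=%d BestConfidence=%.6f SpectrumID=%s",
              s$precursor_mz,
              if (nzchar(e$mod_key)) e$mod_key else "none",
              e$copy_count, e$best_confidence, s$spectrum_id),
      sprintf("Num peaks: %d", length(s$mz)),
      sprintf("%.6f\t%.6f", s$mz, s$intensity),
      ""), con)
  }
  invisible(path)
}

#' @rdname read_library
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  entries <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "Name: ")) { i <- i + 1L; next }
    name <- sub("^Name: ", "", lines[i])
    parts <- strsplit(name, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("corrupt msp record at line ", i, ": ", lines[i])
    comment <- sub("^Comment: ", "", lines[i + 1L])
    fields <- strsplit(comment, " ", fixed = TRUE)[[1]]
    getf <- function(key) {
      v <- fields[startsWith(fields, paste0(key, "="))]
      if (length(v) != 1) stop("corrupt msp Comment at line ", i + 1L)
      sub(paste0("^", key, "="), "", v)
    }
    np <- as.integer(sub("^Num peaks: ", "", lines[i + 2L]))
    if (is.na(np)) stop("corrupt msp 'Num peaks' at line ", i + 2L)
    peak_lines <- lines[seq.int(i + 3L, i + 2L + np)]
    pm <- do.call(rbind, strsplit(peak_lines, "\t", fixed = TRUE))
    mk <- getf("Mods"); if (mk == "none") mk <- ""
    sp <- spectrum(getf("SpectrumID"), as.numeric(getf("Parent")),
                   as.integer(parts[2]),
                   as.numeric(pm[, 1]), as.numeric(pm[, 2]))
    key <- sprintf("%s/%s%s", parts[1], parts[2],
                   if (nzchar(mk)) paste0("[", mk, "]") else "")
    entries[[key]] <- list(key = key, sequence = parts[1],
                           charge = as.integer(parts[2]), mod_key = mk,
                           representative = sp,
                           copy_count = as.integer(getf("Copies")),
                           best_confidence = as.numeric(getf("BestConfidence")))
    i <- i + 3L + np
  }
  structure(list(entries = sort_entries(entries), metadata = list()),
            class = "spectral_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
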