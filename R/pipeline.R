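#' Run a pipeline subcommand
#'
#' Thin programmatic entry point behind the `nativemrm` command-line
#' script. Subcommands: `masses` (print precursor/fragment m/z for a
#' peptide spec), `build-library` (pepXML + spectra to blib/msp with
#' filtering and FDR re-estimation), `design` (transition enumeration,
#' ranking and light/heavy export), `quantify` (chromatogram CSV to
#' concentrations) and `simulate` (synthetic identification sets or MRM
#' runs). Progress is logged as JSON lines with stage counts
#' (parsed, filtered, ions, entries), and outputs are written to a
#' temporary file then renamed so partial artifacts are never left behind.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first).
#' @param log Connection or `""` for stdout; JSON-lines log destination.
#' @return Integer exit status (0 on success), invisibly.
#' @export
run_pipeline <- function(argv, log = "") {
  emit <- function(...) {
    rec <- list(...)
    rec$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "", file = log)
  }
  fail <- function(msg) {
    message("error: ", msg)
    invisible(1L)
  }
  opts <- parse_argv(argv[-1])
  if (length(argv) == 0) return(fail("no subcommand given"))
  getopt <- function(name, default = NULL, required = FALSE) {
    if (!is.null(opts[[name]])) return(opts[[name]])
    if (required) stop(sprintf("missing required option --%s", name))
    default
  }
  atomic_write <- function(write_fn, path) {
    tmp <- paste0(path, ".tmp")
    write_fn(tmp)
    file.rename(tmp, path)
  }
  status <- tryCatch({
    switch(argv[1],
      "masses" = {
        pep <- parse_peptide_spec(getopt("peptide", required = TRUE))
        z <- as.integer(getopt("charge", "2"))
        cat(sprintf("%.2f\n", mz_round(precursor_mz(pep, z))))
        0L
      },
      "build-library" = {
        records <- read_pepxml(getopt("pepxml", required = TRUE))
        emit(stage = "parsed", n = nrow(records))
        cfg <- filter_config(
          min_confidence = as.numeric(getopt("min-confidence", "0.95")),
          mass_tolerance = as.numeric(getopt("tolerance", "0.2")))
        f <- filter_identifications(records, cfg)
        emit(stage = "filtered", retained = nrow(f$retained),
             decoys = nrow(f$decoys), rejected = nrow(f$rejected))
        fdr <- estimate_fdr(rbind(f$retained, f$decoys))
        emit(stage = "fdr", spectrum = fdr$fdr[1], ion = fdr$fdr[2],
             peptide = fdr$fdr[3])
        spectra <- if (!is.null(opts[["mzxml"]])) read_mzxml(opts[["mzxml"]])
                   else read_msp(getopt("msp", required = TRUE))
        if (inherits(spectra, "spectral_library"))
          spectra <- lapply(spectra$entries, `[[`, "representative")
        lib <- build_library(f$retained, spectra,
                             metadata = list(filter = unclass(cfg)))
        emit(stage = "library", ions = length(lib$entries))
        out <- getopt("out", required = TRUE)
        fmt <- if (grepl("\\.msp$", out)) "msp" else "blib"
        atomic_write(function(p) write_library(lib, p, fmt), out)
        0L
      },
      "design" = {
        lib <- read_library(getopt("library", required = TRUE),
                            if (grepl("\\.msp$", opts[["library"]])) "msp"
                            else "blib")
        pep <- parse_peptide_spec(getopt("peptide", required = TRUE))
        z <- as.integer(getopt("charge", "2"))
        entry <- library_entry(lib, pep$sequence, z)
        if (is.null(entry))
          stop("no library entry for ", pep$sequence, " at charge ", z)
        cands <- enumerate_candidates(peptide(pep$sequence))
        cands <- cands[cands$precursor_charge == z, , drop = FALSE]
        emit(stage = "candidates", n = nrow(cands))
        sel <- rank_and_select(cands, entry,
                               as.integer(getopt("top", "5")))
        sel <- assign_ce_dp(sel, "fixture-table")
        pair <- heavy_counterparts(sel, pep$label)
        emit(stage = "selected", n = nrow(sel))
        atomic_write(function(p) export_transition_list(pair, p),
                     getopt("out", required = TRUE))
        0L
      },
      "quantify" = {
        chroms <- read_chromatograms(getopt("chromatograms",
                                            required = TRUE))
        emit(stage = "chromatograms", n = length(chroms))
        spikes <- triplex_peptides()
        res <- quantify_runs(chroms, spikes)
        atomic_write(function(p)
          utils::write.table(res, p, sep = "\t", row.names = FALSE,
                             quote = FALSE),
          getopt("out", required = TRUE))
        0L
      },
      "simulate" = {
        what <- getopt("what", "ids")
        seed <- as.integer(getopt("seed", "1"))
        out <- getopt("out", required = TRUE)
        if (what == "ids") {
          cfg <- sim_id_config(n_spectra =
                                 as.integer(getopt("n-spectra", "600")))
          sim <- simulate_identifications(cfg, seed = seed)
          atomic_write(function(p) write_pepxml(sim$records, p), out)
        } else if (what == "mrm") {
          peps <- triplex_peptides()
          panel <- triplex_panel()
          sim <- simulate_mrm_runs(panel,
            concentrations = c(DSGEGDFLAEGGGVR = 500,
                               SSKITHRIHWESASLL = 50,
                               NGFKSHALQLNNRQI = 5),
            spikes = vapply(peps, `[[`, numeric(1), "spike_fmol_ul") |>
              stats::setNames(vapply(peps, `[[`, character(1), "sequence")),
            seed = seed)
          atomic_write(function(p) write_mrm_csv(sim, p), out)
        } else stop("unknown simulate target: ", what)
        emit(stage = "simulated", what = what, seed = seed)
        0L
      },
      fail(paste("unknown subcommand:", argv[1]))
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_argv <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (grepl("=", key)) {
      kv <- strsplit(key, "=", fixed = TRUE)[[1]]
      opts[[kv[1]]] <- paste(kv[-1], collapse = "=")
    } else {
      if (i == length(args)) stop("option --", key, " needs a value")
      opts[[key]] <- args[i + 1L]
      i <- i + 1L
    }
    i <- i + 1L
  }
  opts
}

#' Reference light/heavy transition panel of the triplex assay
#'
#' The optimized panel: the three most intense optimized transitions for
#' the FIBA 2+ and CO4 3+ precursors and the two most intense from each of
#' the CO3 3+ and 4+ precursors, with the empirically optimized DP/CE
#' values, paired light/heavy.
#'
#' @return List with `light` and `heavy` transition data.frames.
#' @export
triplex_panel <- function() {
  peps <- triplex_peptides()
  spec <- list(
    list(p = "FIBA", z = 2L, frags = c("y8", "y7", "y5"), fz = 1L),
    list(p = "CO3", z = 3L, frags = c("b14", "b15"), fz = 2L),
    list(p = "CO3", z = 4L, frags = c("b13", "b14"), fz = 2L),
    list(p = "CO4", z = 3L, frags = c("y7", "y6", "y5"), fz = 1L))
  rows <- lapply(spec, function(s) {
    pp <- peps[[s$p]]
    pep <- peptide(pp$sequence)
    data.frame(sequence = pp$sequence, precursor_charge = s$z,
               precursor_mz = precursor_mz(pep, s$z),
               series = substr(s$frags, 1, 1),
               index = as.integer(sub("^[yb]", "", s$frags)),
               fragment_charge = s$fz,
               product_mz = vapply(s$frags, function(f)
                 fragment_mz(pep, substr(f, 1, 1),
                             as.integer(sub("^[yb]", "", f)), s$fz),
                 numeric(1)),
               fragment = s$frags, stringsAsFactors = FALSE)
  })
  light <- assign_ce_dp(do.call(rbind, rows), "fixture-table")
  labels <- stats::setNames(lapply(peps, `[[`, "label"),
                            vapply(peps, `[[`, character(1), "sequence"))
  heavy <- light
  for (i in seq_len(nrow(light))) {
    hp <- peptide(light$sequence[i], label = labels[[light$sequence[i]]])
    heavy$precursor_mz[i] <- precursor_mz(hp, light$precursor_charge[i])
    heavy$product_mz[i] <- fragment_mz(hp, light$series[i], light$index[i],
                                       light$fragment_charge[i])
  }
  light$form <- "light"; heavy$form <- "heavy"
  list(light = light, heavy = heavy)
}

#' Quantify light/heavy chromatogram pairs
#'
#' Integrates each transition over `rt_width` minutes around the peak
#' apex of its heavy channel, sums areas per peptide and form, and converts
#' the light/heavy ratio into a concentration via the spike level.
#'
#' @param chromatograms Named list of chromatograms (see
#'   [read_chromatograms()]); names follow the
#'   `<sequence>.<form>.<z>+.<fragment>` convention of
#'   [simulate_mrm_runs()].
#' @param peptides A list shaped like [triplex_peptides()].
#' @param rt_width Half-width of the integration window, minutes.
#' @return Data.frame with `sequence`, `light_area`, `heavy_area`, `ratio`,
#'   `concentration_fmol_ul`.
#' @export
quantify_runs <- function(chromatograms, peptides = triplex_peptides(),
                          rt_width = 0.25) {
  parts <- strsplit(names(chromatograms), ".", fixed = TRUE)
  seqs <- vapply(parts, `[[`, character(1), 1)
  forms <- vapply(parts, `[[`, character(1), 2)
  out <- list()
  for (p in peptides) {
    idx <- which(seqs == p$sequence)
    if (length(idx) == 0) next
    areas <- c(light = 0, heavy = 0)
    # apex from the summed heavy channel defines the shared window
    hv <- idx[forms[idx] == "heavy"]
    apex_tr <- chromatograms[[hv[1]]]
    apex <- apex_tr$time[which.max(apex_tr$intensity)]
    win <- c(apex - rt_width, apex + rt_width)
    for (i in idx) {
      ch <- chromatograms[[i]]
      areas[forms[i]] <- areas[forms[i]] +
        integrate_peak(ch$time, ch$intensity, win)
    }
    q <- absolute_quant(areas["light"], areas["heavy"], p$spike_fmol_ul)
    out[[p$sequence]] <- data.frame(
      sequence = p$sequence, light_area = unname(areas["light"]),
      heavy_area = unname(areas["heavy"]), ratio = q$ratio,
      concentration_fmol_ul = q$concentration, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
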