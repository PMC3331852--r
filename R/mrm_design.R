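#' Candidate-transition enumeration settings
#'
#' Defaults cover the charge and series space relevant for native
#' (non-tryptic) peptides, where no tryptic heuristics (y-only, 2+
#' precursor / 1+ fragment) apply: precursor charges 2-4, fragment charges
#' 1-2, both y and b series. The product m/z window defaults to the
#' acquired MS/MS range, 150-2000 Th, and single-residue fragments (index
#' 1) are excluded by default because b1/y1 ions are non-specific and carry
#' no library evidence; both choices are switchable.
#'
#' @param precursor_charges,fragment_charges Integer vectors.
#' @param series Character vector over `"y"`, `"b"`.
#' @param min_index Smallest fragment length considered.
#' @param max_index Largest fragment length, `NULL` for `length - 1`.
#' @param mz_min,mz_max Product-ion m/z window (Th). The window filters
#'   product ions only; precursors are not constrained by it unless
#'   `window_precursors = TRUE`.
#' @param window_precursors Also require the precursor m/z inside the
#'   window.
#' @param fragment_charge_lt_precursor Require fragment charge strictly
#'   below precursor charge (off by default; non-tryptic peptides violate
#'   this heuristic).
#' @return A list of class `"enumeration_settings"`.
#' @export
enumeration_settings <- function(precursor_charges = 2:4,
                                 fragment_charges = 1:2,
                                 series = c("y", "b"),
                                 min_index = 2L,
                                 max_index = NULL,
                                 mz_min = 150,
                                 mz_max = 2000,
                                 window_precursors = FALSE,
                                 fragment_charge_lt_precursor = FALSE) {
  stopifnot(length(precursor_charges) > 0, length(fragment_charges) > 0,
            length(series) > 0, all(series %in% c("y", "b")),
            mz_min < mz_max, min_index >= 1)
  structure(list(precursor_charges = as.integer(precursor_charges),
                 fragment_charges = as.integer(fragment_charges),
                 series = series, min_index = as.integer(min_index),
                 max_index = max_index, mz_min = mz_min, mz_max = mz_max,
                 window_precursors = window_precursors,
                 fragment_charge_lt_precursor = fragment_charge_lt_precursor),
            class = "enumeration_settings")
}

#' Enumerate candidate MRM transitions for a peptide
#'
#' Cartesian product of precursor charges, ion series, fragment indices and
#' fragment charges, keeping candidates whose product m/z falls inside the
#' settings window. Rows are ordered deterministically by precursor charge,
#' series (in settings order), index, then fragment charge.
#'
#' @param pep A [peptide()] (label scheme included in all m/z).
#' @param settings An [enumeration_settings()].
#' @return Data.frame with columns `sequence`, `precursor_charge`,
#'   `precursor_mz`, `series`, `index`, `fragment_charge`, `product_mz`,
#'   `fragment` (e.g. `"y8"`).
#' @export
enumerate_candidates <- function(pep, settings = enumeration_settings()) {
  pep <- as_peptide(pep)
  n <- length(pep$residues)
  kmax <- settings$max_index %||% (n - 1L)
  kmax <- min(kmax, n - 1L)
  rows <- list()
  for (pz in settings$precursor_charges) {
    pmz <- precursor_mz(pep, pz)
    if (settings$window_precursors &&
        (pmz < settings$mz_min || pmz > settings$mz_max)) next
    for (ser in settings$series) {
      if (settings$min_index > kmax) next
      for (k in seq.int(settings$min_index, kmax)) {
        for (fz in settings$fragment_charges) {
          if (settings$fragment_charge_lt_precursor && fz >= pz) next
          fmz <- fragment_mz(pep, ser, k, fz)
          if (fmz < settings$mz_min || fmz > settings$mz_max) next
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = pep$sequence, precursor_charge = pz,
            precursor_mz = pmz, series = ser, index = k,
            fragment_charge = fz, product_mz = fmz,
            fragment = paste0(ser, k), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(sequence = character(), precursor_charge = integer(),
                      precursor_mz = numeric(), series = character(),
                      index = integer(), fragment_charge = integer(),
                      product_mz = numeric(), fragment = character()))
  do.call(rbind, rows)
}

#' Score candidates against a library spectrum and select the top n
#'
#' Each candidate is scored by the maximum library peak intensity within
#' `match_tol` of its product m/z (0 when unmatched). The `n` highest-scored
#' candidates are returned, ties broken by ascending product m/z, the
#' result sorted by descending score. Zero-score candidates are dropped
#' unless `pad_zero = TRUE` and fewer than `n` candidates matched.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param entry A library entry (from [library_entry()]) or a [spectrum()].
#' @param n Number of transitions to select.
#' @param match_tol Peak-match tolerance in Th.
#' @param pad_zero Allow zero-score candidates to pad the selection.
#' @return Subset of `candidates` with an added `score` column.
#' @export
rank_and_select <- function(candidates, entry, n, match_tol = 0.05,
                            pad_zero = FALSE) {
  if (n < 1) stop("n must be >= 1")
  if (nrow(candidates) == 0) {
    candidates$score <- numeric(0)
    return(candidates)
  }
  spec <- if (inherits(entry, "spectrum")) entry else entry$representative
  score <- vapply(candidates$product_mz, function(mz) {
    hit <- abs(spec$mz - mz) <= match_tol
    if (any(hit)) max(spec$intensity[hit]) else 0
  }, numeric(1))
  candidates$score <- score
  o <- order(-score, candidates$product_mz)
  candidates <- candidates[o, , drop = FALSE]
  if (!pad_zero) candidates <- candidates[candidates$score > 0, , drop = FALSE]
  utils::head(candidates, n)
}

#' Pair a light transition panel with its heavy counterparts
#'
#' For every light transition the heavy precursor and product m/z are
#' recomputed under the label scheme; fragment identity (series, index,
#' charge) and any instrument parameters (DP, CE) are copied from the light
#' row. With an empty label the heavy panel equals the light one.
#'
#' @param panel_light Data.frame of light transitions (as produced by
#'   [enumerate_candidates()] / [rank_and_select()], optionally with
#'   `dp`/`ce` columns).
#' @param label A [label_scheme()] or `NULL`.
#' @return List with `light` and `heavy` data.frames, rows paired 1:1, each
#'   carrying a `form` column.
#' @export
heavy_counterparts <- function(panel_light, label) {
  heavy <- panel_light
  if (!is.null(label)) {
    for (i in seq_len(nrow(panel_light))) {
      hp <- peptide(panel_light$sequence[i], label = label)
      heavy$precursor_mz[i] <- precursor_mz(hp, panel_light$precursor_charge[i])
      heavy$product_mz[i] <- fragment_mz(hp, panel_light$series[i],
                                         panel_light$index[i],
                                         panel_light$fragment_charge[i])
    }
  }
  panel_light$form <- "light"
  heavy$form <- "heavy"
  list(light = panel_light, heavy = heavy)
}

#' Default per-charge collision-energy / declustering-potential model
#'
#' Linear CE in precursor m/z, `CE = slope[z] * mz + intercept[z]`, with a
#' per-charge constant DP. Coefficients are generic QTRAP-style starting
#' values meant to be replaced by empirically optimized ones (see the
#' fixture table shipped with the package).
#'
#' @param ce_slope,ce_intercept,dp Named numeric vectors keyed by charge.
#' @return List of class `"ce_dp_model"`.
#' @export
ce_dp_model <- function(ce_slope = c("2" = 0.044, "3" = 0.0544, "4" = 0.0544),
                        ce_intercept = c("2" = 5.5, "3" = -2.41, "4" = -2.41),
                        dp = c("2" = 85, "3" = 80, "4" = 70)) {
  structure(list(ce_slope = ce_slope, ce_intercept = ce_intercept, dp = dp),
            class = "ce_dp_model")
}

#' Assign declustering potential and collision energy to transitions
#'
#' `method = "fixture-table"` looks up empirically optimized values keyed by
#' (precursor m/z rounded to 2 decimals, fragment label); entries missing
#' from the table fall back to the linear model with a warning.
#' `method = "linear-default"` always uses the linear model.
#'
#' @param transitions Data.frame with `precursor_mz`, `precursor_charge`,
#'   `fragment` columns.
#' @param method `"fixture-table"` or `"linear-default"`.
#' @param fixture Data.frame with columns `precursor_mz`, `fragment`, `dp`,
#'   `ce`; defaults to the optimized QTRAP parameters shipped with the
#'   package.
#' @param model A [ce_dp_model()].
#' @return `transitions` with `dp` and `ce` columns added.
#' @export
assign_ce_dp <- function(transitions,
                         method = c("fixture-table", "linear-default"),
                         fixture = NULL, model = ce_dp_model()) {
  method <- match.arg(method)
  if (method == "fixture-table" && is.null(fixture)) {
    fixture <- utils::read.csv(system.file("extdata",
                                           "qtrap_optimized_params.csv",
                                           package = "nativemrm"))
  }
  linear <- function(i) {
    z <- as.character(transitions$precursor_charge[i])
    sl <- model$ce_slope[z]; ic <- model$ce_intercept[z]; dp <- model$dp[z]
    if (is.na(sl) || is.na(ic) || is.na(dp))
      stop("no CE/DP coefficients for charge ", z)
    c(dp = unname(dp), ce = unname(sl * transitions$precursor_mz[i] + ic))
  }
  dp <- numeric(nrow(transitions)); ce <- numeric(nrow(transitions))
  misses <- 0L
  for (i in seq_len(nrow(transitions))) {
    v <- NULL
    if (method == "fixture-table") {
      hit <- which(abs(fixture$precursor_mz -
                         round(transitions$precursor_mz[i], 2)) < 0.005 &
                   fixture$fragment == transitions$fragment[i])
      if (length(hit)) v <- c(dp = fixture$dp[hit[1]], ce = fixture$ce[hit[1]])
      else misses <- misses + 1L
    }
    if (is.null(v)) v <- linear(i)
    dp[i] <- v["dp"]; ce[i] <- v["ce"]
  }
  if (misses > 0)
    warning(sprintf("%d transition(s) missing from the fixture table; used the linear CE/DP model",
                    misses))
  transitions$dp <- dp
  transitions$ce <- ce
  transitions
}

#' Export a scheduled-MRM transition list
#'
#' CSV with columns `Q1`, `Q3`, `dwell_ms`, `name`, `DP`, `CE`, compatible
#' with vendor transition-list import. m/z values are printed at 2 decimals
#' (half-even), names as `<sequence>.<form>.<charge>+.<fragment>`.
#'
#' @param panel List with `light`/`heavy` data.frames
#'   (from [heavy_counterparts()]) or a single transitions data.frame.
#' @param path Output CSV path.
#' @param dwell_ms Dwell time per transition, milliseconds.
#' @return `path`, invisibly.
#' @export
export_transition_list <- function(panel, path, dwell_ms = 30) {
  if (is.data.frame(panel)) {
    if (is.null(panel$form)) panel$form <- "light"
    tab <- panel
  } else {
    tab <- rbind(panel$light, panel$heavy)
  }
  out <- data.frame(
    Q1 = sprintf("%.2f", mz_round(tab$precursor_mz)),
    Q3 = sprintf("%.2f", mz_round(tab$product_mz)),
    dwell_ms = dwell_ms,
    name = sprintf("%s.%s.%d+.%s", tab$sequence, tab$form,
                   tab$precursor_charge, tab$fragment),
    DP = if (!is.null(tab$dp)) sprintf("%.1f", tab$dp) else NA,
    CE = if (!is.null(tab$ce)) sprintf("%.1f", tab$ce) else NA,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The three serum peptides of the reference triplex assay
#'
#' FIBA (fibrinogen alpha chain) DSGEGDFLAEGGGVR with one 13C per glycine in
#' its heavy form; CO3 (complement C3) SSKITHRIHWESASLL with 13C6+15N1 on
#' Leu15; CO4 (complement C4) NGFKSHALQLNNRQI with 13C6+15N1 on Leu10.
#'
#' @return Named list; each element has `sequence`, `label`
#'   (a [label_scheme()]) and `spike_fmol_ul` (internal-standard spike per
#'   microliter of serum).
#' @export
triplex_peptides <- function() {
  list(
    FIBA = list(sequence = "DSGEGDFLAEGGGVR",
                label = label_scheme(residue_rule("G", n_13C = 1)),
                spike_fmol_ul = 500),
    CO3 = list(sequence = "SSKITHRIHWESASLL",
               label = label_scheme(residue_rule(position = 15,
                                                 n_13C = 6, n_15N = 1)),
               spike_fmol_ul = 500),
    CO4 = list(sequence = "NGFKSHALQLNNRQI",
               label = label_scheme(residue_rule(position = 10,
                                                 n_13C = 6, n_15N = 1)),
               spike_fmol_ul = 50))
}
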