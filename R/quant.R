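#' Integrate an MRM chromatographic peak
#'
#' Trapezoidal integral of intensity over a retention-time window, with an
#' optional linear baseline drawn between the window endpoints. Window
#' endpoints falling between samples are handled by linear interpolation.
#' The result is floored at zero.
#'
#' @param time,intensity Parallel numeric vectors; `time` strictly
#'   increasing (minutes), intensities non-negative counts.
#' @param rt_window Length-2 numeric `(start, end)` in minutes.
#' @param baseline `"none"` or `"linear"`.
#' @return Peak area in counts x min.
#' @export
integrate_peak <- function(time, intensity, rt_window,
                           baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(length(time) == length(intensity), length(rt_window) == 2,
            rt_window[1] < rt_window[2])
  if (any(diff(time) <= 0)) stop("time axis must be strictly increasing")
  lo <- max(rt_window[1], min(time))
  hi <- min(rt_window[2], max(time))
  if (lo >= hi) stop("integration window does not overlap the time axis")
  inside <- time > lo & time < hi
  t <- c(lo, time[inside], hi)
  y <- c(stats::approx(time, intensity, lo)$y,
         intensity[inside],
         stats::approx(time, intensity, hi)$y)
  area <- pracma::trapz(t, y)
  if (baseline == "linear") {
    base <- (y[1] + y[length(y)]) / 2 * (hi - lo)
    area <- area - base
  }
  max(0, area)
}

#' Absolute concentration from a light/heavy area pair
#'
#' Stable-isotope dilution: `concentration = (light_area / heavy_area) *
#' spike`, where `spike` is the amount of heavy internal standard added per
#' microliter of sample.
#'
#' @param light_area,heavy_area Integrated peak areas.
#' @param spike Internal-standard spike level (fmol/ul).
#' @return List with `ratio`, `concentration` (fmol/ul) and `ok`. When
#'   `heavy_area` is zero, `ok` is `FALSE` and the numeric fields are `NA`
#'   (quantification failure, not zero).
#' @export
absolute_quant <- function(light_area, heavy_area, spike) {
  stopifnot(light_area >= 0, heavy_area >= 0, spike > 0)
  if (heavy_area == 0)
    return(list(ratio = NA_real_, concentration = NA_real_, ok = FALSE))
  r <- light_area / heavy_area
  list(ratio = r, concentration = r * spike, ok = TRUE)
}

#' Recovery of a peptide through sample preparation
#'
#' The change in light/heavy ratio between a spiked, processed sample and
#' the unprocessed reference mixture: `100 * spiked_ratio / reference_ratio`
#' percent.
#'
#' @param spiked_ratio Light/heavy ratio measured after processing.
#' @param reference_ratio Light/heavy ratio of the directly measured
#'   mixture.
#' @return Recovery in percent.
#' @export
recovery <- function(spiked_ratio, reference_ratio) {
  if (reference_ratio <= 0) stop("reference ratio must be positive")
  100 * spiked_ratio / reference_ratio
}

#' Remaining fraction of a peptide over an incubation time course
#'
#' Normalizes light/heavy intensity ratios to the baseline time point:
#' `fraction(t) = ratio(t) / ratio(baseline)`; 1 at baseline by
#' construction. Used to read out peptide stability under different
#' denaturing conditions.
#'
#' @param times Numeric time points.
#' @param ratios Light/heavy intensity ratios at `times`.
#' @param baseline_time The baseline time point (must be in `times`).
#' @return Data.frame with `time` and `fraction`.
#' @export
stability_series <- function(times, ratios, baseline_time = min(times)) {
  stopifnot(length(times) == length(ratios))
  i0 <- which(times == baseline_time)
  if (length(i0) != 1) stop("baseline time point missing or duplicated")
  if (ratios[i0] <= 0) stop("baseline ratio must be positive")
  data.frame(time = times, fraction = ratios / ratios[i0])
}

#' Linearity, precision and limit of quantification of a dilution series
#'
#' Fits normalized response against nominal amount by least squares (on the
#' log10 scale by default, matching how dilution curves spanning several
#' orders of magnitude are assessed), computes the per-level coefficient of
#' variation over replicates, and derives the LOQ as the lowest level whose
#' CV passes `cv_threshold` with all higher levels passing too. Dynamic
#' range is `log10(top level / LOQ)`.
#'
#' @param nominal Numeric vector of nominal amounts (one per measurement).
#' @param response Numeric vector of measured responses (e.g. light/heavy
#'   ratio or normalized area), parallel to `nominal`.
#' @param cv_threshold Maximum acceptable CV, percent.
#' @param log_scale Fit on log10-log10 scale (default) or linear.
#' @return List of class `"dilution_report"`: `levels` (data.frame with
#'   `nominal`, `n`, `mean`, `cv_percent`, `pass`), `fit`
#'   (`slope`, `intercept`, `r_squared`), `loq` (`NA` if no level passes,
#'   with `loq_defined = FALSE`), `dynamic_range_orders`.
#' @export
linearity_loq <- function(nominal, response, cv_threshold = 20,
                          log_scale = TRUE) {
  stopifnot(length(nominal) == length(response))
  lv <- sort(unique(nominal))
  if (length(lv) < 3) stop("need at least 3 dilution levels")
  per <- lapply(lv, function(x) {
    y <- response[nominal == x]
    if (length(y) < 2) stop("need >= 2 replicates per level (level ", x, ")")
    m <- mean(y)
    data.frame(nominal = x, n = length(y), mean = m,
               cv_percent = if (m > 0) 100 * stats::sd(y) / m else Inf)
  })
  levels <- do.call(rbind, per)
  levels$pass <- levels$cv_percent <= cv_threshold
  x <- if (log_scale) log10(levels$nominal) else levels$nominal
  y <- if (log_scale) log10(levels$mean) else levels$mean
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  # LOQ: lowest level passing such that every higher level passes as well
  loq <- NA_real_
  for (i in seq_len(nrow(levels))) {
    if (all(levels$pass[i:nrow(levels)])) { loq <- levels$nominal[i]; break }
  }
  structure(list(
    levels = levels,
    fit = list(slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2),
    loq = loq, loq_defined = !is.na(loq),
    dynamic_range_orders = if (is.na(loq)) NA_real_
                           else log10(max(levels$nominal) / loq),
    cv_threshold = cv_threshold), class = "dilution_report")
}

#' @export
print.dilution_report <- function(x, ...) {
  cat(sprintf("<dilution_report> %d levels, R^2 = %.4f, LOQ = %s, range = %s orders\n",
              nrow(x$levels), x$fit$r_squared,
              if (x$loq_defined) format(x$loq) else "undefined",
              if (x$loq_defined) sprintf("%.2f", x$dynamic_range_orders) else "NA"))
  invisible(x)
}

#' Carry-over and light/heavy cross-talk assessment
#'
#' Carry-over per transition is `100 * blank area / preceding sample area`
#' (a blank injected after a sample); cross-talk is
#' `100 * counterpart-channel area / injected-channel area` when only one
#' isotopic form was injected.
#'
#' @param sample_areas,blank_areas Named numeric vectors of areas keyed by
#'   transition; each blank must follow the like-named sample in run order.
#' @param injected_areas,counterpart_areas Named numeric vectors for the
#'   cross-talk experiment (single-form injections).
#' @return List with data.frames `carryover` (`transition`,
#'   `carryover_percent`) and `crosstalk` (`transition`,
#'   `crosstalk_percent`). Transitions lacking a preceding sample are
#'   skipped with a warning.
#' @export
carryover_and_crosstalk <- function(sample_areas, blank_areas,
                                    injected_areas = numeric(),
                                    counterpart_areas = numeric()) {
  keys <- names(blank_areas)
  have <- keys %in% names(sample_areas)
  if (any(!have))
    warning("no preceding sample for transition(s): ",
            paste(keys[!have], collapse = ", "), "; skipped")
  keys <- keys[have]
  carry <- data.frame(
    transition = keys,
    carryover_percent = 100 * unname(blank_areas[keys]) /
      unname(sample_areas[keys]),
    stringsAsFactors = FALSE)
  ck <- intersect(names(injected_areas), names(counterpart_areas))
  cross <- data.frame(
    transition = ck,
    crosstalk_percent = if (length(ck))
      100 * unname(counterpart_areas[ck]) / unname(injected_areas[ck])
    else numeric(0),
    stringsAsFactors = FALSE)
  list(carryover = carry, crosstalk = cross)
}

#' Compare peptide concentrations across groups (rank-based)
#'
#' Kruskal-Wallis test followed by Dunn's pairwise post test with
#' multiplicity adjustment. A convenience wrapper around standard
#' statistics, not a novel method.
#'
#' @param values Numeric vector of concentrations.
#' @param groups Factor or character vector of group labels, parallel to
#'   `values`; at least two non-empty groups.
#' @param p_adjust Adjustment method for the pairwise p-values
#'   (default Bonferroni).
#' @return List with `kruskal` (`statistic`, `p_value`, `df`) and `dunn`
#'   (data.frame of pairwise `z` and adjusted `p_value`).
#' @export
group_compare <- function(values, groups, p_adjust = "bonferroni") {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 1)) stop("every group needs at least 1 observation")
  kw <- stats::kruskal.test(values, groups)
  # Dunn's z: difference of mean ranks scaled by the tie-corrected
  # variance of the rank sum
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / ns[p[1]] + 1 / ns[p[2]]))
    (rbar[p[1]] - rbar[p[2]]) / se
  })
  praw <- 2 * stats::pnorm(-abs(z))
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = as.numeric(z),
                     p_value = stats::p.adjust(praw, method = p_adjust),
                     stringsAsFactors = FALSE)
  list(kruskal = list(statistic = unname(kw$statistic),
                      p_value = kw$p.value,
                      df = unname(kw$parameter)),
       dunn = dunn)
}

#' Read MRM chromatograms from long-format CSV
#'
#' Expected columns: `transition_id`, `time_min`, `intensity`.
#'
#' @param path CSV path.
#' @return Named list of data.frames (`time`, `intensity`), one per
#'   transition, times sorted ascending.
#' @export
read_chromatograms <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transition_id", "time_min", "intensity")
  if (!all(need %in% names(tab)))
    stop("chromatogram CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$transition_id), function(d) {
    d <- d[order(d$time_min), ]
    data.frame(time = d$time_min, intensity = d$intensity)
  })
}

#' Normalized peak areas of a precursor's transitions
#'
#' Each transition's area divided by the summed areas of all transitions of
#' that precursor; used to detect background interference as a shift in the
#' relative transition pattern.
#'
#' @param areas Named numeric vector of transition areas for one precursor.
#' @return Named numeric vector summing to 1 (all-zero input returns
#'   zeros).
#' @export
normalized_areas <- function(areas) {
  s <- sum(areas)
  if (s == 0) return(areas)
  areas / s
}
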