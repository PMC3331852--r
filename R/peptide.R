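#' Construct a peptide
#'
#' A peptide is a sequence of canonical amino acids plus optional fixed
#' modifications and an optional stable-isotope label scheme. It is the unit
#' from which all precursor and fragment masses derive.
#'
#' @param sequence Character scalar; uppercase one-letter codes for the 20
#'   canonical amino acids.
#' @param modifications `NULL` or a data.frame with columns `position`
#'   (integer residue index, 1-based; `0` denotes the N-terminus and
#'   `length + 1` the C-terminus), `mass_delta` (Da) and `name`.
#' @param label `NULL` or a [label_scheme()].
#' @return An object of class `"peptide"`.
#' @examples
#' peptide("DSGEGDFLAEGGGVR", label = label_scheme(residue_rule("G", n_13C = 1)))
#' @export
peptide <- function(sequence, modifications = NULL, label = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty character scalar")
  letters <- strsplit(sequence, "")[[1]]
  known <- names(MASS_CONSTANTS$residues)
  bad <- which(!letters %in% known)
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 letters[bad[1]], bad[1], sequence))
  n <- length(letters)
  if (!is.null(modifications)) {
    stopifnot(is.data.frame(modifications),
              all(c("position", "mass_delta", "name") %in% names(modifications)))
    pos <- modifications$position
    if (any(pos < 0 | pos > n + 1L))
      stop("modification positions must lie in 0..length+1 (0 = N-term, length+1 = C-term)")
  }
  if (!is.null(label)) {
    stopifnot(inherits(label, "label_scheme"))
    for (rule in label$rules) {
      if (!is.na(rule$position) && (rule$position < 1L || rule$position > n))
        stop(sprintf("label position %d outside 1..%d", rule$position, n))
      if (!is.na(rule$target) && !any(letters == rule$target))
        stop(sprintf("label targets residue '%s' absent from '%s'", rule$target, sequence))
    }
  }
  structure(list(sequence = sequence, residues = letters,
                 modifications = modifications, label = label),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide>", x$sequence, "\n")
  if (!is.null(x$modifications) && nrow(x$modifications))
    cat("  modifications:",
        paste(sprintf("%s@%s", x$modifications$name, x$modifications$position),
              collapse = ", "), "\n")
  if (!is.null(x$label)) cat("  label:", format_label(x$label), "\n")
  invisible(x)
}

#' @export
length.peptide <- function(x) length(x$residues)

#' Stable-isotope label rule
#'
#' A rule places `n_13C` carbon-13 and `n_15N` nitrogen-15 substitutions on
#' every residue matching `target` (a one-letter code), or on the single
#' residue at `position`. The per-rule mass delta is
#' `n_13C * 1.003355 + n_15N * 0.997035` Da.
#'
#' @param target One-letter residue code, or `NA` when `position` is given.
#' @param position 1-based residue index, or `NA` when `target` is given.
#' @param n_13C,n_15N Non-negative integer isotope counts.
#' @return A list of class `"label_rule"`.
#' @export
residue_rule <- function(target = NA_character_, n_13C = 0L, n_15N = 0L,
                         position = NA_integer_) {
  if (is.na(target) == is.na(position))
    stop("exactly one of target or position must be given")
  if (n_13C < 0 || n_15N < 0) stop("isotope counts must be non-negative")
  structure(list(target = target, position = as.integer(position),
                 n_13C = as.integer(n_13C), n_15N = as.integer(n_15N)),
            class = "label_rule")
}

#' @rdname residue_rule
#' @param ... `label_rule` objects.
#' @export
label_scheme <- function(...) {
  rules <- list(...)
  if (!all(vapply(rules, inherits, TRUE, "label_rule")))
    stop("all arguments must be label_rule objects")
  structure(list(rules = rules), class = "label_scheme")
}

rule_delta <- function(rule)
  rule$n_13C * MASS_CONSTANTS$d13C + rule$n_15N * MASS_CONSTANTS$d15N

format_label <- function(label) {
  paste(vapply(label$rules, function(r) {
    iso <- c(if (r$n_13C > 0) sprintf("13C%d", r$n_13C),
             if (r$n_15N > 0) sprintf("15N%d", r$n_15N))
    sprintf("%s@%s", paste(iso, collapse = ","),
            if (is.na(r$target)) r$position else r$target)
  }, character(1)), collapse = " ")
}

#' Per-residue label mass deltas for a peptide
#'
#' Expands a peptide's label scheme into one mass delta per residue position.
#' Residue-targeted rules apply to every matching residue; positional rules
#' to exactly one. Rules compose additively.
#'
#' @param pep A [peptide()].
#' @return Numeric vector, one delta (Da) per residue.
#' @export
label_deltas <- function(pep) {
  n <- length(pep$residues)
  d <- numeric(n)
  if (is.null(pep$label)) return(d)
  for (rule in pep$label$rules) {
    if (!is.na(rule$target)) {
      hit <- pep$residues == rule$target
    } else {
      hit <- seq_len(n) == rule$position
    }
    d[hit] <- d[hit] + rule_delta(rule)
  }
  d
}

# modification deltas mapped onto residue positions; terminal mods are
# assigned to residue 1 (N-term) / residue n (C-term) so that fragment spans
# pick them up on the correct side.
mod_deltas <- function(pep) {
  n <- length(pep$residues)
  d <- numeric(n)
  if (is.null(pep$modifications)) return(d)
  for (i in seq_len(nrow(pep$modifications))) {
    p <- pep$modifications$position[i]
    p <- if (p == 0L) 1L else if (p == n + 1L) n else p
    d[p] <- d[p] + pep$modifications$mass_delta[i]
  }
  d
}

#' Parse a peptide specification string
#'
#' Mini-grammar: `"<SEQUENCE> [label=<rule>[;<rule>...]]"` where each rule is
#' `"13C<k>[,15N<k>]@<target>"` and the target is either a residue letter
#' (rule applies to every such residue) or a 1-based position. Examples:
#' `"DSGEGDFLAEGGGVR label=13C1@G"` (one 13C in each glycine) and
#' `"SSKITHRIHWESASLL label=13C6,15N1@15"` (13C6 + 15N on residue 15).
#'
#' @param text Character scalar.
#' @return A [peptide()].
#' @export
parse_peptide_spec <- function(text) {
  text <- trimws(text)
  parts <- strsplit(text, "\\s+")[[1]]
  seq <- parts[1]
  label <- NULL
  if (length(parts) > 1) {
    kv <- parts[-1]
    lab <- kv[startsWith(kv, "label=")]
    if (length(lab) != length(kv) || length(lab) > 1)
      stop("unrecognized token(s) in peptide spec: ",
           paste(setdiff(kv, lab), collapse = " "))
    if (length(lab)) {
      rules <- lapply(strsplit(sub("^label=", "", lab), ";")[[1]], parse_label_rule)
      label <- do.call(label_scheme, rules)
    }
  }
  peptide(seq, label = label)
}

parse_label_rule <- function(txt) {
  m <- regmatches(txt, regexec("^([0-9A-Za-z,]+)@(.+)$", txt))[[1]]
  if (length(m) != 3) stop("cannot parse label rule: ", txt)
  n13 <- 0L; n15 <- 0L
  for (iso in strsplit(m[2], ",")[[1]]) {
    im <- regmatches(iso, regexec("^1([35])([CN])([0-9]+)$", iso))[[1]]
    if (length(im) != 4) stop("cannot parse isotope token: ", iso)
    if (im[2] == "3" && im[3] == "C") n13 <- n13 + as.integer(im[4])
    else if (im[2] == "5" && im[3] == "N") n15 <- n15 + as.integer(im[4])
    else stop("unsupported isotope token: ", iso)
  }
  tgt <- m[3]
  if (grepl("^[0-9]+$", tgt))
    residue_rule(position = as.integer(tgt), n_13C = n13, n_15N = n15)
  else
    residue_rule(target = tgt, n_13C = n13, n_15N = n15)
}
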