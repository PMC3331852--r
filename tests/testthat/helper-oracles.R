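# Independent oracle implementations used to cross-check package results.
# These deliberately share no code with the package internals.

# binned cosine on sqrt intensities via data.frame merge
oracle_cosine <- function(mz_a, int_a, mz_b, int_b, bin = 0.05) {
  agg <- function(mz, int) {
    d <- stats::aggregate(list(v = sqrt(int)), list(bin = floor(mz / bin)), sum)
    d
  }
  m <- merge(agg(mz_a, int_a), agg(mz_b, int_b), by = "bin", all = TRUE)
  m[is.na(m)] <- 0
  num <- sum(m$v.x * m$v.y)
  den <- sqrt(sum(m$v.x^2)) * sqrt(sum(m$v.y^2))
  if (den == 0) 0 else num / den
}

# exhaustive mean-similarity representative choice, tie -> smallest id
oracle_representative <- function(spectra) {
  n <- length(spectra)
  if (n == 1) return(1L)
  means <- sapply(seq_len(n), function(i) {
    mean(sapply(setdiff(seq_len(n), i), function(j)
      oracle_cosine(spectra[[i]]$mz, spectra[[i]]$intensity,
                    spectra[[j]]$mz, spectra[[j]]$intensity)))
  })
  cand <- which(abs(means - max(means)) <= 1e-12)
  ids <- sapply(spectra[cand], function(s) s$spectrum_id)
  cand[order(ids)[1]]
}

# exhaustive top-n selection: max matched intensity, tie by product m/z
oracle_topn <- function(product_mz, spec_mz, spec_int, n, tol = 0.05) {
  score <- sapply(product_mz, function(mz) {
    hit <- abs(spec_mz - mz) <= tol
    if (any(hit)) max(spec_int[hit]) else 0
  })
  keep <- which(score > 0)
  keep <- keep[order(-score[keep], product_mz[keep])]
  head(keep, n)
}

random_test_peptide <- function(min_len = 2, max_len = 25) {
  aa <- names(nativemrm::MASS_CONSTANTS$residues)
  paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

# the three assay peptides with light and heavy forms
assay_forms <- function() {
  p <- triplex_peptides()
  lapply(p, function(x) list(
    light = peptide(x$sequence),
    heavy = peptide(x$sequence, label = x$label),
    spike = x$spike_fmol_ul))
}
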