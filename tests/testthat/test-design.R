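test_that("candidate enumeration matches combinatorial expectations", {
  # unconstrained: |pz| * |series| * (n-1) * |fz| for a 15-mer
  wide <- enumeration_settings(min_index = 1, mz_min = 1, mz_max = 1e6)
  cands <- enumerate_candidates(peptide("DSGEGDFLAEGGGVR"), wide)
  expect_equal(nrow(cands), 3 * 2 * 14 * 2)
  # dipeptide, single precursor charge, y only -> one candidate
  tiny <- enumeration_settings(precursor_charges = 1L,
                               fragment_charges = 1L, series = "y",
                               min_index = 1, mz_min = 1, mz_max = 1e6)
  gg <- enumerate_candidates(peptide("GG"), tiny)
  expect_equal(nrow(gg), 1)
  expect_equal(gg$fragment, "y1")
  # deterministic ordering: precursor charge, series, index, fragment charge
  o <- order(cands$precursor_charge,
             match(cands$series, c("y", "b")), cands$index,
             cands$fragment_charge)
  expect_equal(o, seq_len(nrow(cands)))
  # the window filters product ions only
  all_cands <- enumerate_candidates(peptide("DSGEGDFLAEGGGVR"))
  expect_true(all(all_cands$product_mz >= 150 &
                    all_cands$product_mz <= 2000))
  expect_true(any(all_cands$precursor_mz < 150 * 4))
  # every m/z agrees with direct mass computation
  i <- sample(nrow(all_cands), 10)
  expect_equal(all_cands$product_mz[i],
               mapply(function(s, k, z)
                 fragment_mz(peptide("DSGEGDFLAEGGGVR"), s, k, z),
                 all_cands$series[i], all_cands$index[i],
                 all_cands$fragment_charge[i]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("default settings give 459 candidates over the three assay peptides", {
  total <- sum(sapply(triplex_peptides(), function(p)
    nrow(enumerate_candidates(peptide(p$sequence)))))
  expect_equal(total, 459)
})

test_that("ranking against a spectrum equals the exhaustive sort oracle", {
  pep <- peptide("DSGEGDFLAEGGGVR")
  cands <- enumerate_candidates(pep,
    enumeration_settings(precursor_charges = 2L, min_index = 1))
  # synthetic spectrum with planted intensity order over 8 candidates
  set.seed(21)
  picked <- sample(nrow(cands), 8)
  spec <- spectrum("planted", precursor_mz(pep, 2), 2L,
                   mz = cands$product_mz[picked],
                   intensity = c(80, 10, 60, 90, 20, 70, 30, 40))
  for (n in c(3, 5, 8, 12)) {
    sel <- rank_and_select(cands, spec, n)
    oracle <- oracle_topn(cands$product_mz, spec$mz, spec$intensity, n)
    expect_equal(nrow(sel), min(n, 8))
    expect_equal(sel$product_mz, cands$product_mz[oracle])
    expect_equal(sel$score, sort(sel$score, decreasing = TRUE))
  }
  # exactly one matched candidate -> it ranks first, everything else dropped
  spec1 <- spectrum("one", precursor_mz(pep, 2), 2L,
                    mz = cands$product_mz[5], intensity = 100)
  sel1 <- rank_and_select(cands, spec1, 5)
  expect_equal(nrow(sel1), 1)
  expect_equal(sel1$product_mz, cands$product_mz[5])
  # padding with zero-score candidates only on request
  sel_pad <- rank_and_select(cands, spec1, 5, pad_zero = TRUE)
  expect_equal(nrow(sel_pad), 5)
  expect_error(rank_and_select(cands, spec1, 0), "n must be")
  empty <- rank_and_select(cands[0, ], spec1, 3)
  expect_equal(nrow(empty), 0)
})

test_that("library-guided selection follows the spectrum's intensity order", {
  # FIBA 2+ spectrum with y8 > y7 > y5 dominating
  sim <- simulate_spectra("DSGEGDFLAEGGGVR", 2, seed = 2,
                          intensities = c(y8 = 100, y7 = 80, y5 = 60))
  cands <- enumerate_candidates(peptide("DSGEGDFLAEGGGVR"))
  cands <- cands[cands$precursor_charge == 2, ]
  top3 <- rank_and_select(cands, sim$spectra[[1]], 3)
  expect_setequal(top3$fragment, c("y8", "y7", "y5"))
  expect_equal(top3$fragment[1], "y8")
})

test_that("b2-dominant precursors select only doubly charged b-ions", {
  pep <- peptide("SSKITHRIHWESASLL")
  cands <- enumerate_candidates(pep)
  for (z in c(3L, 4L)) {
    sim <- simulate_spectra(pep, z, seed = 4, profile = "b2-dominant")
    sel <- rank_and_select(cands[cands$precursor_charge == z, ],
                           sim$spectra[[1]], 5)
    expect_equal(nrow(sel), 5)
    expect_true(all(sel$series == "b" & sel$fragment_charge == 2))
  }
})

test_that("heavy counterparts shift only fragments containing the label", {
  p <- triplex_peptides()
  fib <- peptide(p$FIBA$sequence)
  cands <- enumerate_candidates(fib)
  light <- cands[cands$precursor_charge == 2 &
                   cands$fragment %in% c("y8", "y7", "y5") &
                   cands$fragment_charge == 1, ]
  pair <- heavy_counterparts(light, p$FIBA$label)
  expect_equal(nrow(pair$heavy), nrow(pair$light))
  expect_equal(pair$heavy$fragment, pair$light$fragment)
  y8 <- which(pair$light$fragment == "y8")
  expect_equal(mz_round(pair$light$product_mz[y8]), 758.42)
  expect_equal(mz_round(pair$heavy$product_mz[y8]), 761.43)
  # CO3 b14 2+ identical light/heavy (label outside span)
  co3 <- peptide(p$CO3$sequence)
  c3 <- enumerate_candidates(co3)
  b14 <- c3[c3$precursor_charge == 3 & c3$fragment == "b14" &
              c3$fragment_charge == 2, ]
  pr <- heavy_counterparts(b14, p$CO3$label)
  expect_equal(pr$heavy$product_mz, pr$light$product_mz)
  expect_equal(mz_round(pr$heavy$product_mz), 810.92)
  # empty label -> heavy equals light
  id <- heavy_counterparts(light, NULL)
  expect_equal(id$heavy$product_mz, id$light$product_mz)
  expect_equal(id$heavy$precursor_mz, id$light$precursor_mz)
})

test_that("CE/DP assignment uses the fixture with linear fallback", {
  tr <- data.frame(sequence = "DSGEGDFLAEGGGVR", precursor_charge = 2L,
                   precursor_mz = 733.331, fragment = "y8",
                   stringsAsFactors = FALSE)
  out <- assign_ce_dp(tr, "fixture-table")
  expect_equal(out$dp, 85)
  expect_equal(out$ce, 38.3)
  tr2 <- data.frame(sequence = "SSKITHRIHWESASLL", precursor_charge = 4L,
                    precursor_mz = 467.006, fragment = "b13",
                    stringsAsFactors = FALSE)
  out2 <- assign_ce_dp(tr2, "fixture-table")
  expect_equal(out2$dp, 70)
  expect_equal(out2$ce, 21.7)
  # linear model arithmetic
  out3 <- assign_ce_dp(tr, "linear-default",
                       model = ce_dp_model(ce_slope = c("2" = 0.044),
                                           ce_intercept = c("2" = 5.5),
                                           dp = c("2" = 85)))
  expect_equal(out3$ce, 0.044 * 733.331 + 5.5, tolerance = 1e-6)
  # missing fixture entry falls back with a warning
  tr4 <- tr; tr4$fragment <- "y9"
  expect_warning(out4 <- assign_ce_dp(tr4, "fixture-table"),
                 "missing from the fixture")
  expect_equal(out4$ce, 0.044 * 733.331 + 5.5, tolerance = 1e-6)
})

test_that("the reference panel pairs 1:1 and exports a stable CSV", {
  panel <- triplex_panel()
  expect_equal(nrow(panel$light), 10)
  expect_equal(nrow(panel$heavy), 10)
  expect_equal(panel$heavy$fragment, panel$light$fragment)
  expect_equal(panel$heavy$fragment_charge, panel$light$fragment_charge)
  expect_equal(panel$heavy$dp, panel$light$dp)
  path <- withr::local_tempfile(fileext = ".csv")
  export_transition_list(panel, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 20)
  expect_named(tab, c("Q1", "Q3", "dwell_ms", "name", "DP", "CE"))
  expect_true(all(tab$dwell_ms == 30))
  # byte-stable exports
  path2 <- withr::local_tempfile(fileext = ".csv")
  export_transition_list(triplex_panel(), path2)
  expect_identical(readLines(path), readLines(path2))
  # every printed Q1/Q3 value appears in the reference table
  expect_true(all(c(733.33, 735.84, 622.34, 624.68, 467.01, 468.76,
                    580.65, 582.99) %in% tab$Q1))
})
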