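make_records <- function(...) {
  defaults <- list(spectrum_id = "s1", sequence = "DSGEGDFLAEGGGVR",
                   charge = 2L, confidence = 0.99,
                   observed_neutral_mass = 1464.64810, is_decoy = FALSE,
                   proteins = "P1", modifications = list(NULL))
  supplied <- list(...)
  args <- defaults
  args[names(supplied)] <- supplied
  do.call(id_records, args)
}

test_that("pepXML round-trips simulated identification sets exactly", {
  sim <- simulate_identifications(sim_id_config(n_spectra = 40,
                                                n_forbidden_mod = 3),
                                  seed = 7)
  path <- withr::local_tempfile(fileext = ".pep.xml")
  write_pepxml(sim$records, path)
  back <- read_pepxml(path)
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$spectrum_id, sim$records$spectrum_id)
  expect_equal(back$sequence, sim$records$sequence)
  expect_equal(back$charge, sim$records$charge)
  expect_equal(back$is_decoy, sim$records$is_decoy)
  expect_equal(back$confidence, sim$records$confidence, tolerance = 1e-6)
  expect_equal(back$observed_neutral_mass,
               sim$records$observed_neutral_mass, tolerance = 1e-6)
  has_mod <- !sapply(sim$records$modifications, is.null)
  expect_equal(!sapply(back$modifications, is.null), has_mod)
  i <- which(has_mod)[1]
  expect_equal(back$modifications[[i]]$mass_delta,
               sim$records$modifications[[i]]$mass_delta, tolerance = 1e-6)
  expect_equal(back$modifications[[i]]$name,
               sim$records$modifications[[i]]$name)
})

test_that("decoy flag comes from the accession prefix", {
  path <- withr::local_tempfile(fileext = ".pep.xml")
  write_pepxml(make_records(spectrum_id = c("a", "b"),
                            sequence = c("GAVR", "GAVK"),
                            confidence = c(0.99, 0.99),
                            observed_neutral_mass = c(401.25, 373.24),
                            is_decoy = c(FALSE, FALSE),
                            proteins = c("sp|P1", "DECOY_sp|P1")), path)
  back <- read_pepxml(path)
  expect_equal(back$is_decoy, c(FALSE, TRUE))
})

test_that("inclusion filters reject on the first failing rule", {
  fib_mass <- monoisotopic_mass(peptide("DSGEGDFLAEGGGVR"))
  # confidence just under the cut
  r <- make_records(confidence = 0.94)
  out <- filter_identifications(r)
  expect_equal(nrow(out$retained), 0)
  expect_equal(out$rejected$reason, "confidence")
  # +1 13C isotope offset is accepted
  r <- make_records(observed_neutral_mass = fib_mass + 1.003355)
  expect_equal(nrow(filter_identifications(r)$retained), 1)
  # +2 accepted, +3 not
  r <- make_records(observed_neutral_mass = fib_mass + 2 * 1.003355)
  expect_equal(nrow(filter_identifications(r)$retained), 1)
  r <- make_records(observed_neutral_mass = fib_mass + 3 * 1.003355)
  expect_equal(filter_identifications(r)$rejected$reason, "mass")
  # mass off by more than 0.2 Da
  r <- make_records(observed_neutral_mass = fib_mass + 0.25)
  expect_equal(filter_identifications(r)$rejected$reason, "mass")
  # deamidation is not whitelisted
  r <- make_records(observed_neutral_mass = fib_mass + 0.984016,
                    modifications = list(data.frame(position = 3,
                                                    mass_delta = 0.984016,
                                                    name = "deamidation")))
  expect_equal(filter_identifications(r)$rejected$reason, "modification")
  # oxidation anywhere is fine; pyro-glu only at residue 1
  r <- make_records(sequence = "MGAVR",
                    observed_neutral_mass =
                      monoisotopic_mass(peptide("MGAVR")) + 15.994915,
                    modifications = list(data.frame(position = 1,
                                                    mass_delta = 15.994915,
                                                    name = "oxidation")))
  expect_equal(nrow(filter_identifications(r)$retained), 1)
  r <- make_records(sequence = "GQAVR",
                    observed_neutral_mass =
                      monoisotopic_mass(peptide("GQAVR")) - 17.026549,
                    modifications = list(data.frame(position = 2,
                                                    mass_delta = -17.026549,
                                                    name = "pyro-glu-Q")))
  expect_equal(filter_identifications(r)$rejected$reason, "modification")
})

test_that("decoys passing the filters go to FDR estimation, not the library", {
  fib_mass <- monoisotopic_mass(peptide("DSGEGDFLAEGGGVR"))
  r <- make_records(spectrum_id = c("t", "d"), is_decoy = c(FALSE, TRUE),
                    confidence = c(0.99, 0.99),
                    observed_neutral_mass = rep(fib_mass, 2))
  out <- filter_identifications(r)
  expect_equal(nrow(out$retained), 1)
  expect_equal(nrow(out$decoys), 1)
  expect_true(out$decoys$is_decoy)
})

test_that("filtering is idempotent and monotone in its thresholds", {
  sim <- simulate_identifications(sim_id_config(n_spectra = 300,
                                                p_false = 0.2,
                                                score_shape_false = c(6, 1)),
                                  seed = 11)
  out1 <- filter_identifications(sim$records)
  out2 <- filter_identifications(out1$retained)
  expect_equal(nrow(out2$retained), nrow(out1$retained))
  expect_equal(nrow(out2$rejected), 0)
  # stricter confidence keeps a subset
  n_loose <- nrow(filter_identifications(sim$records,
                                         filter_config(min_confidence = 0.9))$retained)
  n_strict <- nrow(filter_identifications(sim$records,
                                          filter_config(min_confidence = 0.99))$retained)
  expect_lte(n_strict, n_loose)
  # tighter mass tolerance keeps a subset
  n_tight <- nrow(filter_identifications(sim$records,
                                         filter_config(mass_tolerance = 0.02))$retained)
  n_wide <- nrow(filter_identifications(sim$records,
                                        filter_config(mass_tolerance = 0.2))$retained)
  expect_lte(n_tight, n_wide)
})

test_that("collapsing counts spectra, ions and peptides correctly", {
  r <- make_records(spectrum_id = c("a", "b", "c", "d"),
                    sequence = rep("GAVR", 4), charge = c(2L, 2L, 3L, 3L),
                    confidence = rep(0.99, 4),
                    observed_neutral_mass = rep(401.25, 4))
  lv <- collapse_levels(r)
  expect_equal(nrow(lv$spectra), 4)
  expect_equal(nrow(lv$ions), 2)
  expect_equal(nrow(lv$peptides), 1)
  lv0 <- collapse_levels(make_records()[0, ])
  expect_equal(sapply(lv0, nrow), c(spectra = 0, ions = 0, peptides = 0))
  # randomized sets match brute-force set construction
  set.seed(3)
  seqs <- replicate(30, random_test_peptide(4, 6))
  r <- id_records(spectrum_id = sprintf("s%d", 1:200),
                  sequence = sample(seqs, 200, replace = TRUE),
                  charge = sample(2:4, 200, replace = TRUE),
                  confidence = runif(200),
                  observed_neutral_mass = runif(200, 300, 2000),
                  is_decoy = runif(200) < 0.3)
  lv <- collapse_levels(r)
  expect_equal(nrow(lv$ions),
               length(unique(paste(r$sequence, r$charge))))
  expect_equal(nrow(lv$peptides), length(unique(r$sequence)))
  # a unit is decoy iff all supporting records are decoy
  for (s in unique(r$sequence)) {
    expect_equal(lv$peptides$is_decoy[lv$peptides$key == s],
                 all(r$is_decoy[r$sequence == s]))
  }
})

test_that("FDR is decoy/target per level, capped, NA when undefined", {
  r <- make_records(spectrum_id = sprintf("s%d", 1:102),
                    sequence = c(replicate(100, random_test_peptide(5, 8)),
                                 "WWWAAA", "WWWCCC"),
                    charge = 2L, confidence = 0.99,
                    observed_neutral_mass = 500,
                    is_decoy = c(rep(FALSE, 100), TRUE, TRUE))
  rep <- estimate_fdr(r)
  expect_equal(rep$fdr[rep$level == "spectrum"], 2 / 100)
  # no decoys -> 0 everywhere
  rep0 <- estimate_fdr(r[!r$is_decoy, ])
  expect_equal(rep0$fdr, rep(0, 3))
  # decoy ion with 3 supporting spectra counts 3 / 1 / 1 across levels
  r3 <- make_records(spectrum_id = c("t1", "d1", "d2", "d3"),
                     sequence = c("GAVR", "WWWK", "WWWK", "WWWK"),
                     charge = 2L, confidence = 0.99,
                     observed_neutral_mass = 500,
                     is_decoy = c(FALSE, TRUE, TRUE, TRUE))
  rep3 <- estimate_fdr(r3)
  expect_equal(rep3$decoy_count, c(3, 1, 1))
  # all decoys -> undefined, flagged
  repNA <- estimate_fdr(r3[r3$is_decoy, ])
  expect_true(all(is.na(repNA$fdr)))
  expect_setequal(attr(repNA, "undefined_levels"),
                  c("spectrum", "ion", "peptide"))
})

test_that("FDR report serializes to JSON", {
  r <- make_records(spectrum_id = c("a", "b"), sequence = c("GAVR", "WWWK"),
                    charge = 2L, confidence = 0.99,
                    observed_neutral_mass = 500,
                    is_decoy = c(FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_fdr_json(estimate_fdr(r), path)
  x <- jsonlite::read_json(path)
  expect_equal(x$spectrum$fdr, 1)
  expect_equal(x$peptide$target_count, 1)
})
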