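# Candidate selection, the shared-peak Poisson scorer, the one- and
# two-stage target-decoy searches, purge rules, FDR and the protein rule.

toy_db <- function(seqs, acc = sprintf("P%02d", seq_along(seqs))) {
  build_database(data.frame(accession = acc, description = "",
                            sequence = seqs))
}

# Noise-free spectrum of one peptide (singly charged b/y ions).
peptide_spectrum <- function(pep, charge = 2L, mass_error = 0) {
  theo <- fragment_ions(pep, charges = 1L)$mz
  make_spectrum(mz = sort(theo), intensity = rep(100, length(theo)),
                pepmass = (peptide_mass(pep) + mass_error +
                             charge * MASS_PROTON) / charge,
                charge = charge, peptide = pep)
}

test_that("candidate selection honours tolerance, isotopes and charge", {
  db <- toy_db(c("MKAAAAARGGGGGK", "MMMKLLLRPPPKEEEK"))
  pep <- digest_database(db, "semi", 2)
  st <- search_settings()
  target <- pep$sequence[10]
  sp <- peptide_spectrum(target)
  cand <- candidates(sp, pep, st)
  expect_true(target %in% cand$sequence)
  # one isotope off is still admitted, with the offset identified
  sp1 <- peptide_spectrum(target, mass_error = MASS_ISOTOPE)
  cand1 <- candidates(sp1, pep, st)
  row <- cand1[cand1$sequence == target, ][1, ]
  expect_equal(row$isotope, 1)
  expect_lt(abs(row$error), 1e-6)
  # out-of-range charge yields no candidates
  sp7 <- peptide_spectrum(target); sp7$charge <- 7L
  expect_equal(nrow(candidates(sp7, pep, st)), 0)
  # missing precursor is skipped with a warning
  spna <- peptide_spectrum(target); spna$pepmass <- NA_real_
  expect_warning(out <- candidates(spna, pep, st), "precursor")
  expect_equal(nrow(out), 0)
})

test_that("candidate selection equals the exhaustive mass scan", {
  db <- toy_db(c("MKAAAAARGGGGGK", "MMMKLLLRPPPKEEEK", "CCCKDDDRKKW"))
  pep <- digest_database(db, "semi", 2, len_range = c(4, 35))
  st <- search_settings(peptide_length = c(4, 35))
  set.seed(31)
  for (i in 1:25) {
    mass <- runif(1, min(pep$mass) - 1, max(pep$mass) + 3)
    z <- sample(1:3, 1)
    sp <- make_spectrum(mz = 500, intensity = 1,
                        pepmass = (mass + z * MASS_PROTON) / z,
                        charge = as.integer(z))
    got <- candidates(sp, pep, st)
    expect_identical(sort(unique(sprintf("%s@%d", got$sequence, got$start))),
                     oracle_candidates(sp, pep, st), info = i)
  }
})

test_that("the scorer matches all ions of a clean spectrum and none of a foreign one", {
  pep <- "AAAGGKLLR"
  sp <- peptide_spectrum(pep)
  theo1 <- fragment_ions(pep, charges = 1L)$mz
  # every singly charged theoretical ion is matched
  res <- score_psm(sp, pep, fragment_tolerance = 0.5)
  expect_gte(res$raw_score, length(theo1))
  expect_gt(res$score, 0)
  # a peptide sharing no ions scores zero with E-value 1
  far <- make_spectrum(mz = c(3000, 3100, 3200), intensity = rep(1, 3))
  res0 <- score_psm(far, pep, fragment_tolerance = 0.5)
  expect_equal(res0$raw_score, 0L)
  expect_equal(res0$e_value, 1)
  # empty peak list is defined
  res_empty <- score_psm(make_spectrum(numeric(0), numeric(0)), pep)
  expect_equal(res_empty$raw_score, 0L)
  expect_equal(res_empty$e_value, 1)
})

test_that("the Poisson tail of the E-value equals the summed series", {
  # k >= 5 at rate 2: independently summed series gives 0.05265302
  expect_equal(ppois(4, 2, lower.tail = FALSE),
               1 - sum(exp(-2) * 2^(0:4) / factorial(0:4)),
               tolerance = 1e-12)
  # engineered spectrum with known rate: 10 peaks spanning 1000 Da,
  # tol 0.5 => per-ion hit rate = 2*0.5/1000 * 10 = 0.01
  pep <- "AAAGGKLLR"
  n_theo <- nrow(fragment_ions(pep, charges = 1:2))
  peaks <- seq(500, 1500, length.out = 10)
  sp <- make_spectrum(mz = peaks, intensity = rep(1, 10))
  raw <- morphoproteo:::count_matched_ions(fragment_ions(pep, 1:2)$mz,
                                           sort(peaks), 0.5)
  lam <- n_theo * (2 * 0.5 / 1000) * 10
  want <- 1 - sum(exp(-lam) * lam^(seq_len(raw) - 1) /
                    factorial(seq_len(raw) - 1))
  got <- score_psm(sp, pep, fragment_tolerance = 0.5)
  expect_equal(got$e_value, want, tolerance = 1e-10)
})

test_that("a single-target database attributes clean spectra to it deterministically", {
  db <- toy_db("MKAVLDRGGELKTTPWKFFDAK")
  pep <- digest_database(db, "semi", 2)
  tryptic <- pep[pep$tryptic_termini == 2 & !pep$is_decoy, ]
  sets <- make_set("W:P01", lapply(tryptic$sequence[1:4], function(p)
    peptide_spectrum(p)))
  psm1 <- search_stage(list(sets), db, search_settings())
  psm2 <- search_stage(list(sets), db, search_settings())
  expect_identical(psm1, psm2)
  expect_true(all(!psm1$is_decoy))
  expect_equal(nrow(psm1), 4)
  expect_true(all(psm1$peptide %in% tryptic$sequence))
})

test_that("the two-stage search narrows to surviving proteins at 1:1 target:decoy", {
  db <- toy_db(c("MKAVLDRGGELKTTPWKFFDAK", "MCCCHHKWWYYRDDEEKPPLLK"))
  pep <- digest_database(db, "semi", 2)
  src <- pep[pep$accession == "P01" & pep$tryptic_termini == 2, ]
  sets <- make_set("W:P01", lapply(src$sequence[1:4], peptide_spectrum))
  out <- two_stage_search(list(sets), db, search_settings())
  expect_true(all(sub("^REV_", "", out$accession) == "P01"))
  stage1 <- attr(out, "stage1")
  expect_s3_class(stage1, "data.frame")
  # stage 2 cannot lose identifications relative to stage 1 here
  expect_gte(nrow(out), nrow(stage1) - sum(stage1$is_decoy))
})

test_that("purge removes ties, semi-tryptic termini and >2 missed cleavages", {
  base <- data.frame(
    spectrum_id = sprintf("s%d", 1:4), spot_id = "W:x",
    peptide = c("AAAAKR", "BBBB", "CCCC", "DDDD"),
    accession = "P01", is_decoy = FALSE, is_contaminant = FALSE,
    raw_score = c(10L, 9L, 8L, 7L), score = c(5, 4, 3, 2),
    e_value = 10^-c(5, 4, 3, 2), error = 0, charge = 2L,
    n_missed = c(0L, 0L, 3L, 2L), tryptic_termini = c(2L, 1L, 2L, 2L),
    n_candidates = 5L,
    best_target_raw = c(10, 9, 8, 7), best_decoy_raw = c(3, 2, 1, 7))
  out <- purge_psms(base)
  # row 2: semi-tryptic; row 3: 3 missed; row 4: target/decoy tie
  expect_equal(out$spectrum_id, "s1")
  # idempotent
  expect_identical(purge_psms(out), out)
})

test_that("a palindromic target produces a decoy tie that is purged", {
  # the reversal of this sequence equals itself, so its decoy is identical
  pal <- "AAKCDCKAA"
  expect_identical(reverse_sequence(pal), pal)
  db <- toy_db(pal)
  pep <- digest_database(db, "semi", 2, len_range = c(4, 35))
  st <- search_settings(peptide_length = c(4, 35))
  full <- pep[pep$tryptic_termini == 2 & !pep$is_decoy &
                pep$end - pep$start == nchar(pal), ]
  sets <- make_set("W:P01", list(peptide_spectrum(full$sequence[1])))
  psm <- search_stage(list(sets), db, st)
  expect_equal(psm$best_target_raw, psm$best_decoy_raw)
  expect_equal(nrow(purge_psms(psm)), 0)
})

test_that("FDR bookkeeping follows n_decoy / n_target on constructed inputs", {
  mk <- function(n, score, decoy) data.frame(
    spectrum_id = sprintf("x%d", seq_len(n) + 1000 * decoy + score),
    spot_id = "W:x",
    peptide = sprintf("PEP%d%d%03d", decoy, score, seq_len(n)),
    accession = ifelse(decoy, "REV_P", "P"), is_decoy = decoy,
    is_contaminant = FALSE, raw_score = score, score = score,
    e_value = 10^-score, error = 0, charge = 2L, n_missed = 0L,
    tryptic_termini = 2L, n_candidates = 1L,
    best_target_raw = NA_real_, best_decoy_raw = NA_real_)
  # 10 targets at score 5, 1 decoy at score 5, 5 targets at score 2
  psms <- rbind(mk(10, 5, FALSE), mk(1, 5, TRUE), mk(5, 2, FALSE))
  fdr <- compute_fdr(psms, search_settings(fdr_threshold = 0.11))
  rec5 <- fdr$records[fdr$records$score_threshold == 5, ]
  expect_equal(rec5$n_target, 10); expect_equal(rec5$n_decoy, 1)
  expect_equal(rec5$fdr, 0.1)
  expect_true(all(fdr$peptides$fdr[fdr$peptides$score == 5] == 0.1))
  # raw FDR is not monotonized: the score-2 threshold has fdr 1/15, so
  # all 15 target peptides pass at 0.11 (decoys are never reported)
  rec2 <- fdr$records[fdr$records$score_threshold == 2, ]
  expect_equal(rec2$fdr, 1 / 15)
  expect_equal(nrow(fdr$passing), 15)
  expect_true(all(!fdr$passing$is_decoy))
  # no decoys anywhere: FDR identically zero
  clean <- mk(8, 4, FALSE)
  fdr0 <- compute_fdr(clean, search_settings())
  expect_true(all(fdr0$records$fdr == 0))
  # peptide collapse: no sequence listed twice
  dup <- rbind(mk(3, 5, FALSE), mk(3, 5, FALSE))
  fdr_dup <- compute_fdr(dup, search_settings())
  expect_false(any(duplicated(fdr_dup$peptides$peptide)))
})

test_that("the protein rule requires more than two distinct peptides", {
  mk <- function(acc, peps) data.frame(peptide = peps, accession = acc)
  two <- identify_proteins(mk("P1", c("AAA", "BBB")))
  expect_false(two$identified)
  three <- identify_proteins(mk("P2", c("AAA", "BBB", "CCC")))
  expect_true(three$identified)
  # repeated observations of one peptide do not count twice
  rep3 <- identify_proteins(mk("P3", c("AAA", "AAA", "AAA")))
  expect_equal(rep3$n_peptides, 1)
  expect_false(rep3$identified)
  # singletons across many proteins identify nothing
  singles <- identify_proteins(mk(sprintf("Q%d", 1:6),
                                  sprintf("PEP%d", 1:6)))
  expect_equal(sum(singles$identified), 0)
})
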