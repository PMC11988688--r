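test_that("estimate_fdr_threshold reproduces the hand-evaluated estimator", {
  psms <- data.frame(sm_score = c(10, 9, 8, 8), is_decoy = c(FALSE, FALSE, FALSE, TRUE))
  r <- estimate_fdr_threshold(psms, level = 0.01)
  expect_equal(r$cutoff, 9)
  expect_equal(sum(r$accept), 2)
  # FDR at threshold 8 is 1/3; q-values at 10 and 9 are 0
  expect_equal(r$qvalue, c(0, 0, 1/3, 1/3))

  expect_warning(r0 <- estimate_fdr_threshold(
    data.frame(sm_score = rnorm(100, 10), is_decoy = FALSE)), "no decoy")
  expect_true(all(r0$accept))
  expect_equal(r0$qvalue, rep(0, 100))
  expect_error(estimate_fdr_threshold(
    data.frame(sm_score = 1, is_decoy = TRUE)), "no target")
})

test_that("q-values are monotone in score and accepted sets nest across levels", {
  set.seed(31)
  psms <- data.frame(sm_score = c(rnorm(400, 10, 2), rnorm(100, 5, 2)),
                     is_decoy = rep(c(FALSE, TRUE), c(400, 100)))
  r <- estimate_fdr_threshold(psms, level = 0.05)
  ord <- order(psms$sm_score, decreasing = TRUE)
  expect_true(all(diff(r$qvalue[ord]) >= 0))
  acc1 <- which(estimate_fdr_threshold(psms, level = 0.01)$accept)
  acc5 <- which(estimate_fdr_threshold(psms, level = 0.05)$accept)
  expect_true(all(acc1 %in% acc5))
})

test_that("per-run scope filters within runs before the aggregate check", {
  psms <- data.frame(
    sm_score = c(10, 9, 3, 10, 2, 2),
    is_decoy = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    run_id = c("a", "a", "a", "b", "b", "b"))
  r <- estimate_fdr_threshold(psms, level = 0.01, scope = "run")
  expect_named(r$run_cutoffs, c("a", "b"))
  expect_true(r$accept[4])        # run b's clean top target
  expect_false(r$accept[6])       # below run b's decoy
})

test_that("realized FDP at the 1% cutoff stays at or under 1% on labelled mixtures", {
  cfg <- sim_config(seed = 1, n_target = 2000, n_decoy = 200)
  fdp <- vapply(1:50, function(s) {
    sim <- simulate_psm_table(cfg, seed = s)
    r <- estimate_fdr_threshold(sim$psms, level = 0.01)
    correct <- sim$truth$is_correct[r$accept]
    mean(!correct)
  }, 0)
  # the estimator controls FDP in expectation; the seed mean is allowed two
  # binomial standard errors of sampling noise around the nominal level
  expect_lte(mean(fdp), 0.01 + 2 * sd(fdp) / sqrt(length(fdp)))
})

test_that("apply_fixed_thresholds uses inclusive boundaries and printed ranges", {
  base <- data.frame(sm_score = 7, spi_pct = 50, bcs = 5, charge = 2,
                     peptide = "ACDEFGHIK")
  expect_equal(nrow(apply_fixed_thresholds(base)), 1)  # all boundaries pass
  expect_equal(nrow(apply_fixed_thresholds(transform(base, sm_score = 6.99))), 0)
  expect_equal(nrow(apply_fixed_thresholds(transform(base, spi_pct = 49.9))), 0)
  expect_equal(nrow(apply_fixed_thresholds(transform(base, bcs = 4.9))), 0)
  expect_equal(nrow(apply_fixed_thresholds(transform(base, charge = 5))), 0)
  expect_equal(nrow(apply_fixed_thresholds(
    transform(base, peptide = "ACDEFGHIKLMW"))), 0)  # length 12
  expect_equal(nrow(apply_fixed_thresholds(
    transform(base, peptide = "ACDEFGH"))), 0)       # length 7
  expect_equal(nrow(apply_fixed_thresholds(
    transform(base, peptide = "ACDEFGHIKLM"))), 1)   # length 11
})

test_that("spectral_angle matches closed forms and its invariances", {
  a <- c(y1 = 2, y2 = 3, b2 = 0.5)
  expect_equal(spectral_angle(a, a), 1)
  expect_equal(spectral_angle(c(y1 = 1), c(b1 = 1)), 0)  # disjoint ions
  expect_equal(spectral_angle(c(y1 = 1, y2 = 0), c(y1 = 1, y2 = 1)), 0.5)
  expect_equal(spectral_angle(numeric(), c(y1 = 1)), 0)  # all-zero obs
  expect_error(spectral_angle(c(y1 = -1), c(y1 = 1)), "negative")

  set.seed(4)
  for (i in 1:10) {
    x <- setNames(runif(6), paste0("y", 1:6))
    y <- setNames(runif(6), paste0("y", c(1:4, 7, 8)))
    sa <- spectral_angle(x, y)
    expect_gte(sa, 0); expect_lte(sa, 1)
    expect_equal(spectral_angle(y, x), sa)                 # symmetry
    expect_equal(spectral_angle(3.7 * x, y), sa)           # scale invariance
    expect_equal(spectral_angle(x, 0.01 * y), sa)
  }
})

test_that("select_rt_calibration bins the RT range and ranks by score", {
  psms <- data.frame(rt_obs_min = c(10, 11, 12), sm_score = c(9, 8, 7),
                     source_class = "reference")
  top2 <- select_rt_calibration(psms, n_segments = 1, top_k = 2)
  expect_equal(top2$sm_score, c(9, 8))

  # erv-class PSMs are never used for calibration
  mixed <- rbind(psms, data.frame(rt_obs_min = 11, sm_score = 99,
                                  source_class = "erv"))
  expect_false(any(select_rt_calibration(mixed, 1, 10)$source_class == "erv"))

  # uniform toy over [0,100]: bin edges every 2 min, membership matches
  # brute-force binning
  set.seed(9)
  n <- 500
  psms <- data.frame(rt_obs_min = c(0, 100, runif(n - 2, 0, 100)),
                     sm_score = rnorm(n, 10, 2), source_class = "reference")
  got <- select_rt_calibration(psms, n_segments = 50, top_k = 3)
  bin <- pmin(floor(psms$rt_obs_min / 2) + 1, 50)
  want <- unlist(lapply(split(seq_len(n), bin), function(ix) {
    ix[order(psms$sm_score[ix], decreasing = TRUE)][seq_len(min(3, length(ix)))]
  }))
  expect_setequal(got$rt_obs_min, psms$rt_obs_min[want])
  expect_equal(nrow(select_rt_calibration(psms[0, ], 50, 15)), 0)
})

test_that("binder_category follows the printed brackets", {
  expect_equal(binder_category(c(0.03, 0.499, 0.5, 1.7, 2.0, 2.001, 9)),
               c("strong", "strong", "weak", "weak", "weak", "non", "non"))
  expect_error(binder_category(-0.1), ">= 0")
})

test_that("strike_classify applies the documented pass boundaries and verdicts", {
  expect_equal(strike_classify(0.7, 5, 1.0)$verdict, "pass")
  expect_equal(strike_classify(0.5, 5, 1.0)$verdict, "maybe")
  expect_equal(strike_classify(0.5, 12, 2.5)$verdict, "fail")
  # boundary semantics: SA exactly 0.6 is a strike, |dRT| exactly 10
  # passes, rank exactly 2.0 is a strike (but still a weak binder)
  b <- strike_classify(0.6, -10, 2.0)
  expect_true(b$strike_spectrum)
  expect_false(b$strike_rt)
  expect_true(b$strike_binding)
  expect_equal(b$binder_category, "weak")
})

test_that("verdict is a pure function of the strikes, over all 8 combinations", {
  sa <- c(pass = 0.9, fail = 0.2)
  rt <- c(pass = 0, fail = 30)
  rk <- c(pass = 0.1, fail = 5)
  combos <- expand.grid(s = c("pass", "fail"), r = c("pass", "fail"),
                        k = c("pass", "fail"), stringsAsFactors = FALSE)
  got <- strike_classify(sa[combos$s], rt[combos$r], rk[combos$k])
  n_fail <- (combos$s == "fail") + (combos$r == "fail") + (combos$k == "fail")
  expect_equal(got$strikes, n_fail)
  expect_equal(got$verdict,
               ifelse(n_fail == 0, "pass", ifelse(n_fail == 1, "maybe", "fail")))
})

test_that("sequence_tag_length finds the longest residue-ladder path", {
  gly <- 57.02146; ala <- 71.03711
  expect_equal(sequence_tag_length(c(200, 200 + gly, 200 + gly + ala)), 2L)
  expect_equal(sequence_tag_length(c(200, 200 + gly)), 1L)
  expect_equal(sequence_tag_length(c(200, 300, 450)), 0L)
  expect_equal(sequence_tag_length(numeric()), 0L)
  # branching ladder: longest path wins
  peaks <- c(100, 100 + gly, 100 + ala, 100 + ala + gly, 100 + ala + gly + ala)
  expect_equal(sequence_tag_length(peaks), 3L)
})

test_that("peptide masses agree with atomic-mass arithmetic", {
  expect_equal(peptide_monoisotopic_mass("GG"),
               2 * oracle_residue_mass[["G"]] + 18.010565, tolerance = 1e-4)
  set.seed(14)
  for (i in 1:10) {
    pep <- random_peptide(sample(8:11, 1))
    want <- sum(oracle_residue_mass[strsplit(pep, "")[[1]]]) + 18.0105646863
    expect_equal(peptide_monoisotopic_mass(pep), want, tolerance = 1e-3)
  }
  expect_equal(peptide_monoisotopic_mass("GG", modifications = label_shift("lys8")),
               peptide_monoisotopic_mass("GG") + 8.0142, tolerance = 1e-3)
  expect_error(peptide_monoisotopic_mass(""), "non-empty")
  expect_error(peptide_monoisotopic_mass("GGZ"), "unknown residue")
})

test_that("finalize_peptide_calls runs the audited stage chain in order", {
  db <- data.frame(
    accession = c("R1", "ERV|e1|+1|0", "ERV|e2|+2|0"),
    sequence = c("AAAWKLNDYEK", "FFFWKLNDYEK", "MMMGGHHPPLV"),
    source_class = c("reference", "erv", "erv"),
    description = c("R1", "ERV|e1|+1|0", "ERV|e2|+2|0"))
  peps <- c(ref_hit = "WKLNDYEK",       # also in reference -> stage 1
            normal = "MMMGGHHP",        # seen in normal tissue -> stage 2
            dup = "GGHHPPLV",           # two PSMs -> one call at stage 3
            cys = "ACDEFGHI",           # cysteine -> stage 4
            strikes = "MGGHHPPL",       # 2 strikes -> stage 5
            keep = "GHHPPLV")
  psms <- data.frame(
    psm_id = sprintf("p%d", 1:7),
    peptide = c(peps[["ref_hit"]], peps[["normal"]], peps[["dup"]],
                peps[["dup"]], peps[["cys"]], peps[["strikes"]],
                peps[["keep"]]),
    stringsAsFactors = FALSE)
  maps <- lapply(setNames(nm = unique(psms$peptide)), map_peptide_sources, db = db)
  strikes <- data.frame(psm_id = psms$psm_id,
                        strikes = c(0, 0, 0, 1, 0, 2, 1))
  out <- finalize_peptide_calls(psms, maps, strikes,
                                normal_peptides = peps[["normal"]])
  expect_equal(out$audit$stage,
               c("input", "drop_reference_collisions", "drop_normal_tissue",
                 "collapse_duplicates", "drop_cysteine",
                 "drop_two_strike_failures"))
  expect_equal(out$audit$n_calls, c(7L, 6L, 5L, 4L, 3L, 2L))
  expect_true(all(diff(out$audit$n_calls) <= 0))
  expect_setequal(out$calls$peptide, c(peps[["dup"]], peps[["keep"]]))
  # the duplicate call kept both PSMs and its best verdict
  expect_equal(out$calls$n_psms[out$calls$peptide == peps[["dup"]]], 2L)
  expect_equal(out$calls$verdict[out$calls$peptide == peps[["dup"]]], "pass")
  # surviving peptides list their possible source ERVs
  expect_equal(out$calls$source_ervs[out$calls$peptide == peps[["keep"]]], "e2")

  expect_error(finalize_peptide_calls(psms, maps, strikes[-1, ]), "p1")
})

test_that("finalize stage order matters: normal-tissue exclusion precedes dedup", {
  db <- data.frame(accession = "ERV|e1|+1|0", sequence = "WWWLLLKKKQQ",
                   source_class = "erv", description = "ERV|e1|+1|0")
  psms <- data.frame(psm_id = c("p1", "p2"), peptide = "WLLLKKKQ",
                     stringsAsFactors = FALSE)
  maps <- lapply(setNames(nm = "WLLLKKKQ"), map_peptide_sources, db = db)
  strikes <- data.frame(psm_id = c("p1", "p2"), strikes = c(0, 0))
  out <- finalize_peptide_calls(psms, maps, strikes,
                                normal_peptides = "WLLLKKKQ")
  # both calls vanish at the normal-tissue stage, before dedup could merge
  expect_equal(out$audit$n_calls[out$audit$stage == "drop_normal_tissue"], 0L)
  expect_equal(nrow(out$calls), 0)
})
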