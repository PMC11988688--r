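mk_aln <- function(read_id, mate, txome_mapped, erv_id, nm,
                   frag_pos = 0L, orient = "+") {
  data.frame(read_id = read_id, mate = as.character(mate),
             txome_mapped = txome_mapped, erv_id = erv_id, nm = nm,
             frag_pos = frag_pos, orient = orient, stringsAsFactors = FALSE)
}

test_that("partition_reads is a loss-free partition on the transcriptome flag", {
  aln <- rbind(mk_aln(sprintf("r%d", 1:4), "1", c(TRUE, TRUE, FALSE, FALSE),
                      c(NA, NA, "e1", "e2"), 0L),
               mk_aln(sprintf("r%d", 1:4), "2", c(TRUE, TRUE, TRUE, FALSE),
                      c(NA, NA, NA, "e2"), 0L))
  p <- partition_reads(aln)
  expect_equal(nrow(p$transcriptome) + nrow(p$erv_candidates), nrow(aln))
  expect_true(all(p$transcriptome$txome_mapped))
  expect_true(all(!p$erv_candidates$txome_mapped))

  all_mapped <- mk_aln(sprintf("r%d", 1:10), "1", TRUE, NA, 0L)
  expect_equal(nrow(partition_reads(all_mapped)$erv_candidates), 0)
})

test_that("classify_pair implements the PM / 1MM / common-reference rules", {
  hit <- function(erv, nm) data.frame(erv_id = erv, nm = nm)
  expect_equal(classify_pair(hit("eA", 0), hit("eA", 0)),
               list(category = "PM", erv_ids = "eA"))
  expect_equal(classify_pair(hit("eA", 1), hit("eA", 0))$category, "MM1")
  expect_equal(classify_pair(hit("eA", 1), hit("eA", 1))$category, "none")
  # mates hitting only different ERVs never pair
  expect_equal(classify_pair(hit("eA", 0), hit("eB", 0))$category, "none")
  # PM on one ERV dominates MM1 on another; winners are category-specific
  r1 <- data.frame(erv_id = c("eA", "eB"), nm = c(0L, 0L))
  r2 <- data.frame(erv_id = c("eA", "eB"), nm = c(0L, 1L))
  got <- classify_pair(r1, r2)
  expect_equal(got$category, "PM")
  expect_equal(got$erv_ids, "eA")
})

test_that("retain_single_end enforces all three criteria", {
  perfect <- data.frame(erv_id = "eA", nm = 0L)
  expect_true(retain_single_end(perfect)$retained)
  expect_false(retain_single_end(perfect, pair_in_pe = TRUE)$retained)
  expect_false(retain_single_end(perfect, txome_mapped = TRUE)$retained)
  expect_false(retain_single_end(data.frame(erv_id = "eA", nm = 1L))$retained)
})

test_that("deduplicate_fragments keeps the first record per key and is idempotent", {
  ev <- data.frame(erv_id = c("e1", "e1", "e1", "e2"),
                   kind = c("pe_pm", "pe_pm", "se", "pe_pm"),
                   frag_pos = c(10L, 10L, 10L, 10L),
                   orient = "+",
                   tag = c("first", "dup", "single", "other_erv"))
  d <- deduplicate_fragments(ev)
  expect_equal(d$tag, c("first", "single", "other_erv"))
  expect_equal(deduplicate_fragments(d), d)

  # brute-force key grouping on a random instance with planted duplicates
  set.seed(8)
  n <- 400
  ev <- data.frame(erv_id = sample(c("e1", "e2", "e3"), n, replace = TRUE),
                   kind = sample(c("pe_pm", "pe_1mm", "se"), n, replace = TRUE),
                   frag_pos = sample(1:40, n, replace = TRUE),
                   orient = sample(c("+", "-"), n, replace = TRUE))
  d <- deduplicate_fragments(ev)
  key <- paste(ev$erv_id, ev$frag_pos, ev$orient,
               ifelse(ev$kind == "se", "se", "pe"))
  expect_equal(nrow(d), length(unique(key)))
})

test_that("compute_erv_expression applies the 2x pairs + 1x singles formula", {
  one_pm <- data.frame(erv_id = "e1", kind = "pe_pm", frag_pos = 1L, orient = "+")
  expect_equal(compute_erv_expression(one_pm)$expression_raw, 2L)
  expect_equal(compute_erv_expression(one_pm[0, ], erv_ids = "e1")$expression_raw, 0L)

  ev <- data.frame(erv_id = "e1",
                   kind = c(rep("pe_pm", 3), "pe_1mm", rep("se", 2)),
                   frag_pos = 1:6, orient = "+")
  got <- compute_erv_expression(ev)
  expect_equal(got$n_pe_pm, 3L)
  expect_equal(got$n_pe_1mm, 1L)
  expect_equal(got$n_se, 2L)
  expect_equal(got$expression_raw, 10L)
})

test_that("expression is conserved against a brute-force recount and is +2/+1 monotone", {
  set.seed(21)
  ev <- data.frame(erv_id = sample(sprintf("e%d", 1:5), 200, replace = TRUE),
                   kind = sample(c("pe_pm", "pe_1mm", "se"), 200, replace = TRUE),
                   frag_pos = seq_len(200), orient = "+")
  got <- compute_erv_expression(ev)
  for (e in got$erv_id) {
    sub <- ev[ev$erv_id == e, ]
    expect_equal(got$expression_raw[got$erv_id == e],
                 2 * sum(sub$kind != "se") + sum(sub$kind == "se"))
  }
  base <- got$expression_raw[got$erv_id == "e1"]
  plus_pe <- rbind(ev, data.frame(erv_id = "e1", kind = "pe_pm",
                                  frag_pos = 999L, orient = "+"))
  expect_equal(compute_erv_expression(plus_pe)$expression_raw[
    compute_erv_expression(plus_pe)$erv_id == "e1"], base + 2)
  plus_se <- rbind(ev, data.frame(erv_id = "e1", kind = "se",
                                  frag_pos = 999L, orient = "+"))
  expect_equal(compute_erv_expression(plus_se)$expression_raw[
    compute_erv_expression(plus_se)$erv_id == "e1"], base + 1)
})

test_that("normalize_expression uses the per-million, per-kilobase convention", {
  expect_equal(normalize_expression(10, 1e6, 1e3), 10)
  expect_equal(normalize_expression(0, 1e6, 1e3), 0)
  expect_equal(normalize_expression(7, 2e6, 500), 7)
  expect_error(normalize_expression(1, 0, 100), "library_size")
  expect_error(normalize_expression(1, 100, 0), "erv_length")
})

test_that("quantify_ervs integrates retention, dedup and counting", {
  # r1: PM pair on e1; r2: duplicate of r1 (same fragment key); r3: single
  # end whose mate went to the transcriptome; r4: pair with 2 mismatches
  # (rejected), its perfect mate is rescued as a single end? No - criterion
  # (ii) only blocks mates of *retained* pairs, and r4 is not retained, so
  # its perfect mate IS rescued.
  aln <- rbind(
    mk_aln("r1", "1", FALSE, "e1", 0L, 100L), mk_aln("r1", "2", FALSE, "e1", 0L, 120L),
    mk_aln("r2", "1", FALSE, "e1", 0L, 100L), mk_aln("r2", "2", FALSE, "e1", 0L, 120L),
    mk_aln("r3", "1", FALSE, "e1", 0L, 300L), mk_aln("r3", "2", TRUE, NA, 0L, 300L),
    mk_aln("r4", "1", FALSE, "e2", 0L, 50L), mk_aln("r4", "2", FALSE, "e2", 2L, 60L))
  q <- quantify_ervs(aln, c(e1 = 1000, e2 = 1000))
  e1 <- q[q$erv_id == "e1", ]
  expect_equal(e1$n_pe_pm, 1L)      # r2 removed as duplicate
  expect_equal(e1$n_se, 1L)         # r3 rescued
  expect_equal(e1$expression_raw, 3L)
  e2 <- q[q$erv_id == "e2", ]
  expect_equal(e2$n_pe_pm + e2$n_pe_1mm, 0L)
  expect_equal(e2$n_se, 1L)         # r4 mate 1 rescued under criterion (ii)
  expect_equal(q$library_size, c(8L, 8L))
  expect_equal(e1$expression_norm,
               normalize_expression(3, 8, 1000))
})

test_that("call_responsive applies fold-change, pseudocount and floor", {
  same <- call_responsive(c(5, 7), c(5, 7))
  expect_equal(same$log2fc, 0)
  expect_false(same$responsive)

  cr <- call_responsive(c(15), c(3), pseudocount = 1)
  expect_equal(cr$log2fc, 2)
  expect_true(cr$responsive)

  floor <- call_responsive(c(0.4), c(0))
  expect_false(floor$responsive)
  expect_error(call_responsive(numeric(), 1), "replicate")
})

test_that("tier_and_union tiers per cell line and unions without duplicates", {
  flags <- function(erv, cl, resp) {
    data.frame(erv_id = erv, cell_line = cl,
               comparison = c("VHL_vs_EV", "sgHIF2a_vs_sgCtrl", "PT_vs_Veh"),
               responsive = resp)
  }
  cf <- rbind(flags("eA", "786-O", c(TRUE, TRUE, TRUE)),
              flags("eB", "786-O", c(TRUE, TRUE, FALSE)),
              flags("eC", "786-O", c(TRUE, FALSE, FALSE)))
  pf <- data.frame(erv_id = "eC", cell_line = "786-O",
                   polysome_responsive = TRUE)
  tu <- tier_and_union(cf, pf)
  per <- tu$per_cell_line
  expect_equal(per$tier[per$erv_id == "eA"], "all_three")
  expect_equal(per$tier[per$erv_id == "eB"], "two_of_three")
  expect_equal(per$tier[per$erv_id == "eC"], "fewer")
  # eC is a candidate via the polysome route despite tier 'fewer'
  expect_setequal(tu$candidates$erv_id, c("eA", "eB", "eC"))
  expect_true(tu$candidates$via_polysome[tu$candidates$erv_id == "eC"])
  expect_false(tu$candidates$via_tier[tu$candidates$erv_id == "eC"])
})

test_that("candidate union of two cell-line sets with overlap is non-redundant", {
  # constructed 57- and 31-id sets sharing 7 ids -> union of 81
  set_a <- sprintf("erv%03d", 1:57)
  set_b <- sprintf("erv%03d", c(51:57, 101:124))
  stopifnot(length(set_b) == 31, length(intersect(set_a, set_b)) == 7)
  cf <- rbind(
    data.frame(erv_id = rep(set_a, each = 3), cell_line = "786-O",
               comparison = rep(c("c1", "c2", "c3"), length(set_a)),
               responsive = TRUE),
    data.frame(erv_id = rep(set_b, each = 3), cell_line = "A-498",
               comparison = rep(c("c1", "c2", "c3"), length(set_b)),
               responsive = TRUE))
  tu <- tier_and_union(cf)
  expect_equal(nrow(tu$candidates), 81)
  expect_equal(anyDuplicated(tu$candidates$erv_id), 0L)
  both <- tu$candidates[tu$candidates$erv_id %in% intersect(set_a, set_b), ]
  expect_true(all(both$cell_lines == "786-O,A-498"))
})

test_that("planted abundances are recovered in rank and planted effects in tiers", {
  cfg <- sim_config(seed = 12, n_ervs = 30, n_families = 6,
                    base_abundance = 120, mismatch_rate = 0.05)
  cat <- make_erv_catalog(cfg)
  erv_len <- setNames(cat$ervs$length, cat$ervs$erv_id)
  ab <- planted_abundance(cat, cfg)

  # rank recovery on one high-depth sample, restricted to ERVs planted at
  # >= 50 fragments
  sim <- simulate_alignments(cat, ab$abundance[, "high"], cfg, seed = 77)
  q <- quantify_ervs(sim$alignments, erv_len)
  deep <- q$erv_id[ab$abundance[q$erv_id, "high"] >= 50]
  expect_gte(length(deep), 25)
  rho <- cor(q$expression_norm[match(deep, q$erv_id)],
             ab$abundance[deep, "high"], method = "spearman")
  expect_gte(rho, 0.9)

  # tiering sensitivity: 3 comparisons x 2 replicates/arm, 4-fold effects
  norm <- list()
  sidx <- 0
  # library_size is fixed across samples: real libraries are dominated by
  # host transcriptome reads, so sample depth does not scale with ERV output
  for (cmp in c("c1", "c2", "c3")) for (arm in c("high", "low")) for (r in 1:2) {
    sidx <- sidx + 1
    s <- simulate_alignments(cat, ab$abundance[, arm], cfg, seed = 500 + sidx)
    qq <- quantify_ervs(s$alignments, erv_len, library_size = 1e6)
    norm[[paste(cmp, arm, r, sep = "_")]] <- setNames(qq$expression_norm, qq$erv_id)
  }
  nm <- do.call(cbind, norm)
  cf <- do.call(rbind, lapply(c("c1", "c2", "c3"), function(cmp) {
    cc <- compare_conditions(nm, grep(paste0(cmp, "_high"), colnames(nm)),
                             grep(paste0(cmp, "_low"), colnames(nm)),
                             comparison = cmp)
    cc$cell_line <- "sim"
    cc
  }))
  tu <- tier_and_union(cf)
  per <- tu$per_cell_line
  planted <- ab$responsive
  reached <- per$erv_id[per$tier %in% c("all_three", "two_of_three")]
  expect_gte(mean(planted %in% reached), 0.9)
})
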