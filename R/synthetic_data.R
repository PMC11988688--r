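#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators. One
#' master `seed` governs all sub-generators through a documented
#' derivation, so each stage can be re-simulated independently and
#' identically.
#'
#' @param seed Master RNG seed (integer).
#' @param n_ervs,n_families Catalog size and number of homologous families
#'   (`n_ervs >= n_families >= 1`).
#' @param family_shared_fraction Fraction of each ERV occupied by the
#'   family's shared (homologous) block, in `[0, 1]`.
#' @param erv_length,spacer_length,read_length Geometry in bases.
#' @param base_abundance Expected fragments per ERV in the low-HIF2 arm.
#' @param effect_fold Planted fold-change of responsive ERVs in the
#'   high-HIF2 arm (default 4).
#' @param frac_responsive Fraction of ERVs planted as HIF2-responsive.
#' @param duplicate_rate,se_rate,mismatch_rate,txome_rate Per-fragment
#'   probabilities of PCR duplication, single-end conversion, a per-mate
#'   mismatch, and the relative volume of transcriptome-mapped background
#'   reads; all in `[0, 1]`.
#' @param n_target,n_decoy PSM mixture sizes.
#' @param fraction_correct Fraction of target PSMs that are correct.
#' @param score_high_mean,score_null_mean,score_sd Engine-score
#'   distributions: correct targets draw from
#'   `Normal(score_high_mean, score_sd)`, incorrect targets and decoys from
#'   `Normal(score_null_mean, score_sd)`. Purely for calibration testing,
#'   not a claim about real engines.
#' @param normal_peptide_rate Fraction of simulated peptides also assigned
#'   to a normal-tissue sample.
#' @param n_samples,planted_correlation,n_signature_genes,
#'   n_housekeeping_genes,n_matrix_ervs Expression-matrix generator: a
#'   latent HIF activity per sample on which signature genes and
#'   responsive ERVs load with the planted correlation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ervs = 40L, n_families = 8L,
                       family_shared_fraction = 0.3,
                       erv_length = 600L, spacer_length = 200L,
                       read_length = 100L,
                       base_abundance = 50, effect_fold = 4,
                       frac_responsive = 0.5,
                       duplicate_rate = 0.1, se_rate = 0.1,
                       mismatch_rate = 0.1, txome_rate = 0.2,
                       n_target = 10000L, n_decoy = 1000L,
                       fraction_correct = 0.9,
                       score_high_mean = 12, score_null_mean = 5,
                       score_sd = 2,
                       normal_peptide_rate = 0.1,
                       n_samples = 100L, planted_correlation = 0.8,
                       n_signature_genes = 10L, n_housekeeping_genes = 10L,
                       n_matrix_ervs = 15L) {
  cfg <- as.list(environment())
  rates <- c(family_shared_fraction, frac_responsive, duplicate_rate, se_rate,
             mismatch_rate, txome_rate, fraction_correct, normal_peptide_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (score_sd <= 0) stop("score_sd must be > 0")
  if (n_ervs < n_families || n_families < 1) {
    stop("need n_ervs >= n_families >= 1")
  }
  if (abs(planted_correlation) > 1) stop("planted_correlation must be in [-1, 1]")
  if (erv_length < 3 * read_length) stop("erv_length too small for read_length")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed", x$seed, "):",
      x$n_ervs, "ERVs in", x$n_families, "families;",
      x$n_target, "target /", x$n_decoy, "decoy PSMs;",
      x$n_samples, "expression samples\n")
  invisible(x)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a stop-free (in frame +1) random DNA block, so shared blocks translate to
# long shared ORFs
.random_orf_dna <- function(n_codons) {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

#' Generate a synthetic ERV catalog with homologous families
#'
#' Builds a genome, a stranded ERV BED catalog, and a family map in which
#' members of a family share an identical planted block (placed at the
#' same codon-aligned offset in every member, so translated peptides from
#' the block map to every family member). Deterministic under the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return List `genome` ([Biostrings::DNAStringSet]), `ervs` (catalog data
#'   frame), `families` (`erv_id, family`), `block` (per-family shared
#'   block coordinates within the ERV), and `config`.
#' @export
make_erv_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 1L))
  n <- config$n_ervs
  ids <- sprintf("erv%03d", seq_len(n))
  family <- sort(rep_len(seq_len(config$n_families), n))
  len <- as.integer(config$erv_length)
  shared_codons <- max(0L, as.integer(config$family_shared_fraction * len) %/% 3L)
  block_offset <- 3L * (((len - 3L * shared_codons) %/% 2L) %/% 3L)
  blocks <- vapply(seq_len(config$n_families), function(f) {
    if (shared_codons > 0) .random_orf_dna(shared_codons) else ""
  }, "")
  seqs <- character(n)
  for (i in seq_len(n)) {
    b <- blocks[family[i]]
    left <- .random_dna(block_offset)
    right <- .random_dna(len - block_offset - nchar(b))
    seqs[i] <- paste0(left, b, right)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  spacer <- config$spacer_length
  pieces <- character(2L * n + 1L)
  pieces[1] <- .random_dna(spacer)
  start <- integer(n); pos <- spacer
  for (i in seq_len(n)) {
    start[i] <- pos
    genomic <- if (strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[i])))
    } else seqs[i]
    pieces[2L * i] <- genomic
    pieces[2L * i + 1L] <- .random_dna(spacer)
    pos <- pos + len + spacer
  }
  genome <- Biostrings::DNAStringSet(c(chrS = paste(pieces, collapse = "")))
  ervs <- data.frame(erv_id = ids, chrom = "chrS", start = start,
                     end = start + len, strand = strand, length = len,
                     stringsAsFactors = FALSE)
  list(genome = genome, ervs = ervs,
       families = data.frame(erv_id = ids, family = family,
                             stringsAsFactors = FALSE),
       block = data.frame(family = seq_len(config$n_families),
                          offset = block_offset,
                          length = 3L * shared_codons),
       config = config)
}

#' Planted per-condition abundance table
#'
#' Expected fragments per ERV for a low- and a high-HIF2 condition: every
#' ERV gets a lognormal baseline around `base_abundance`; a planted subset
#' is multiplied by `effect_fold` in the high arm.
#'
#' @param catalog Output of [make_erv_catalog()].
#' @param config A [sim_config()].
#' @return List `abundance` (matrix ERVs x c("low","high")) and
#'   `responsive` (character vector of planted-responsive ERV ids).
#' @export
planted_abundance <- function(catalog, config = catalog$config) {
  set.seed(.derive_seed(config$seed, 2L))
  ids <- catalog$ervs$erv_id
  base <- config$base_abundance * exp(rnorm(length(ids), 0, 0.5))
  responsive <- sort(sample(ids, round(config$frac_responsive * length(ids))))
  high <- base * ifelse(ids %in% responsive, config$effect_fold, 1)
  ab <- cbind(low = base, high = high)
  rownames(ab) <- ids
  list(abundance = ab, responsive = responsive)
}

#' Simulate alignment evidence with planted abundances
#'
#' Draws fragments per ERV (Poisson around the planted abundance), assigns
#' per-mate mismatch counts, converts a fraction of fragments to the
#' single-end pathway (the lost mate appears as a transcriptome-mapped
#' record), injects PCR duplicates sharing the fragment key, multi-maps
#' fragments falling wholly inside the family's shared block to every
#' family member, and adds transcriptome-mapped background reads.
#'
#' @param catalog Output of [make_erv_catalog()].
#' @param abundance Named numeric vector of expected fragments per ERV for
#'   this sample.
#' @param config A [sim_config()].
#' @param seed RNG seed for this sample (default the config seed).
#' @return List `alignments` (evidence data frame, see
#'   [read_alignment_tsv()]) and `truth` (`per_erv`: planted non-duplicate
#'   fragment counts by pathway; `per_read`: read-level provenance).
#' @export
simulate_alignments <- function(catalog, abundance, config = catalog$config,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ids <- catalog$ervs$erv_id
  ab <- abundance[ids]
  if (any(is.na(ab)) || any(ab < 0)) {
    stop("abundance must be a named vector covering the catalog, values >= 0")
  }
  set.seed(.derive_seed(seed, 3L))
  len <- config$erv_length
  rl <- config$read_length
  fam_of <- setNames(catalog$families$family, catalog$families$erv_id)
  members_by_fam <- split(catalog$families$erv_id, catalog$families$family)
  b_off <- catalog$block$offset[1]
  b_len <- catalog$block$length[1]
  n_frag <- rpois(length(ids), ab)
  src <- rep(ids, n_frag)
  N <- length(src)
  empty_aln <- data.frame(read_id = character(), mate = character(),
                          txome_mapped = logical(), erv_id = character(),
                          nm = integer(), frag_pos = integer(),
                          orient = character(), stringsAsFactors = FALSE)
  if (N == 0L) {
    return(list(alignments = empty_aln,
                truth = list(per_erv = data.frame(erv_id = ids,
                                                  n_true_fragments = 0L),
                             per_read = data.frame(read_id = character(),
                                                   true_erv = character(),
                                                   kind = character(),
                                                   duplicate = logical()))))
  }
  frag_pos <- sample.int(len - 2L * rl + 1L, N, replace = TRUE) - 1L
  orient <- sample(c("+", "-"), N, replace = TRUE)
  nm1 <- rbinom(N, 1L, config$mismatch_rate)
  nm2 <- rbinom(N, 1L, config$mismatch_rate)
  as_se <- runif(N) < config$se_rate
  dup <- runif(N) < config$duplicate_rate
  in_block <- b_len > 0L & frag_pos >= b_off & (frag_pos + 2L * rl) <= (b_off + b_len)
  hit_list <- lapply(seq_len(N), function(i) {
    if (in_block[i]) members_by_fam[[as.character(fam_of[[src[i]]])]] else src[i]
  })
  kind <- ifelse(as_se,
                 ifelse(nm1 == 0L, "se", "se_rejected"),
                 ifelse(nm1 + nm2 == 0L, "pe_pm",
                        ifelse(nm1 + nm2 == 1L, "pe_1mm", "pe_rejected")))
  # evidence rows for a set of fragments under given read numbers; mate 2 of
  # a single-end fragment shows up as a transcriptome-mapped record
  rows_for <- function(fsel, numbers) {
    rid <- sprintf("r%07d", numbers)
    nh <- lengths(hit_list[fsel])
    rep_i <- rep(seq_along(fsel), nh)
    f <- fsel[rep_i]
    r1 <- data.table::data.table(
      read_id = rid[rep_i], mate = "1", txome_mapped = FALSE,
      erv_id = unlist(hit_list[fsel], use.names = FALSE),
      nm = nm1[f], frag_pos = frag_pos[f], orient = orient[f])
    pe_sel <- !as_se[f]
    r2 <- data.table::copy(r1[pe_sel])
    r2[, `:=`(mate = "2", nm = nm2[f[pe_sel]])]
    se_in <- as_se[fsel]
    r2t <- data.table::data.table(
      read_id = rid[se_in], mate = "2", txome_mapped = TRUE,
      erv_id = NA_character_, nm = 0L,
      frag_pos = frag_pos[fsel[se_in]], orient = orient[fsel[se_in]])
    data.table::rbindlist(list(r1, r2, r2t))
  }
  originals <- rows_for(seq_len(N), seq_len(N))
  truth <- list(data.frame(read_id = sprintf("r%07d", seq_len(N)),
                           true_erv = src, kind = kind, duplicate = FALSE,
                           stringsAsFactors = FALSE))
  counter <- N
  dsel <- which(dup)
  if (length(dsel)) {
    dnum <- counter + seq_along(dsel)
    counter <- counter + length(dsel)
    dup_rows <- rows_for(dsel, dnum)
    truth <- c(truth, list(data.frame(read_id = sprintf("r%07d", dnum),
                                      true_erv = src[dsel], kind = kind[dsel],
                                      duplicate = TRUE,
                                      stringsAsFactors = FALSE)))
  } else {
    dup_rows <- NULL
  }
  n_bg <- rpois(1L, config$txome_rate * N)
  if (n_bg > 0L) {
    bnum <- counter + seq_len(n_bg)
    brid <- sprintf("r%07d", bnum)
    bg_rows <- data.table::data.table(
      read_id = rep(brid, each = 2L), mate = rep(c("1", "2"), n_bg),
      txome_mapped = TRUE, erv_id = NA_character_, nm = 0L,
      frag_pos = 0L, orient = "+")
    truth <- c(truth, list(data.frame(read_id = brid, true_erv = NA_character_,
                                      kind = "txome", duplicate = FALSE,
                                      stringsAsFactors = FALSE)))
  } else {
    bg_rows <- NULL
  }
  aln <- as.data.frame(data.table::rbindlist(
    Filter(Negate(is.null), list(originals, dup_rows, bg_rows))))
  per_read <- do.call(rbind, truth)
  keep <- !per_read$duplicate & per_read$kind %in% c("pe_pm", "pe_1mm", "se")
  tab <- table(factor(per_read$true_erv[keep], levels = ids))
  per_erv <- data.frame(erv_id = ids, n_true_fragments = as.integer(tab),
                        stringsAsFactors = FALSE)
  list(alignments = aln, truth = list(per_erv = per_erv, per_read = per_read))
}

.PSM_ALPHABET <- c("A","C","D","E","F","G","H","K","L","M","N","P","Q","R",
                   "S","T","V","W","Y","I")

#' Simulate a PSM table with planted correctness
#'
#' Correct targets draw their engine score from the high Normal
#' distribution and pass the three rescoring checks with high probability;
#' incorrect targets and decoys draw from the null distribution and fail
#' most checks. A configurable fraction of peptides is also assigned to a
#' normal-tissue sample.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default the config seed).
#' @return List `psms` (data frame with engine metrics, rescoring metrics,
#'   run/sample ids, `is_decoy`, `tissue`, `source_class`) and `truth`
#'   (`psm_id, is_correct`).
#' @export
simulate_psm_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(seed, 4L))
  nt <- config$n_target; nd <- config$n_decoy
  n <- nt + nd
  is_decoy <- rep(c(FALSE, TRUE), c(nt, nd))
  correct <- c(runif(nt) < config$fraction_correct, rep(FALSE, nd))
  score <- ifelse(correct,
                  rnorm(n, config$score_high_mean, config$score_sd),
                  rnorm(n, config$score_null_mean, config$score_sd))
  pep_len <- sample(8:11, n, replace = TRUE)
  peptide <- vapply(pep_len, function(L) {
    paste(sample(.PSM_ALPHABET, L, replace = TRUE), collapse = "")
  }, "")
  sa <- ifelse(correct, pmin(1, pmax(0, rnorm(n, 0.85, 0.08))),
               pmin(1, pmax(0, rnorm(n, 0.35, 0.15))))
  drt <- ifelse(correct, rnorm(n, 0, 3), rnorm(n, 0, 15))
  rank <- ifelse(correct, abs(rnorm(n, 0, 0.7)), runif(n, 0, 8))
  rt_pred <- runif(n, 5, 95)
  psms <- data.frame(
    psm_id = sprintf("psm%06d", seq_len(n)),
    peptide = peptide,
    charge = sample(1:4, n, replace = TRUE, prob = c(0.1, 0.5, 0.3, 0.1)),
    sample_id = sample(sprintf("s%02d", 1:4), n, replace = TRUE),
    run_id = sample(sprintf("run%d", 1:4), n, replace = TRUE),
    sm_score = score,
    spi_pct = ifelse(correct, runif(n, 55, 95), runif(n, 20, 80)),
    bcs = ifelse(correct, runif(n, 5, 12), runif(n, 1, 8)),
    rt_pred_min = rt_pred,
    rt_obs_min = rt_pred + drt,
    sa_dp = sa,
    hla_rank = rank,
    is_decoy = is_decoy,
    tissue = "tumor",
    source_class = ifelse(runif(n) < 0.8, "reference", "erv"),
    stringsAsFactors = FALSE)
  normal_peps <- sample(unique(peptide),
                        round(config$normal_peptide_rate * length(unique(peptide))))
  psms$tissue[psms$peptide %in% normal_peps & runif(n) < 0.5] <- "normal"
  list(psms = psms,
       truth = data.frame(psm_id = psms$psm_id, is_correct = correct,
                          stringsAsFactors = FALSE))
}

#' Simulate an expression matrix with a planted HIF2 correlation
#'
#' A latent HIF activity per sample; signature genes and responsive ERVs
#' load on it with the planted correlation (on the log2 scale used by
#' [log_zscore()], the loading is exactly linear); housekeeping genes and
#' the remaining ERVs are independent noise.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default the config seed).
#' @return List `mat` (features x samples, non-negative), `truth`
#'   (`latent`, `responsive_ervs`, `signature_genes`,
#'   `housekeeping_genes`, `rho`).
#' @export
simulate_expression_matrix <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 3) stop("need n_samples >= 3")
  set.seed(.derive_seed(seed, 5L))
  ns <- config$n_samples
  rho <- config$planted_correlation
  h <- rnorm(ns)
  load_on <- function(n_feat, corr) {
    t(vapply(seq_len(n_feat), function(i) {
      z <- corr * h + sqrt(1 - corr^2) * rnorm(ns)
      # strictly positive; log2(x + 1) is close to linear in z over the
      # bulk of the distribution, so the planted correlation survives the
      # log/z-score transform nearly unattenuated
      2^(5 + 2 * z)
    }, numeric(ns)))
  }
  sig_genes <- sprintf("HIF2SIG_%02d", seq_len(config$n_signature_genes))
  hk_genes <- sprintf("HK_%02d", seq_len(config$n_housekeeping_genes))
  n_erv <- config$n_matrix_ervs
  n_resp <- max(1L, n_erv %/% 2L)
  erv_ids <- sprintf("erv%03d", seq_len(n_erv))
  responsive <- erv_ids[seq_len(n_resp)]
  mat <- rbind(load_on(length(sig_genes), rho),
               load_on(length(hk_genes), 0),
               load_on(n_resp, rho),
               load_on(n_erv - n_resp, 0))
  rownames(mat) <- c(sig_genes, hk_genes, erv_ids)
  colnames(mat) <- sprintf("sample%03d", seq_len(ns))
  list(mat = mat,
       truth = list(latent = h, responsive_ervs = responsive,
                    signature_genes = sig_genes, housekeeping_genes = hk_genes,
                    rho = rho))
}

#' Simulate HIF2 ChIP peaks around a synthetic catalog
#'
#' Plants, per ERV, either a superimposed peak, a peak at a controlled gap
#' (within the 1, 5 or 10 kb window), or no peak, so the proximity
#' annotation has known truth. The planted truth is exact only when
#' neighboring ERVs are farther apart than the largest window (build the
#' catalog with `spacer_length` > 10000 when asserting against it);
#' with tight packing a peak planted for one ERV can also sit near its
#' neighbor.
#'
#' @param catalog Output of [make_erv_catalog()].
#' @param seed RNG seed.
#' @return List `peaks` (peak data frame) and `truth` (`erv_id, relation,
#'   window_kb`).
#' @export
simulate_peaks <- function(catalog, seed = catalog$config$seed) {
  set.seed(.derive_seed(seed, 6L))
  ervs <- catalog$ervs
  cls <- sample(c("superimposed", "1", "5", "10", "none"), nrow(ervs),
                replace = TRUE, prob = c(0.2, 0.15, 0.15, 0.15, 0.35))
  peaks <- list(); truth <- list()
  # gap ranges placing the peak in exactly one window tier (gap in bases;
  # extended peak overlaps iff gap < w * 1000)
  gap_lower <- c(`1` = 1L, `5` = 1000L, `10` = 5000L)
  for (i in seq_len(nrow(ervs))) {
    if (cls[i] == "none") {
      truth[[i]] <- data.frame(erv_id = ervs$erv_id[i], relation = "none",
                               window_kb = NA_real_, stringsAsFactors = FALSE)
      next
    }
    if (cls[i] == "superimposed") {
      s <- ervs$start[i] + 10L
      e <- min(ervs$end[i] - 10L, s + 200L)
      w <- 0
    } else {
      w <- as.numeric(cls[i])
      lower <- gap_lower[[cls[i]]]
      gap <- sample(seq(lower, w * 1000L - 1L), 1L)
      s <- ervs$end[i] + gap
      e <- s + 200L
    }
    peaks[[length(peaks) + 1L]] <- data.frame(
      peak_id = sprintf("peak%03d", i), chrom = ervs$chrom[i],
      start = s, end = e, score = round(runif(1, 10, 100), 1),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      erv_id = ervs$erv_id[i],
      relation = if (w == 0) "superimposed" else "within_window",
      window_kb = w, stringsAsFactors = FALSE)
  }
  list(peaks = if (length(peaks)) do.call(rbind, peaks) else
         data.frame(peak_id = character(), chrom = character(),
                    start = integer(), end = integer(), score = numeric(),
                    stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}
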