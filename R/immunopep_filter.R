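#' Monoisotopic residue masses of the 20 standard amino acids
#'
#' Named numeric vector of in-chain (residue) monoisotopic masses in
#' daltons, computed from standard atomic masses.
#'
#' @export
AA_RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.MASS_WATER <- 18.010565

#' Target-decoy FDR estimation and score cutoff
#'
#' `FDR(s) = #decoys(score >= s) / max(1, #targets(score >= s))`; the
#' cutoff is the smallest score at which the estimate is at or below
#' `level`, and each PSM's q-value is the minimum FDR over all thresholds
#' that would accept it (so q-values are non-increasing in score). With
#' `scope = "run"`, estimation is applied within each `run_id` first and an
#' aggregate check is then applied on top, mirroring a dual per-run /
#' aggregate requirement.
#'
#' @param psms Data frame with `sm_score` and logical `is_decoy`; `run_id`
#'   required when `scope = "run"`.
#' @param level FDR level (default 0.01).
#' @param scope `"aggregate"` (default) or `"run"`.
#' @return List `cutoff` (aggregate score cutoff; per-run cutoffs in
#'   `run_cutoffs` when scoped), `qvalue` (per input row) and `accept`
#'   (logical per input row; decoy rows get accept = FALSE).
#' @export
estimate_fdr_threshold <- function(psms, level = 0.01,
                                   scope = c("aggregate", "run")) {
  scope <- match.arg(scope)
  stopifnot(all(c("sm_score", "is_decoy") %in% names(psms)))
  if (!any(!psms$is_decoy)) stop("no target PSMs supplied")
  if (!any(psms$is_decoy)) {
    warning("no decoy PSMs: FDR estimate is 0, all targets accepted")
    return(list(cutoff = min(psms$sm_score[!psms$is_decoy]),
                qvalue = rep(0, nrow(psms)),
                accept = !psms$is_decoy))
  }
  agg <- .td_qvalues(psms$sm_score, psms$is_decoy)
  accept <- agg$qvalue <= level
  cutoff <- if (any(accept)) min(psms$sm_score[accept]) else Inf
  run_cutoffs <- NULL
  if (scope == "run") {
    stopifnot("run_id" %in% names(psms))
    accept_run <- logical(nrow(psms))
    run_cutoffs <- list()
    for (r in unique(psms$run_id)) {
      ix <- which(psms$run_id == r)
      if (!any(psms$is_decoy[ix])) {
        accept_run[ix] <- TRUE
        run_cutoffs[[as.character(r)]] <-
          if (any(!psms$is_decoy[ix])) min(psms$sm_score[ix][!psms$is_decoy[ix]]) else Inf
        next
      }
      qr <- .td_qvalues(psms$sm_score[ix], psms$is_decoy[ix])$qvalue
      accept_run[ix] <- qr <= level
      run_cutoffs[[as.character(r)]] <-
        if (any(qr <= level)) min(psms$sm_score[ix][qr <= level]) else Inf
    }
    accept <- accept & accept_run
  }
  list(cutoff = cutoff, qvalue = agg$qvalue,
       accept = accept & !psms$is_decoy, run_cutoffs = run_cutoffs)
}

# internal: q-values for a score/decoy vector; ties share the most
# permissive count
.td_qvalues <- function(score, is_decoy) {
  ord <- order(score, decreasing = TRUE)
  n_dec <- cumsum(is_decoy[ord])
  n_tar <- cumsum(!is_decoy[ord])
  fdr <- n_dec / pmax(1L, n_tar)
  s_sorted <- score[ord]
  # at threshold s, all PSMs with score >= s are counted: every member of a
  # tie group takes the group's last (most inclusive) cumulative counts
  idx <- seq_along(fdr)
  grp_last <- stats::ave(idx, s_sorted, FUN = max)
  fdr_thr <- fdr[grp_last]
  q_sorted <- rev(cummin(rev(fdr_thr)))
  q <- numeric(length(score))
  q[ord] <- q_sorted
  list(qvalue = q)
}

#' Fixed subset-specific score thresholds
#'
#' Keeps PSMs meeting all fixed thresholds: engine score >= 7, scored peak
#' intensity >= 50 percent, backbone cleavage score >= 5, precursor charge
#' 1-4 and peptide length 8-11 residues. All "minimum" thresholds and both
#' ranges are inclusive.
#'
#' @param psms Data frame with `sm_score, spi_pct, bcs, charge, peptide`.
#' @param min_score,min_spi,min_bcs Fixed minimums (defaults 7, 50, 5).
#' @param charge_range,length_range Inclusive ranges (defaults 1-4, 8-11).
#' @return The surviving rows of `psms`.
#' @export
apply_fixed_thresholds <- function(psms, min_score = 7, min_spi = 50,
                                   min_bcs = 5, charge_range = c(1, 4),
                                   length_range = c(8, 11)) {
  len <- nchar(psms$peptide)
  keep <- psms$sm_score >= min_score & psms$spi_pct >= min_spi &
    psms$bcs >= min_bcs &
    psms$charge >= charge_range[1] & psms$charge <= charge_range[2] &
    len >= length_range[1] & len <= length_range[2]
  psms[keep, , drop = FALSE]
}

#' Spectral angle between observed and predicted fragment intensities
#'
#' Normalized spectral-contrast angle on L2-normalized, non-negative b/y
#' ion intensity vectors aligned on the union of ion labels (a label
#' missing from one spectrum contributes zero):
#' `SA = 1 - (2/pi) * arccos(<a, b> / (|a| |b|))`, clipped to `[0, 1]`.
#' Identical spectra give 1, orthogonal (disjoint ion sets) give 0. If
#' either vector is all-zero the angle is defined as 0.
#'
#' @param by_obs,by_pred Named non-negative numeric vectors keyed by ion
#'   label (e.g. `"y3^1"`).
#' @return Spectral angle in `[0, 1]`.
#' @export
spectral_angle <- function(by_obs, by_pred) {
  if (any(by_obs < 0) || any(by_pred < 0)) stop("negative fragment intensity")
  labels <- union(names(by_obs), names(by_pred))
  if (is.null(labels) && (length(by_obs) == length(by_pred))) {
    a <- as.numeric(by_obs); b <- as.numeric(by_pred)
  } else {
    a <- setNames(numeric(length(labels)), labels)
    b <- a
    a[names(by_obs)] <- by_obs
    b[names(by_pred)] <- by_pred
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  cs <- min(1, max(-1, sum(a * b) / (na * nb)))
  min(1, max(0, 1 - 2 * acos(cs) / pi))
}

#' Select the retention-time calibration subset
#'
#' Divides the observed retention-time range of all PSMs into
#' `n_segments` equal-width bins and keeps, within each bin, the `top_k`
#' reference-proteome-derived PSMs by engine score (all of them when a bin
#' has fewer). This subset calibrates the RT predictor.
#'
#' @param psms Data frame with `rt_obs_min`, `sm_score`, `source_class`.
#' @param n_segments Number of RT segments (default 50).
#' @param top_k PSMs retained per segment (default 15).
#' @return The calibration rows of `psms` (reference class only).
#' @export
select_rt_calibration <- function(psms, n_segments = 50, top_k = 15) {
  if (!nrow(psms)) return(psms)
  rng <- range(psms$rt_obs_min)
  ref <- psms[psms$source_class == "reference", , drop = FALSE]
  if (!nrow(ref)) return(ref)
  if (rng[1] == rng[2]) {
    bin <- rep(1L, nrow(ref))
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_segments + 1L)
    bin <- findInterval(ref$rt_obs_min, edges, rightmost.closed = TRUE)
    bin <- pmin(pmax(bin, 1L), n_segments)
  }
  keep <- unlist(lapply(split(seq_len(nrow(ref)), bin), function(ix) {
    ix[order(ref$sm_score[ix], decreasing = TRUE)][seq_len(min(top_k, length(ix)))]
  }), use.names = FALSE)
  ref[sort(keep), , drop = FALSE]
}

#' HLA binder category from percentile rank
#'
#' `strong` below 0.5, `weak` from 0.5 to 2 (inclusive), `non` above 2.
#'
#' @param hla_rank Non-negative percentile rank(s) for the best allele.
#' @return Character vector in `{strong, weak, non}`.
#' @export
binder_category <- function(hla_rank) {
  if (any(hla_rank < 0)) stop("hla_rank must be >= 0")
  ifelse(hla_rank < 0.5, "strong", ifelse(hla_rank <= 2, "weak", "non"))
}

#' Three-metric strike classification of PSMs
#'
#' Each PSM earns a strike per failed check: predicted-vs-observed spectral
#' angle (pass strictly above 0.6), retention-time deviation (pass within
#' +/- 10 min inclusive), and HLA percentile rank (pass strictly below
#' 2.0). Verdict: 0 strikes = pass, 1 = maybe, 2 or 3 = fail. Note the
#' deliberate boundary asymmetry with [binder_category()]: a rank of
#' exactly 2.0 is still a weak binder by the printed category brackets but
#' earns a strike under the strict "< 2.0" pass condition.
#'
#' @param sa_dp Spectral angle(s) in `[0, 1]`.
#' @param delta_rt_min Signed observed-minus-predicted RT deviation(s), min.
#' @param hla_rank Percentile rank(s).
#' @param sa_min,rt_tol_min,rank_max The three pass thresholds
#'   (defaults 0.6, 10, 2.0).
#' @return Data frame `sa_dp, delta_rt_min, hla_rank, binder_category,
#'   strike_spectrum, strike_rt, strike_binding, strikes, verdict`.
#' @export
strike_classify <- function(sa_dp, delta_rt_min, hla_rank, sa_min = 0.6,
                            rt_tol_min = 10, rank_max = 2.0) {
  stopifnot(all(is.finite(sa_dp)), all(is.finite(delta_rt_min)),
            all(is.finite(hla_rank)))
  s_sp <- !(sa_dp > sa_min)
  s_rt <- abs(delta_rt_min) > rt_tol_min
  s_bd <- !(hla_rank < rank_max)
  strikes <- s_sp + s_rt + s_bd
  data.frame(sa_dp = sa_dp, delta_rt_min = delta_rt_min, hla_rank = hla_rank,
             binder_category = binder_category(hla_rank),
             strike_spectrum = s_sp, strike_rt = s_rt, strike_binding = s_bd,
             strikes = strikes,
             verdict = ifelse(strikes == 0, "pass",
                              ifelse(strikes == 1, "maybe", "fail")),
             stringsAsFactors = FALSE)
}

#' Sequence-tag length of an MS/MS peak list
#'
#' Longest chain of peaks successively separated by in-chain residue
#' masses (within `tol` Da), reported as an edge count: three peaks
#' separated by two consecutive residue masses give tag length 2. A
#' spectrum passes the quality filter when the tag length exceeds 1.
#'
#' @param peaks Numeric m/z values.
#' @param residue_masses Named residue mass table
#'   (default [AA_RESIDUE_MASSES]).
#' @param tol Mass tolerance in Da (> 0).
#' @return Integer tag length (0 for fewer than two linkable peaks).
#' @export
sequence_tag_length <- function(peaks, residue_masses = AA_RESIDUE_MASSES,
                                tol = 0.01) {
  .assert_scalar_number(tol, "tol", min = .Machine$double.eps)
  peaks <- sort(unique(as.numeric(peaks)))
  n <- length(peaks)
  if (n < 2L) return(0L)
  masses <- unique(as.numeric(residue_masses))
  best <- integer(n)  # longest residue-linked path ending at peak i
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      gap <- peaks[i] - peaks[j]
      if (any(abs(gap - masses) <= tol) && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
      }
    }
  }
  max(best)
}

#' Peptide monoisotopic mass and heavy-label shifts
#'
#' `peptide_monoisotopic_mass()` sums residue masses plus one water;
#' `label_shift()` returns the mass increment of a stable-isotope label.
#' The lys8 label (six 13C, two 15N) shifts a peptide by 8.0142 Da,
#' conventionally printed as "8 Da".
#'
#' @param peptide Peptide over the 20 standard residues.
#' @param modifications Additional mass to add in Da (default 0).
#' @return Mass in daltons.
#' @export
peptide_monoisotopic_mass <- function(peptide, modifications = 0) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    stop("peptide must be a non-empty string")
  }
  res <- strsplit(toupper(peptide), "")[[1]]
  unknown <- setdiff(res, names(AA_RESIDUE_MASSES))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  }
  sum(AA_RESIDUE_MASSES[res]) + .MASS_WATER + modifications
}

#' @rdname peptide_monoisotopic_mass
#' @param label Label name; currently `"lys8"` (K +13C6, +15N2).
#' @export
label_shift <- function(label = c("lys8")) {
  label <- match.arg(label)
  # isotope masses: 12C = 12 exactly, 13C = 13.00335484, 14N = 14.00307401,
  # 15N = 15.00010890
  6 * (13.00335484 - 12) + 2 * (15.00010890 - 14.00307401)
}

#' Final ERV peptide call set with stage audit
#'
#' Applies the terminal peptide-level filter chain, recording surviving
#' call counts after each stage: (1) drop peptides that also map to the
#' reference proteome (I/L-aware); (2) drop peptides observed in any
#' normal-tissue sample; (3) collapse exact duplicate calls to one;
#' (4) drop cysteine-containing peptides (validation of such peptides is
#' technically fraught); (5) drop peptides whose best PSM verdict is
#' `fail` (at least two strikes). Surviving peptides carry all their
#' possible source ERVs.
#'
#' @param psms Data frame with `psm_id` and `peptide` (tumor PSMs surviving
#'   FDR and fixed thresholds).
#' @param source_maps Named list of [map_peptide_sources()] results keyed by
#'   peptide sequence.
#' @param strikes Data frame with `psm_id` and `strikes` (e.g.
#'   [strike_classify()] output bound to psm ids).
#' @param normal_peptides Character vector of peptides seen in normal
#'   tissue.
#' @return List `calls` (peptide, source_ervs, strikes, verdict, n_psms)
#'   and `audit` (stage, n_calls), counts non-increasing along stages.
#' @export
finalize_peptide_calls <- function(psms, source_maps, strikes,
                                   normal_peptides = character()) {
  missing_strike <- setdiff(psms$psm_id, strikes$psm_id)
  if (length(missing_strike)) {
    stop("missing strike verdict for psm(s): ",
         paste(head(missing_strike, 5), collapse = ", "))
  }
  missing_map <- setdiff(unique(psms$peptide), names(source_maps))
  if (length(missing_map)) {
    stop("missing source map for peptide(s): ",
         paste(head(missing_map, 5), collapse = ", "))
  }
  audit <- list(c(stage = "input", n = nrow(psms)))
  cur <- psms
  # stage 1: reference-proteome collisions (I/L aware via the source maps)
  hits_ref <- vapply(cur$peptide, function(p) {
    any(source_maps[[p]]$matches$source_class == "reference")
  }, TRUE)
  cur <- cur[!hits_ref, , drop = FALSE]
  audit <- c(audit, list(c(stage = "drop_reference_collisions", n = nrow(cur))))
  # stage 2: normal-tissue exclusion
  cur <- cur[!(cur$peptide %in% normal_peptides), , drop = FALSE]
  audit <- c(audit, list(c(stage = "drop_normal_tissue", n = nrow(cur))))
  # stage 3: collapse exact duplicate calls
  n_psms_by_pep <- table(cur$peptide)
  cur <- cur[!duplicated(cur$peptide), , drop = FALSE]
  audit <- c(audit, list(c(stage = "collapse_duplicates", n = nrow(cur))))
  # stage 4: cysteine removal
  cur <- cur[!grepl("C", cur$peptide, fixed = TRUE), , drop = FALSE]
  audit <- c(audit, list(c(stage = "drop_cysteine", n = nrow(cur))))
  # stage 5: strike verdicts; a peptide's verdict is its best (fewest
  # strikes) PSM
  strike_by_psm <- setNames(strikes$strikes, strikes$psm_id)
  pep_strikes <- vapply(cur$peptide, function(p) {
    ids <- psms$psm_id[psms$peptide == p]
    min(strike_by_psm[as.character(ids)])
  }, 0)
  cur <- cur[pep_strikes < 2, , drop = FALSE]
  pep_strikes <- pep_strikes[pep_strikes < 2]
  audit <- c(audit, list(c(stage = "drop_two_strike_failures", n = nrow(cur))))
  calls <- data.frame(
    peptide = cur$peptide,
    source_ervs = vapply(cur$peptide, function(p) {
      m <- source_maps[[p]]$matches
      # duplicate-collapsed entries carry all contributing accessions in
      # 'sources'; expand so every homologous ERV is listed
      erv_acc <- unlist(strsplit(
        if ("sources" %in% names(m)) m$sources[m$source_class == "erv"]
        else m$accession[m$source_class == "erv"], ";", fixed = TRUE))
      if (!length(erv_acc)) return("")
      ids <- unique(vapply(strsplit(erv_acc, "|", fixed = TRUE), function(x) {
        if (length(x) >= 2) x[2] else x[1]
      }, ""))
      paste(sort(ids), collapse = ";")
    }, ""),
    strikes = as.integer(pep_strikes),
    verdict = ifelse(pep_strikes == 0, "pass", "maybe"),
    n_psms = as.integer(n_psms_by_pep[cur$peptide]),
    stringsAsFactors = FALSE, row.names = NULL)
  audit_df <- data.frame(
    stage = vapply(audit, `[[`, "", "stage"),
    n_calls = as.integer(vapply(audit, `[[`, "", "n")),
    stringsAsFactors = FALSE)
  list(calls = calls, audit = audit_df)
}
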