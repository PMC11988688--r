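#' @import data.table
NULL

.datatable.aware <- TRUE

#' Read the simplified alignment evidence TSV
#'
#' One row per (read, candidate ERV hit). Columns: `read_id`, `mate`
#' (`1`, `2` or `single`), `txome_mapped` (0/1: the read aligned to the
#' human transcriptome), `erv_id` (`.` when the read hit no ERV), `nm`
#' (mismatch count of that hit), `frag_pos` (leftmost fragment coordinate
#' on the ERV), `orient` (`+`/`-`).
#'
#' @param path TSV path with the header above.
#' @return Data frame of alignment evidence.
#' @export
read_alignment_tsv <- function(path) {
  if (!file.exists(path)) stop("alignment TSV not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "mate", "txome_mapped", "erv_id", "nm", "frag_pos", "orient")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("alignment TSV missing column(s): ", paste(miss, collapse = ", "))
  x$mate <- as.character(x$mate)
  x$txome_mapped <- as.logical(x$txome_mapped)
  x$erv_id[x$erv_id %in% c(".", "*", "")] <- NA_character_
  x
}

#' Partition reads into transcriptome-mapped and ERV-candidate sets
#'
#' Reads that aligned to the human transcriptome are excluded from all ERV
#' counting; only transcriptome-unmapped reads proceed to pair
#' classification, which also enforces the "no transcriptome match"
#' criterion for retained single ends.
#'
#' @param aln Alignment evidence data frame (see [read_alignment_tsv()]).
#' @return List with `transcriptome` and `erv_candidates` data frames; every
#'   input row lands in exactly one.
#' @export
partition_reads <- function(aln) {
  mapped <- as.logical(aln$txome_mapped)
  list(transcriptome = aln[mapped, , drop = FALSE],
       erv_candidates = aln[!mapped, , drop = FALSE])
}

#' Classify one read pair against the ERV reference
#'
#' A pair is `PM` when some single ERV is hit by both mates with zero
#' mismatches each; `MM1` when some common ERV accumulates at most one
#' mismatch summed across both mates (and the pair is not PM); otherwise
#' `none`. "At most one mismatch across both reads" is read as a
#' fragment-level budget against a shared reference; mates hitting only
#' different ERVs never form a retained pair.
#'
#' @param r1,r2 Data frames of ERV hits for mate 1 and mate 2, each with
#'   columns `erv_id` and `nm`.
#' @return List `category` (`"PM"`, `"MM1"` or `"none"`) and `erv_ids`
#'   (sorted ids achieving that category; empty for `none`).
#' @export
classify_pair <- function(r1, r2) {
  h1 <- r1[!is.na(r1$erv_id), c("erv_id", "nm"), drop = FALSE]
  h2 <- r2[!is.na(r2$erv_id), c("erv_id", "nm"), drop = FALSE]
  common <- merge(h1, h2, by = "erv_id", suffixes = c("_1", "_2"))
  if (nrow(common)) {
    pm <- common$erv_id[common$nm_1 == 0 & common$nm_2 == 0]
    if (length(pm)) return(list(category = "PM", erv_ids = sort(unique(pm))))
    mm <- common$erv_id[common$nm_1 + common$nm_2 <= 1]
    if (length(mm)) return(list(category = "MM1", erv_ids = sort(unique(mm))))
  }
  list(category = "none", erv_ids = character())
}

#' Single-end retention rule
#'
#' A single read is retained iff (i) it has a perfect (0-mismatch) match to
#' an ERV, (ii) its fragment was not already classified as a paired-end PM
#' or 1MM match, and (iii) it has no transcriptome match.
#'
#' @param read Data frame of ERV hits for the read (`erv_id`, `nm`), plus a
#'   `txome_mapped` column or attribute-free logical via `txome_mapped`.
#' @param pair_in_pe Logical: the read's fragment is part of a retained
#'   paired-end PM/1MM match.
#' @param txome_mapped Logical: the read matched the transcriptome.
#' @return List `retained` (flag) and `erv_ids` (perfect-hit ERVs, empty
#'   when not retained).
#' @export
retain_single_end <- function(read, pair_in_pe = FALSE, txome_mapped = FALSE) {
  perfect <- read$erv_id[!is.na(read$erv_id) & read$nm == 0]
  ok <- length(perfect) > 0L && !isTRUE(pair_in_pe) && !isTRUE(txome_mapped)
  list(retained = ok, erv_ids = if (ok) sort(unique(perfect)) else character())
}

#' Remove duplicate fragments
#'
#' At most one paired-end (resp. single-end) record is retained per
#' fragment key `(erv_id, leftmost position, orientation)`; the first
#' record in input order wins. Idempotent.
#'
#' @param evidence Data frame with columns `erv_id, kind, frag_pos, orient`
#'   where `kind` is `pe_pm`, `pe_1mm` or `se`.
#' @return The deduplicated evidence data frame.
#' @export
deduplicate_fragments <- function(evidence) {
  type <- ifelse(evidence$kind == "se", "se", "pe")
  key <- paste(evidence$erv_id, evidence$frag_pos, evidence$orient, type,
               sep = "\r")
  evidence[!duplicated(key), , drop = FALSE]
}

#' Per-ERV raw expression from retained evidence
#'
#' Raw expression is `2 x (paired-end PM + 1MM fragments) + single-end
#' matches`: each retained pair contributes two reads of evidence, each
#' retained single end one.
#'
#' @param evidence Deduplicated evidence data frame (`erv_id`, `kind`).
#' @param erv_ids Optional ERV universe; ids without evidence get zero rows.
#' @return Data frame `erv_id, n_pe_pm, n_pe_1mm, n_se, expression_raw`.
#' @export
compute_erv_expression <- function(evidence, erv_ids = NULL) {
  dt <- data.table::as.data.table(evidence)
  if (nrow(dt)) {
    counts <- dt[, .(n_pe_pm = sum(kind == "pe_pm"),
                     n_pe_1mm = sum(kind == "pe_1mm"),
                     n_se = sum(kind == "se")), by = erv_id]
  } else {
    counts <- data.table::data.table(erv_id = character(), n_pe_pm = integer(),
                                     n_pe_1mm = integer(), n_se = integer())
  }
  if (!is.null(erv_ids)) {
    base <- data.table::data.table(erv_id = erv_ids)
    counts <- merge(base, counts, by = "erv_id", all.x = TRUE, sort = FALSE)
    for (cl in c("n_pe_pm", "n_pe_1mm", "n_se")) {
      data.table::set(counts, which(is.na(counts[[cl]])), cl, 0L)
    }
  }
  counts[, expression_raw := 2L * (n_pe_pm + n_pe_1mm) + n_se]
  as.data.frame(counts)
}

#' Library-size and length normalization
#'
#' Reads-per-kilobase-per-million convention:
#' `raw / (library_size / 1e6) / (erv_length / 1e3)`.
#'
#' @param raw Raw expression value(s).
#' @param library_size Total reads in the sample (> 0).
#' @param erv_length ERV length(s) in bases (> 0).
#' @return Normalized expression, vectorized over `raw`/`erv_length`.
#' @export
normalize_expression <- function(raw, library_size, erv_length) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(erv_length <= 0)) stop("erv_length must be > 0")
  raw / (library_size / 1e6) / (erv_length / 1e3)
}

#' Quantify ERV expression for one sample
#'
#' Full per-sample flow: exclude transcriptome-mapped reads, classify read
#' pairs (PM / 1MM against a common ERV), apply the single-end retention
#' rule, remove duplicate fragments, count, and normalize. A fragment
#' matching several ERVs at its achieved category is counted toward every
#' such ERV by default (`multimap = "all"`); `multimap = "first"` keeps the
#' first hit only.
#'
#' @param aln Alignment evidence data frame.
#' @param erv_lengths Named numeric vector `erv_id` -> length in bases.
#' @param library_size Total reads in the sample; defaults to the number of
#'   distinct (read_id, mate) records in `aln`.
#' @param multimap `"all"` (default) or `"first"`.
#' @return Data frame `erv_id, n_pe_pm, n_pe_1mm, n_se, expression_raw,
#'   expression_norm, library_size, erv_length`, one row per catalog ERV.
#' @export
quantify_ervs <- function(aln, erv_lengths, library_size = NULL,
                          multimap = c("all", "first")) {
  multimap <- match.arg(multimap)
  if (is.null(names(erv_lengths))) stop("erv_lengths must be named by erv_id")
  if (is.null(library_size)) {
    library_size <- nrow(unique(aln[c("read_id", "mate")]))
  }
  cand <- partition_reads(aln)$erv_candidates
  dt <- data.table::as.data.table(cand)
  hits <- dt[!is.na(erv_id)]
  ev_pe <- data.table::data.table(read_id = character(), erv_id = character(),
                                  kind = character(), frag_pos = integer(),
                                  orient = character())
  if (nrow(hits)) {
    m1 <- hits[mate == "1"]; m2 <- hits[mate == "2"]
    common <- merge(m1, m2, by = c("read_id", "erv_id"),
                    suffixes = c("_1", "_2"), allow.cartesian = TRUE)
    if (nrow(common)) {
      common[, pm := nm_1 == 0 & nm_2 == 0]
      common[, mm1 := nm_1 + nm_2 <= 1]
      common[, category := if (any(pm)) "PM" else if (any(mm1)) "MM1" else "none",
             by = read_id]
      pe <- common[(category == "PM" & pm) | (category == "MM1" & mm1)]
      if (nrow(pe)) {
        pe[, `:=`(kind = ifelse(category == "PM", "pe_pm", "pe_1mm"),
                  frag_pos = pmin(frag_pos_1, frag_pos_2),
                  orient = orient_1)]
        if (multimap == "first") pe <- pe[, .SD[1], by = read_id]
        ev_pe <- pe[, .(read_id, erv_id, kind, frag_pos, orient)]
      }
    }
  }
  pe_frags <- unique(ev_pe$read_id)
  se <- hits[nm == 0 & !(read_id %in% pe_frags)]
  if (nrow(se)) {
    se <- se[, .(read_id, erv_id, kind = "se", frag_pos, orient)]
    if (multimap == "first") se <- se[, .SD[1], by = read_id]
  } else {
    se <- ev_pe[0]
  }
  evidence <- rbind(ev_pe, se)
  evidence <- deduplicate_fragments(as.data.frame(evidence))
  counts <- compute_erv_expression(evidence, erv_ids = names(erv_lengths))
  counts$erv_length <- unname(erv_lengths[counts$erv_id])
  counts$library_size <- library_size
  counts$expression_norm <- normalize_expression(counts$expression_raw,
                                                 library_size, counts$erv_length)
  counts
}

#' Call HIF2 responsiveness for one ERV in one pairwise comparison
#'
#' The per-comparison criterion: fold change on pseudocounted arm means,
#' `log2fc = log2((mean_high + c) / (mean_low + c))`, with responsiveness
#' requiring `log2fc >= log2fc_min` and `mean_high >= min_expr`. The floor
#' guards against calling near-zero ERVs responsive on ratio alone.
#'
#' @param high,low Numeric vectors of normalized expression replicates for
#'   the high-HIF2 and low-HIF2 arms (>= 1 replicate each).
#' @param pseudocount Pseudocount `c` (default 1).
#' @param log2fc_min Fold-change threshold in log2 (default 1, i.e. 2-fold).
#' @param min_expr Minimum high-arm mean normalized expression (default 1).
#' @return List `log2fc, responsive, mean_high, mean_low`.
#' @export
call_responsive <- function(high, low, pseudocount = 1, log2fc_min = 1,
                            min_expr = 1) {
  if (!length(high) || !length(low)) stop("both arms need >= 1 replicate")
  mh <- mean(high); ml <- mean(low)
  lfc <- log2((mh + pseudocount) / (ml + pseudocount))
  list(log2fc = lfc,
       responsive = lfc >= log2fc_min && mh >= min_expr,
       mean_high = mh, mean_low = ml)
}

#' Responsiveness calls for a whole expression matrix
#'
#' Applies [call_responsive()] row-wise to a normalized expression matrix.
#'
#' @param norm_mat Matrix ERVs x samples of normalized expression, rownames
#'   = erv_id.
#' @param high_cols,low_cols Column names/indices of the two arms.
#' @param comparison Label recorded in the output.
#' @inheritParams call_responsive
#' @return Data frame `erv_id, comparison, log2fc, responsive`.
#' @export
compare_conditions <- function(norm_mat, high_cols, low_cols,
                               comparison = "high_vs_low", pseudocount = 1,
                               log2fc_min = 1, min_expr = 1) {
  res <- lapply(rownames(norm_mat), function(id) {
    cr <- call_responsive(norm_mat[id, high_cols], norm_mat[id, low_cols],
                          pseudocount, log2fc_min, min_expr)
    data.frame(erv_id = id, comparison = comparison, log2fc = cr$log2fc,
               responsive = cr$responsive, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Tier ERVs per cell line and form the non-redundant candidate union
#'
#' Tiers each ERV by how many of the pairwise high-vs-low comparisons it
#' scored in (`all_three` / `two_of_three` / `fewer`) per cell line; an ERV
#' is a candidate when it reaches at least two of three comparisons or is
#' polysome-responsive (translated, pVHL-suppressible), or both. The union
#' across cell lines is duplicate-free with provenance retained.
#'
#' @param comparison_flags Data frame `erv_id, cell_line, comparison,
#'   responsive`.
#' @param polysome_flags Optional data frame `erv_id, cell_line,
#'   polysome_responsive`.
#' @return List `per_cell_line` (tier table) and `candidates`
#'   (non-redundant union with `cell_lines`, `via_tier`, `via_polysome`).
#' @export
tier_and_union <- function(comparison_flags, polysome_flags = NULL) {
  cf <- data.table::as.data.table(comparison_flags)
  per <- cf[, .(n_responsive = sum(responsive)), by = .(erv_id, cell_line)]
  if (!is.null(polysome_flags) && nrow(polysome_flags)) {
    pf <- data.table::as.data.table(polysome_flags)
    per <- merge(per, pf[, .(erv_id, cell_line, polysome_responsive)],
                 by = c("erv_id", "cell_line"), all = TRUE)
    per[is.na(n_responsive), n_responsive := 0L]
    per[is.na(polysome_responsive), polysome_responsive := FALSE]
  } else {
    per[, polysome_responsive := FALSE]
  }
  per[, tier := ifelse(n_responsive >= 3, "all_three",
                       ifelse(n_responsive == 2, "two_of_three", "fewer"))]
  per[, candidate := tier %in% c("all_three", "two_of_three") | polysome_responsive]
  cand <- per[candidate == TRUE]
  candidates <- cand[, .(
    cell_lines = paste(sort(unique(cell_line)), collapse = ","),
    via_tier = any(tier %in% c("all_three", "two_of_three")),
    via_polysome = any(polysome_responsive)), by = erv_id]
  data.table::setorder(candidates, erv_id)
  list(per_cell_line = as.data.frame(per), candidates = as.data.frame(candidates))
}
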