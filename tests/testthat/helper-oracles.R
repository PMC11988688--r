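# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (and Biostrings) so implementation vs oracle is a
# genuine dual route.

# standard genetic code, hardcoded
ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_translate <- function(s) {
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return("")
  codons <- substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aa <- ORACLE_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# all six frames, split at '*', keep stretches >= min_len; returns the
# multiset of ORF sequences (sorted)
oracle_sixframe_orfs <- function(seq, min_len) {
  out <- character()
  for (s in c(seq, oracle_revcomp(seq))) {
    for (off in 0:2) {
      aa <- oracle_translate(substr(s, off + 1L, nchar(s)))
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      out <- c(out, parts[nchar(parts) >= min_len])
    }
  }
  sort(out)
}

# all-pairs proximity oracle under the package's documented conventions:
# half-open overlap, extension clipped at 0, distance = gap + 1,
# lexicographic tie-break
oracle_annotate <- function(ervs, peaks, windows_kb) {
  windows_kb <- sort(unique(windows_kb))
  res <- lapply(seq_len(nrow(ervs)), function(i) {
    es <- ervs$start[i]; ee <- ervs$end[i]; ec <- ervs$chrom[i]
    same <- peaks[peaks$chrom == ec, , drop = FALSE]
    win <- NA_real_
    for (w in windows_kb) {
      f <- w * 1000
      ov <- pmax(pmax(0, same$start - f), es) < pmin(same$end + f, ee)
      if (any(ov)) { win <- w; break }
    }
    if (nrow(same)) {
      ov0 <- pmax(same$start, es) < pmin(same$end, ee)
      d <- ifelse(ov0, 0L, pmax(same$start, es) - pmin(same$end, ee) + 1L)
      dmin <- min(d)
      nearest <- sort(same$peak_id[d == dmin])[1]
    } else {
      dmin <- NA_integer_; nearest <- NA_character_
    }
    data.frame(
      erv_id = ervs$erv_id[i],
      peak_id = if (is.na(win)) NA_character_ else nearest,
      relation = if (is.na(win)) "none" else
        if (win == 0) "superimposed" else "within_window",
      window_kb = win, distance_bp = dmin, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

random_intervals <- function(n, kind, chroms = c("chr1", "chr2"),
                             max_pos = 50000L, max_len = 2000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + len,
                   stringsAsFactors = FALSE)
  if (kind == "erv") {
    cbind(data.frame(erv_id = sprintf("erv%04d", seq_len(n))), df,
          strand = sample(c("+", "-"), n, replace = TRUE),
          length = df$end - df$start)
  } else {
    cbind(data.frame(peak_id = sprintf("pk%04d", sample(seq_len(10 * n), n))), df,
          score = 1)
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_peptide <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# residue monoisotopic masses recomputed from atomic masses (independent of
# the package's table): elemental compositions of the 20 residues
oracle_residue_mass <- local({
  m <- c(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
         S = 31.97207100)
  comp <- list(
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  vapply(comp, function(x) sum(x * m), 0)
})
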