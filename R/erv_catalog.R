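#' Read a BED-style interval file of ERVs or ChIP peaks
#'
#' Parses a 3-6 column whitespace-separated BED file into a data frame of
#' interval records. Coordinates are BED convention: 0-based, half-open.
#' Optional columns (name, score, strand) are honored when present; missing
#' names are autogenerated from the line number.
#'
#' @param path Path to the interval file.
#' @param kind `"erv"` or `"peak"`; controls the id column name and whether
#'   strand is retained.
#' @return A `data.frame` in file order. For `kind = "erv"`: columns
#'   `erv_id, chrom, start, end, strand, length`. For `kind = "peak"`:
#'   `peak_id, chrom, start, end, score`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tERVX\t0\t+", f)
#' read_interval_file(f, "erv")
#' @export
read_interval_file <- function(path, kind = c("erv", "peak")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("interval file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  rec <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    ln <- idx[i]
    if (length(f) < 3L) {
      stop("line ", ln, ": expected >= 3 whitespace-separated columns")
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("line ", ln, ": malformed coordinate (non-integer start/end)")
    }
    if (start >= end) {
      stop("line ", ln, ": malformed coordinate (start >= end)")
    }
    name <- if (length(f) >= 4L) f[4] else sprintf("%s_%d", kind, i)
    score <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else NA_real_
    strand <- if (length(f) >= 6L) f[6] else "+"
    if (!strand %in% c("+", "-", ".")) {
      stop("line ", ln, ": unknown strand symbol '", strand, "'")
    }
    rec[[i]] <- list(name = name, chrom = f[1], start = start, end = end,
                     score = score, strand = if (strand == ".") "+" else strand)
  }
  name <- vapply(rec, `[[`, "", "name")
  chrom <- vapply(rec, `[[`, "", "chrom")
  start <- vapply(rec, function(r) r$start, 0L)
  end <- vapply(rec, function(r) r$end, 0L)
  if (kind == "erv") {
    if (anyDuplicated(name)) {
      stop("duplicate erv_id in catalog: ",
           paste(unique(name[duplicated(name)]), collapse = ", "))
    }
    data.frame(erv_id = name, chrom = chrom, start = start, end = end,
               strand = vapply(rec, `[[`, "", "strand"),
               length = end - start, stringsAsFactors = FALSE)
  } else {
    data.frame(peak_id = name, chrom = chrom, start = start, end = end,
               score = vapply(rec, function(r) r$score, 0), stringsAsFactors = FALSE)
  }
}

#' Write intervals back out as BED
#'
#' @param x A data frame from [read_interval_file()] (either kind).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_file <- function(x, path) {
  id_col <- if ("erv_id" %in% names(x)) "erv_id" else "peak_id"
  out <- data.frame(x$chrom, x$start, x$end, x[[id_col]],
                    if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0,
                    if ("strand" %in% names(x)) x$strand else "+")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: BED data.frame -> GRanges (1-based closed); seqlevels can be
# forced to a shared namespace so cross-set overlap calls stay quiet
.bed_to_granges <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*")
}

#' Extract ERV nucleotide sequences from a genome
#'
#' Pulls the genomic sequence for each catalog interval. Minus-strand records
#' are reverse-complemented so downstream translation sees the sense
#' orientation first (six-frame translation makes orientation immaterial to
#' the final ORF set, but the convention is fixed for reproducibility).
#'
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome, or a path
#'   to a FASTA file.
#' @param ervs ERV catalog data frame (see [read_interval_file()]).
#' @return Named character vector: `erv_id` -> nucleotide sequence.
#' @export
extract_erv_sequences <- function(genome, ervs) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  missing_chr <- setdiff(unique(ervs$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome: ", paste(missing_chr, collapse = ", "))
  }
  out <- character(nrow(ervs))
  for (i in seq_len(nrow(ervs))) {
    chr_len <- length(genome[[ervs$chrom[i]]])
    if (ervs$end[i] > chr_len || ervs$start[i] < 0L) {
      stop("interval ", ervs$erv_id[i], " out of range for ", ervs$chrom[i],
           " (length ", chr_len, ")")
    }
    s <- Biostrings::subseq(genome[[ervs$chrom[i]]],
                            start = ervs$start[i] + 1L, end = ervs$end[i])
    if (ervs$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  names(out) <- ervs$erv_id
  out
}

#' Extend peak intervals symmetrically
#'
#' Each interval is widened by `flank_bp` on both sides; starts are clipped
#' at zero. Order and ids are preserved.
#'
#' @param peaks Peak data frame.
#' @param flank_bp Non-negative flank in bases.
#' @return The peaks data frame with updated `start`/`end`.
#' @export
extend_intervals <- function(peaks, flank_bp) {
  .assert_scalar_number(flank_bp, "flank_bp", min = 0)
  peaks$start <- pmax(0L, peaks$start - as.integer(flank_bp))
  peaks$end <- peaks$end + as.integer(flank_bp)
  peaks
}

#' Annotate each ERV with its relation to the nearest HIF2 peak
#'
#' For every ERV, finds the smallest window (in kb) at which any peak,
#' extended by that window on both sides, overlaps the ERV under half-open
#' overlap semantics (`max(starts) < min(ends)`). Window 0 means a
#' superimposed binding site. Distance between disjoint intervals is the gap
#' in bases plus one, so touching half-open intervals have distance 1; ties
#' on distance resolve to the lexicographically smallest `peak_id`.
#'
#' @param ervs ERV catalog data frame.
#' @param peaks Peak data frame.
#' @param windows_kb Ascending windows in kb; 0 must be included to detect
#'   superimposed sites. Default `c(0, 1, 5, 10)`.
#' @return Data frame `erv_id, peak_id, relation, window_kb, distance_bp`,
#'   one row per ERV, in catalog order. `relation` is one of
#'   `superimposed`, `within_window`, `none`.
#' @export
annotate_peak_proximity <- function(ervs, peaks, windows_kb = c(0, 1, 5, 10)) {
  if (length(windows_kb) == 0L) stop("windows_kb must be non-empty")
  windows_kb <- sort(unique(windows_kb))
  n <- nrow(ervs)
  chroms <- unique(c(ervs$chrom, peaks$chrom))
  erv_gr <- .bed_to_granges(ervs, chroms)
  window_at <- rep(NA_real_, n)
  if (nrow(peaks) > 0L) {
    peak_gr <- .bed_to_granges(peaks, chroms)
    for (w in windows_kb) {
      ext <- GenomicRanges::resize(peak_gr,
                                   width = GenomicRanges::width(peak_gr) + 2L * as.integer(w * 1000),
                                   fix = "center")
      ext <- GenomicRanges::trim(GenomicRanges::restrict(ext, start = 1L))
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(erv_gr, ext, ignore.strand = TRUE)))
      unassigned <- which(is.na(window_at))
      window_at[intersect(hit, unassigned)] <- w
    }
  }
  # nearest peak + distance, computed directly per chromosome so distance
  # ties across both sides of the ERV resolve by the documented
  # lexicographic rule (GenomicRanges::nearest() picks one side arbitrarily)
  nearest_id <- rep(NA_character_, n)
  dist_bp <- rep(NA_integer_, n)
  if (nrow(peaks) > 0L) {
    peaks_by_chrom <- split(peaks, peaks$chrom)
    for (i in seq_len(n)) {
      same <- peaks_by_chrom[[ervs$chrom[i]]]
      if (is.null(same)) next
      ov <- pmax(same$start, ervs$start[i]) < pmin(same$end, ervs$end[i])
      d <- ifelse(ov, 0L,
                  pmax(same$start, ervs$start[i]) -
                    pmin(same$end, ervs$end[i]) + 1L)
      dmin <- min(d)
      nearest_id[i] <- sort(same$peak_id[d == dmin])[1L]
      dist_bp[i] <- as.integer(dmin)
    }
  }
  relation <- ifelse(is.na(window_at), "none",
                     ifelse(window_at == 0, "superimposed", "within_window"))
  data.frame(
    erv_id = ervs$erv_id,
    peak_id = ifelse(relation == "none", NA_character_, nearest_id),
    relation = relation,
    window_kb = window_at,
    distance_bp = dist_bp,
    stringsAsFactors = FALSE)
}

#' Tabulate proximity annotations per window
#'
#' Summarises [annotate_peak_proximity()] output into per-window counts
#' (cumulative: an ERV superimposed on a peak also counts at larger windows),
#' the shape used to report "n ERVs with a binding site within w kb".
#'
#' @param annot Output of [annotate_peak_proximity()].
#' @param windows_kb Windows to tabulate.
#' @return Data frame `window_kb, n_ervs`.
#' @export
proximity_window_counts <- function(annot, windows_kb = c(0, 1, 5, 10)) {
  windows_kb <- sort(unique(windows_kb))
  n <- vapply(windows_kb, function(w) {
    sum(!is.na(annot$window_kb) & annot$window_kb <= w)
  }, 0L)
  data.frame(window_kb = windows_kb, n_ervs = n)
}
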