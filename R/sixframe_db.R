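#' Six-frame ORF translation of a nucleotide sequence
#'
#' Translates all six reading frames with the standard genetic code, splits
#' each frame's translation at stop codons into maximal stop-free stretches,
#' drops trailing partial codons, and keeps stretches of at least
#' `min_protein_length` residues. A methionine start is not required by
#' default, matching proteogenomic practice for short retroviral ORFs; with
#' `require_met = TRUE` each stretch is trimmed to its first M and
#' re-checked against the length floor. Codons containing N translate to
#' `X`; `X` never terminates an ORF but also never matches a peptide query
#' downstream.
#'
#' @param seq Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param min_protein_length Minimum ORF length in residues (default 7).
#' @param require_met Require/trim to an initiator methionine (default FALSE).
#' @return Data frame `frame` (one of `+1,+2,+3,-1,-2,-3`), `aa_offset`
#'   (0-based residue offset within that frame's translation) and `sequence`.
#' @examples
#' six_frame_orfs("ATGAAATAA", min_protein_length = 1)
#' @export
six_frame_orfs <- function(seq, min_protein_length = 7, require_met = FALSE) {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside the A/C/G/T/N alphabet")
  }
  .assert_scalar_number(min_protein_length, "min_protein_length", min = 1)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- list()
  for (dir in c("+", "-")) {
    s <- if (dir == "+") seq else rc
    for (off in 0:2) {
      n_codons <- (nchar(s) - off) %/% 3L
      if (n_codons < 1L) next
      sub <- substr(s, off + 1L, off + 3L * n_codons)
      aa <- .translate_dna(sub)
      m <- gregexpr("[^*]+", aa)[[1]]
      if (m[1] == -1L) next
      lens <- attr(m, "match.length")
      for (j in seq_along(m)) {
        orf <- substr(aa, m[j], m[j] + lens[j] - 1L)
        aa_offset <- m[j] - 1L
        if (require_met) {
          mpos <- regexpr("M", orf, fixed = TRUE)
          if (mpos == -1L) next
          orf <- substr(orf, mpos, nchar(orf))
          aa_offset <- aa_offset + mpos - 1L
        }
        if (nchar(orf) >= min_protein_length) {
          out[[length(out) + 1L]] <- list(frame = paste0(dir, off + 1L),
                                          aa_offset = aa_offset,
                                          sequence = orf)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = character(), aa_offset = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  data.frame(frame = vapply(out, `[[`, "", "frame"),
             aa_offset = vapply(out, function(x) as.integer(x$aa_offset), 0L),
             sequence = vapply(out, `[[`, "", "sequence"),
             stringsAsFactors = FALSE)
}

# standard genetic code, cached once; codons containing N translate to X
.CODON_TABLE <- c(Biostrings::GENETIC_CODE)

.translate_dna <- function(s) {
  n <- nchar(s)
  codons <- substring(s, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- .CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame ORFs for a set of ERV sequences
#'
#' @param seqs Named character vector of nucleotide sequences
#'   (`erv_id` -> sequence), e.g. from [extract_erv_sequences()].
#' @inheritParams six_frame_orfs
#' @return Data frame `source_id, frame, aa_offset, sequence`.
#' @export
six_frame_orfs_all <- function(seqs, min_protein_length = 7, require_met = FALSE) {
  stopifnot(!is.null(names(seqs)))
  res <- lapply(names(seqs), function(id) {
    o <- six_frame_orfs(seqs[[id]], min_protein_length, require_met)
    if (nrow(o)) cbind(source_id = id, o, stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.frame(source_id = character(), frame = character(),
                      aa_offset = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Build the merged proteogenomic search database
#'
#' Appends six-frame ERV ORF proteins (and optional laboratory contaminants)
#' to a base reference proteome. ERV entries are given accessions
#' `ERV|<erv_id>|<frame>|<aa_offset>`. Exact duplicate sequences within a
#' source class are collapsed to one entry: the first accession wins and the
#' collapsed entry's `description` lists all contributing accessions, which
#' preserves the many-homologous-ERVs-per-peptide bookkeeping.
#'
#' @param reference Named character vector of reference proteins, an
#'   `AAStringSet`, or a FASTA path.
#' @param erv_orfs Data frame from [six_frame_orfs_all()] (may be NULL).
#' @param contaminants Like `reference`; optional.
#' @return Data frame `accession, sequence, source_class, description` with
#'   `source_class` in `reference`, `erv`, `contaminant`.
#' @export
build_search_db <- function(reference, erv_orfs = NULL, contaminants = NULL) {
  ref <- .as_protein_vector(reference, "reference")
  if (!length(ref)) stop("reference proteome must be non-empty")
  entries <- list(.db_block(names(ref), unname(ref), "reference"))
  if (!is.null(contaminants)) {
    cont <- .as_protein_vector(contaminants, "contaminants")
    if (length(cont)) entries <- c(entries, list(.db_block(names(cont), unname(cont), "contaminant")))
  }
  if (!is.null(erv_orfs) && nrow(erv_orfs)) {
    acc <- sprintf("ERV|%s|%s|%d", erv_orfs$source_id, erv_orfs$frame,
                   erv_orfs$aa_offset)
    entries <- c(entries, list(.db_block(acc, erv_orfs$sequence, "erv")))
  }
  db <- do.call(rbind, entries)
  if (anyDuplicated(db$accession)) {
    stop("duplicate accession across inputs: ",
         paste(head(unique(db$accession[duplicated(db$accession)]), 5), collapse = ", "))
  }
  rownames(db) <- NULL
  db
}

# internal: one source-class block with within-class exact-sequence collapse
.db_block <- function(accession, sequence, source_class) {
  if (any(!nzchar(sequence))) stop("empty sequence in ", source_class, " input")
  if (anyDuplicated(accession)) {
    stop("duplicate accession within ", source_class, " input")
  }
  grp <- split(seq_along(sequence), sequence)
  first <- vapply(grp, `[`, 0L, 1L)
  ord <- order(first)
  first <- first[ord]; grp <- grp[ord]
  desc <- vapply(grp, function(ix) paste(accession[ix], collapse = ";"), "")
  data.frame(accession = accession[first], sequence = sequence[first],
             source_class = source_class, description = unname(desc),
             stringsAsFactors = FALSE)
}

.as_protein_vector <- function(x, what) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readAAStringSet(x)
  }
  if (methods::is(x, "AAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("%s_%d", what, seq_along(x))
    return(x)
  }
  stop("cannot interpret ", what, " input")
}

#' Write / read a search database as FASTA
#'
#' The source class is encoded in the header as `|class=<class>` so the
#' database round-trips through a single FASTA file.
#'
#' @param db Search database data frame.
#' @param path FASTA path.
#' @return `path` (write) or the database data frame (read).
#' @export
write_search_db_fasta <- function(db, path) {
  hdr <- sprintf(">%s|class=%s %s", db$accession, db$source_class, db$description)
  writeLines(as.vector(rbind(hdr, db$sequence)), path)
  invisible(path)
}

#' @rdname write_search_db_fasta
#' @export
read_search_db_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  acc_class <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  cls <- sub("^.*\\|class=", "", acc_class)
  acc <- sub("\\|class=.*$", "", acc_class)
  data.frame(accession = acc, sequence = as.character(aa), source_class = cls,
             description = desc, stringsAsFactors = FALSE)
}

# internal: all k-mers of a character vector of sequences (I/L collapsed)
.kmer_set <- function(seqs, k, collapse_il = TRUE) {
  if (collapse_il) seqs <- chartr("I", "L", seqs)
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) return(character())
  unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE))
}

#' Unique k-mer contribution per source class
#'
#' Counts distinct I/L-collapsed k-mers attributed to exactly one class by
#' the priority `reference > contaminant > erv`: a k-mer shared with the
#' reference proteome never counts as ERV-specific, mirroring the
#' downstream elimination of reference-mapping peptides.
#'
#' @param db Search database data frame.
#' @param k K-mer length (default 9, the modal HLA-I peptide length).
#' @param collapse_il Collapse isobaric I/L before counting (default TRUE).
#' @return Data frame `source_class, n_unique_kmers, fraction`; fractions sum
#'   to 1 over non-empty classes (all zero when no sequence reaches length k).
#' @export
unique_kmer_contribution <- function(db, k = 9, collapse_il = TRUE) {
  .assert_scalar_number(k, "k", min = 1)
  classes <- c("reference", "contaminant", "erv")
  sets <- lapply(classes, function(cl) .kmer_set(db$sequence[db$source_class == cl], k, collapse_il))
  names(sets) <- classes
  attributed <- list(
    reference = sets$reference,
    contaminant = setdiff(sets$contaminant, sets$reference),
    erv = setdiff(sets$erv, union(sets$reference, sets$contaminant)))
  n <- vapply(attributed, length, 0L)
  total <- sum(n)
  present <- classes[classes %in% db$source_class]
  data.frame(source_class = present,
             n_unique_kmers = unname(n[present]),
             fraction = if (total > 0) unname(n[present]) / total else rep(0, length(present)),
             stringsAsFactors = FALSE)
}

#' Map a peptide to all its database sources
#'
#' Finds every substring occurrence of `peptide` across the search database.
#' With `collapse_il = TRUE` (default) isoleucine and leucine are treated as
#' one symbol, since the two residues are isobaric and indistinguishable by
#' fragment mass. `X` residues in the database (from ambiguous codons) never
#' match a standard-residue query.
#'
#' @param peptide Amino-acid string (length >= 1).
#' @param db Search database data frame.
#' @param collapse_il Treat I and L as equivalent (default TRUE).
#' @return List with `peptide`, `il_collapsed`, and `matches`: a data frame
#'   `accession, source_class, position` (1-based match positions).
#' @export
map_peptide_sources <- function(peptide, db, collapse_il = TRUE) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide)) {
    stop("peptide must be a non-empty string")
  }
  q <- toupper(peptide)
  subj <- db$sequence
  if (collapse_il) {
    q <- chartr("I", "L", q)
    subj <- chartr("I", "L", subj)
  }
  hits <- gregexpr(q, subj, fixed = TRUE)
  desc <- if ("description" %in% names(db)) db$description else db$accession
  rows <- lapply(seq_along(hits), function(i) {
    p <- hits[[i]]
    if (p[1] == -1L) return(NULL)
    data.frame(accession = db$accession[i], source_class = db$source_class[i],
               position = as.integer(p), sources = desc[i],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), source_class = character(),
               position = integer(), sources = character(),
               stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  structure(list(peptide = peptide, il_collapsed = collapse_il,
                 matches = matches),
            class = "peptide_source_map")
}

#' Is a mapped peptide exclusive to ERV sources?
#'
#' TRUE iff the peptide has at least one ERV match and no reference-proteome
#' match (I/L-aware when the map was built with `collapse_il = TRUE`).
#'
#' @param map A `peptide_source_map` from [map_peptide_sources()].
#' @return Logical scalar.
#' @export
is_erv_exclusive <- function(map) {
  stopifnot(inherits(map, "peptide_source_map"))
  any(map$matches$source_class == "erv") &&
    !any(map$matches$source_class == "reference")
}

#' @export
print.peptide_source_map <- function(x, ...) {
  cat("peptide_source_map:", x$peptide,
      if (x$il_collapsed) "(I/L collapsed)" else "", "\n")
  cat("  matches:", nrow(x$matches), "across",
      length(unique(x$matches$accession)), "entries\n")
  invisible(x)
}
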