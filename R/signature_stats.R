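#' Log-transform and z-score an expression matrix
#'
#' Per feature (row): `z = (log2(x + 1) - mean) / sd` across samples, with
#' the sample (n-1) standard deviation. Zero-variance features become
#' all-zero rows with a warning rather than NaN, so downstream signature
#' averaging stays defined.
#'
#' @param mat Non-negative numeric matrix, features x samples.
#' @return Matrix of the same shape with standardized rows.
#' @export
log_zscore <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("expression values must be >= 0")
  lz <- log2(mat + 1)
  mu <- rowMeans(lz)
  s <- apply(lz, 1, sd)
  zero_var <- s == 0 | is.na(s)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance feature(s) set to all-zero rows")
    s[zero_var] <- 1
  }
  z <- (lz - mu) / s
  z[zero_var, ] <- 0
  z
}

#' Per-sample signature score
#'
#' Averages the standardized expression rows of a gene set, one score per
#' sample. Members absent from the matrix are dropped with a warning.
#'
#' @param zmat Standardized matrix (see [log_zscore()]), rownames = genes.
#' @param gene_set Character vector of member genes.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(zmat, gene_set) {
  present <- intersect(gene_set, rownames(zmat))
  if (!length(present)) {
    stop("no gene of the set present in the matrix: ",
         paste(gene_set, collapse = ", "))
  }
  missing <- setdiff(gene_set, present)
  if (length(missing)) {
    warning("signature member(s) absent: ", paste(missing, collapse = ", "))
  }
  colMeans(zmat[present, , drop = FALSE])
}

#' Pearson correlation of ERVs against signature/gene targets with BH
#'
#' Computes Pearson r and a two-sided p-value for each (ERV, target) pair
#' and applies Benjamini-Hochberg adjustment within each target family
#' (one family per target, across ERVs). Zero-variance inputs yield an NA
#' correlation, are flagged, and are excluded from the BH family.
#'
#' @param erv_mat Numeric matrix, ERVs x samples (rownames = erv ids).
#' @param targets Named list of per-sample numeric vectors (signature
#'   scores or single-gene rows), each of length `ncol(erv_mat)`.
#' @return Data frame `erv_id, target, r, p, p_adj, flagged`.
#' @export
correlate_with_bh <- function(erv_mat, targets) {
  erv_mat <- as.matrix(erv_mat)
  if (ncol(erv_mat) < 3) stop("need >= 3 samples")
  stopifnot(is.list(targets), !is.null(names(targets)))
  out <- list()
  for (tg in names(targets)) {
    y <- targets[[tg]]
    if (length(y) != ncol(erv_mat)) {
      stop("target '", tg, "' length != number of samples")
    }
    rows <- lapply(rownames(erv_mat), function(id) {
      x <- erv_mat[id, ]
      if (sd(x) == 0 || sd(y) == 0) {
        return(data.frame(erv_id = id, target = tg, r = NA_real_,
                          p = NA_real_, flagged = TRUE,
                          stringsAsFactors = FALSE))
      }
      ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
      data.frame(erv_id = id, target = tg, r = unname(ct$estimate),
                 p = ct$p.value, flagged = FALSE, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$p_adj <- NA_real_
    ok <- !fam$flagged
    fam$p_adj[ok] <- p.adjust(fam$p[ok], method = "BH")
    out[[tg]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("erv_id", "target", "r", "p", "p_adj", "flagged")]
}
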