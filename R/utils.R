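#' Hamming distance between two equal-length sequences
#'
#' Position-wise mismatch count between two strings, e.g. two peptides of the
#' same length.
#'
#' @param a,b Character scalars of equal length.
#' @return Integer number of differing positions.
#' @examples
#' hamming_distance("ATFLGSLTGK", "ATFLGSLTWK")
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance() requires equal-length sequences (", nchar(a),
         " vs ", nchar(b), ")")
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# internal: %||%
`%||%` <- function(x, y) if (is.null(x)) y else x

.assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop("'", name, "' must be a single number >= ", min)
  }
  invisible(x)
}

# derive a child RNG seed from a master seed; stays within 32-bit range
.derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}
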