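# Internal helpers shared across modules.

# Coerce a counts input to a sparse dgCMatrix with cells as rows.
# Accepts base matrix, any Matrix class, or data.frame of counts.
as_count_matrix <- function(counts, transpose = FALSE) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!inherits(counts, "Matrix")) {
    if (!is.matrix(counts)) {
      abort("`counts` must be a matrix, Matrix, or data.frame of counts.")
    }
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (transpose) counts <- Matrix::t(counts)
  counts
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count matrix must carry cell ids (rownames) and gene ids (colnames).")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate cell ids in count matrix.")
  if (anyDuplicated(colnames(counts))) abort("duplicate gene ids in count matrix.")
  x <- counts@x
  if (length(x) && (any(!is.finite(x)) || any(x < 0))) {
    abort("count matrix entries must be finite and non-negative.")
  }
  invisible(counts)
}

# Number of genes detected (count > 0) per cell.
n_expressed_genes <- function(counts) {
  Matrix::rowSums(counts > 0)
}

# round() half-away-from-zero (base round() is banker's rounding).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Deterministic seeded evaluation that does not disturb the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

# Derive a stream-specific child seed from a base seed (stays below 2^31).
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) * 7919L
}

`%||%` <- rlang::`%||%`
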