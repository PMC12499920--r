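#' Read a single-cell count matrix
#'
#' Reads either a Matrix Market directory/triplet (CellRanger dialect:
#' `matrix.mtx` with `barcodes.tsv` and `features.tsv`/`genes.tsv` sidecars,
#' plain or gzipped) or a dense delimited table with header row and id column.
#' The internal orientation is cells-as-rows; CellRanger MTX stores genes as
#' rows, so MTX input is transposed on load by default.
#'
#' @param path Path to a directory containing the MTX triplet, to a `.mtx`
#'   file, or to a delimited text file (`.csv`/`.tsv`/`.txt`).
#' @param transpose Transpose the matrix after reading. Default `TRUE` for
#'   MTX input (genes-as-rows on disk), `FALSE` for dense tables
#'   (assumed cells-as-rows).
#' @return A sparse `dgCMatrix` with cells as rows and genes as columns.
#' @export
read_counts <- function(path, transpose = NULL) {
  if (dir.exists(path)) {
    mtx <- list.files(path, pattern = "\\.mtx(\\.gz)?$", full.names = TRUE)
    if (length(mtx) == 0) abort(paste0("no .mtx file found in ", path))
    return(read_counts_mtx(mtx[[1]], transpose = transpose %||% TRUE))
  }
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    return(read_counts_mtx(path, transpose = transpose %||% TRUE))
  }
  read_counts_dense(path, transpose = transpose %||% FALSE)
}

read_counts_mtx <- function(mtx_path, transpose = TRUE) {
  dir <- dirname(mtx_path)
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  sidecar <- function(stems) {
    for (stem in stems) {
      for (ext in c(".tsv", ".tsv.gz", ".txt", ".txt.gz")) {
        f <- file.path(dir, paste0(stem, ext))
        if (file.exists(f)) return(f)
      }
    }
    NULL
  }
  bc <- sidecar("barcodes")
  ft <- sidecar(c("features", "genes"))
  if (is.null(bc) || is.null(ft)) {
    abort("MTX input requires barcodes and features/genes sidecar files.")
  }
  barcodes <- read.delim(bc, header = FALSE, stringsAsFactors = FALSE)[[1]]
  feat <- read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  # CellRanger features.tsv: id, name, type; use the first column as gene id
  genes <- feat[[1]]
  rownames(m) <- genes
  colnames(m) <- barcodes
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  if (transpose) m <- Matrix::t(m)
  validate_counts(m)
  m
}

read_counts_dense <- function(path, transpose = FALSE) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as_count_matrix(as.matrix(df), transpose = transpose)
  validate_counts(m)
  m
}

#' Write a count or normalized matrix
#'
#' Writes either the CellRanger-style MTX triplet (`matrix.mtx`,
#' `barcodes.tsv`, `features.tsv`; genes as rows on disk) or a dense
#' delimited table with cells as rows. A [normalize_log()] result is
#' accepted and its value matrix written.
#'
#' @param x A cells-by-genes matrix or a `stardust_norm` object.
#' @param path Output directory (MTX) or file path (`.csv`/`.tsv`).
#' @param format `"mtx"` or `"dense"`; inferred from `path` when `NULL`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = NULL) {
  if (inherits(x, "stardust_norm")) x <- x$values
  format <- format %||% if (grepl("\\.(csv|tsv|txt)$", path)) "dense" else "mtx"
  if (format == "mtx") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(Matrix::t(methods::as(x, "CsparseMatrix")),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(x), file.path(path, "barcodes.tsv"))
    writeLines(colnames(x), file.path(path, "features.tsv"))
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- as.data.frame(as.matrix(x), check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Read an externally computed 2D embedding
#'
#' Expects a delimited table with columns for the cell id and the two
#' embedding coordinates (named `cell`/`cell_id`/`id`, `x`, `y`, or the
#' first three columns in that order).
#'
#' @param path Delimited text file.
#' @return A tibble with columns `node_id`, `node_type` (`"cell"`), `x`, `y`.
#' @export
read_embedding <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  idc <- intersect(c("cell", "cell_id", "id", "node_id"), names(df))
  if (length(idc)) {
    id <- df[[idc[[1]]]]
    xy <- df[, intersect(c("x", "y"), names(df)), drop = FALSE]
    if (ncol(xy) < 2) xy <- df[, setdiff(names(df), idc)[1:2]]
  } else {
    id <- df[[1]]
    xy <- df[, 2:3]
  }
  tibble(node_id = as.character(id), node_type = "cell",
         x = as.numeric(xy[[1]]), y = as.numeric(xy[[2]]))
}

#' Write an embedding to a delimited table
#'
#' @param emb An embedding tibble (`node_id`, `node_type`, `x`, `y`, and
#'   optionally `cluster`).
#' @param path Output file; `.csv` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(as.data.frame(emb), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a bin map for spatial zonation
#'
#' A bin map consists of a genes-by-bins matrix of probabilistic mapping
#' scores plus a table of bin coordinates (2D or 3D).
#'
#' @param scores_path Delimited file of mapping scores; first column is the
#'   gene id, remaining columns are bins.
#' @param coords_path Delimited file of bin coordinates; first column is the
#'   bin id, remaining 2-3 columns are coordinates.
#' @return A `stardust_binmap` object; see [binmap()].
#' @export
read_binmap <- function(scores_path, coords_path) {
  rd <- function(p) {
    sep <- if (grepl("\\.csv(\\.gz)?$", p)) "," else "\t"
    read.delim(p, sep = sep, header = TRUE, row.names = 1, check.names = FALSE)
  }
  scores <- as.matrix(rd(scores_path))
  coords <- as.matrix(rd(coords_path))
  binmap(scores, coords)
}

#' Construct a bin map object
#'
#' @param scores Numeric genes-by-bins matrix of probabilistic mapping
#'   scores with gene rownames and bin colnames.
#' @param coords Numeric bins-by-2 (or 3) matrix of bin positions with bin
#'   rownames matching `colnames(scores)`.
#' @return A `stardust_binmap` list with elements `scores` and `coords`.
#' @export
binmap <- function(scores, coords) {
  scores <- as.matrix(scores)
  coords <- as.matrix(coords)
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    abort("`scores` must have gene rownames and bin colnames.")
  }
  if (is.null(rownames(coords))) rownames(coords) <- colnames(scores)
  if (!identical(sort(colnames(scores)), sort(rownames(coords)))) {
    abort("bin ids differ between `scores` columns and `coords` rows.")
  }
  coords <- coords[colnames(scores), , drop = FALSE]
  if (any(!is.finite(scores))) abort("`scores` must be finite.")
  structure(list(scores = scores, coords = coords), class = "stardust_binmap")
}

#' @export
print.stardust_binmap <- function(x, ...) {
  cat("<stardust_binmap> ", nrow(x$scores), " genes x ", ncol(x$scores),
      " bins (", ncol(x$coords), "D coordinates)\n", sep = "")
  invisible(x)
}
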