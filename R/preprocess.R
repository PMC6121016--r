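#' Log2-transform a raw expression matrix
#'
#' Applies `log2(v + offset)` to every cell, where the offset is the smallest
#' strictly positive value in the whole matrix. This is the standard first step
#' for RSEM/FPKM-like abundance values before linear modeling: it pulls the
#' heavy right tail in so that per-gene expression is approximately Gaussian,
#' while the global (not per-gene) offset keeps zeros finite and preserves the
#' ordering of raw values.
#'
#' @param raw Numeric matrix, genes in rows and samples in columns, all values
#'   non-negative. Dimnames are carried through.
#' @return A numeric matrix of the same shape with attribute `log2_offset`
#'   recording the offset used.
#' @examples
#' m <- matrix(c(0, 1, 3, 7), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' log2_transform(m)
#' @export
log2_transform <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("expression matrix must be numeric")
  if (anyNA(raw)) stop("expression matrix contains missing values")
  if (any(raw < 0)) stop("expression matrix contains negative values")
  pos <- raw[raw > 0]
  if (length(pos) == 0L) {
    stop("all values are zero: no non-zero offset can be computed")
  }
  offset <- min(pos)
  out <- log2(raw + offset)
  attr(out, "log2_offset") <- offset
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces the sample columns to share one empirical distribution: within each
#' scope unit, every column's values are replaced by the across-column mean of
#' sorted values at the corresponding rank, so that after normalization the
#' sorted values of every column are identical. Ties within a column receive
#' the mean of the reference values their ranks span, which keeps the map
#' deterministic and rank-preserving.
#'
#' @param m Numeric matrix, genes in rows and samples in columns.
#' @param scope `"joint"` (default) normalizes all samples against one common
#'   reference; `"per_group"` normalizes the normal and tumor columns
#'   separately, each against its own group reference.
#' @param group For `scope = "per_group"`, a vector of `"normal"`/`"tumor"`
#'   labels, one per column.
#' @return A matrix of the same shape with attribute `qn_scope`.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(m, scope = c("joint", "per_group"), group = NULL) {
  scope <- match.arg(scope)
  m <- as.matrix(m)
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (scope == "joint") {
    out <- qn_columns(m)
  } else {
    group <- check_group(group, ncol(m))
    out <- m
    for (g in levels(group)) {
      idx <- which(group == g)
      out[, idx] <- qn_columns(m[, idx, drop = FALSE])
    }
  }
  dimnames(out) <- dimnames(m)
  attr(out, "qn_scope") <- scope
  out
}

# One scope unit: columns mapped onto the mean-of-sorted-columns reference.
qn_columns <- function(m) {
  if (ncol(m) < 2L) {
    stop("quantile normalization needs at least 2 samples in each scope unit")
  }
  ref <- rowMeans(matrix(apply(m, 2, sort), nrow = nrow(m)))
  out <- apply(m, 2, function(col) {
    # ties.method = "first" places a tie group on consecutive ranks; averaging
    # the reference over each group of equal values applies the tie rule.
    mapped <- ref[rank(col, ties.method = "first")]
    stats::ave(mapped, match(col, col), FUN = mean)
  })
  matrix(out, nrow = nrow(m), dimnames = dimnames(m))
}

#' Full normalization pipeline for raw abundance values
#'
#' Convenience wrapper: [log2_transform()] followed by [quantile_normalize()].
#'
#' @inheritParams log2_transform
#' @inheritParams quantile_normalize
#' @return Normalized matrix carrying both provenance attributes.
#' @export
preprocess_expression <- function(raw, scope = c("joint", "per_group"),
                                  group = NULL) {
  lg <- log2_transform(raw)
  out <- quantile_normalize(lg, scope = scope, group = group)
  attr(out, "log2_offset") <- attr(lg, "log2_offset")
  out
}

check_group <- function(group, n) {
  if (is.null(group)) stop("per-group normalization needs a group vector")
  if (length(group) != n) stop("group length does not match number of samples")
  group <- factor(as.character(group), levels = c("normal", "tumor"))
  if (anyNA(group)) stop("group labels must be 'normal' or 'tumor'")
  droplevels(group)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample IDs and gene identifiers in the first
#' column; remaining cells numeric, no missing values.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("gene identifiers are not unique")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression file contains missing or non-numeric values")
  if (anyDuplicated(colnames(m))) stop("sample identifiers are not unique")
  rownames(m) <- ids
  m
}

#' Write an expression matrix as tab-separated text
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @param id_column Name for the gene-identifier column.
#' @export
write_expression <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
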