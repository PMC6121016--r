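#' Pooled-variance two-sample t-test
#'
#' The purity-blind baseline: a classical equal-variance two-sample t
#' statistic for tumor minus normal, with `n0 + n1 - 2` degrees of freedom
#' and a two-sided p-value. A zero pooled variance with equal means gives
#' `t = 0, p = 1`.
#'
#' @param x Normal-group values (length >= 2).
#' @param y Tumor-group values (length >= 2).
#' @return List with `t`, `p_value`, `df`.
#' @examples
#' two_sample_t_test(c(0, 2), c(3, 5)) # t = 3 / sqrt(2)
#' @export
two_sample_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  res <- row_t_test(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(t = res$t[1L], p_value = res$p_value[1L], df = res$df)
}

#' Row-wise pooled-variance t-tests
#'
#' Vectorized version of [two_sample_t_test()] across genes: one test per
#' row of aligned matrices.
#'
#' @param X Genes x normal-samples matrix.
#' @param Y Genes x tumor-samples matrix (same row order).
#' @return List with vectors `t` and `p_value` and scalar `df`.
#' @export
row_t_test <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("matrices must have the same genes")
  nx <- ncol(X); ny <- ncol(Y)
  if (nx < 2L || ny < 2L) stop("each group needs >= 2 samples")
  df <- nx + ny - 2L
  mx <- rowMeans(X); my <- rowMeans(Y)
  ss <- rowSums((X - mx)^2) + rowSums((Y - my)^2)
  se <- sqrt(ss / df * (1 / nx + 1 / ny))
  diff <- my - mx
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df = df))
  list(t = unname(t), p_value = unname(p), df = df)
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with ties counted 1/2. Computed from
#' average ranks, which is exactly the normalized Wilcoxon statistic.
#'
#' @param scores Numeric scores, larger = more confidently positive.
#' @param labels Logical (or 0/1) truth labels, same length.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels misaligned")
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Compare the purity-corrected caller with the t-test baseline
#'
#' Runs [run_dectp()] (by default with the reported, possibly noisy,
#' purities) and the row-wise pooled t-test on a simulated dataset's observed
#' matrices (X, Y'), ranks genes by absolute statistic, and scores each
#' method by ROC AUC against the simulation's true-DEG labels.
#'
#' @param dataset A [simulate_dataset()] result with both truth classes
#'   present.
#' @param shrink_weight Variance-shrinkage weight passed to [run_dectp()].
#' @param use_reported Use reported (noisy) purities if `TRUE` (default),
#'   otherwise the true purities.
#' @param extra_scores Optional named list of externally computed per-gene
#'   score vectors (aligned to the dataset's gene order) to evaluate
#'   alongside the built-in methods.
#' @return An object of class `dectp_comparison`: list with `summary` (a
#'   `data.frame`: method, auc, n_genes, n_true_deg, seed) and `scores`
#'   (per-gene score matrix, one column per method).
#' @export
compare_methods <- function(dataset, shrink_weight = 0.5,
                            use_reported = TRUE, extra_scores = NULL) {
  stopifnot(inherits(dataset, "dectp_simulation"))
  truth <- dataset$truth$is_deg
  if (all(truth) || !any(truth)) {
    stop("truth labels contain a single class; AUC is undefined")
  }
  purity <- if (use_reported) dataset$reported_purities else dataset$true_purities
  expr <- cbind(dataset$X, dataset$Y_prime)
  de <- run_dectp(expr, purity, shrink_weight = shrink_weight)
  tt <- row_t_test(dataset$X, dataset$Y_prime)

  scores <- cbind(DECtp = abs(de$wald_t), t_test = abs(tt$t))
  if (!is.null(extra_scores)) {
    for (nm in names(extra_scores)) {
      if (length(extra_scores[[nm]]) != nrow(scores)) {
        stop("extra score vector '", nm, "' is misaligned")
      }
      scores <- cbind(scores, extra_scores[[nm]])
      colnames(scores)[ncol(scores)] <- nm
    }
  }
  rownames(scores) <- dataset$truth$gene_id
  aucs <- apply(scores, 2, roc_auc, labels = truth)
  structure(list(
    summary = data.frame(method = colnames(scores), auc = unname(aucs),
                         n_genes = nrow(scores), n_true_deg = sum(truth),
                         seed = dataset$config$seed,
                         stringsAsFactors = FALSE, row.names = NULL),
    scores = scores,
    truth = truth
  ), class = "dectp_comparison")
}

#' Write a method-comparison summary
#'
#' @param comparison A [compare_methods()] result.
#' @param path Output TSV path for the summary table.
#' @param scores_path Optional path for the per-gene score table.
#' @export
write_comparison <- function(comparison, path, scores_path = NULL) {
  stopifnot(inherits(comparison, "dectp_comparison"))
  utils::write.table(comparison$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(scores_path)) {
    df <- data.frame(gene_id = rownames(comparison$scores),
                     comparison$scores, is_deg = comparison$truth,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, scores_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
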