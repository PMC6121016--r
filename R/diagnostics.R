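#' Per-gene Spearman correlation between expression and tumor purity
#'
#' Under the mixture model, a gene's observed tumor expression depends on
#' purity exactly when its pure-tumor mean differs from its normal mean, so
#' strong expression-purity correlation flags differential genes. This
#' computes, for every gene, the Spearman rank correlation (average-rank tie
#' handling) between its expression across tumor samples and the purities;
#' optionally against a single seeded permutation of the purities, which
#' serves as the empirical null.
#'
#' @param expr_tumor Genes x tumor-samples matrix (>= 3 samples).
#' @param purities Purity vector aligned to the columns.
#' @param shuffle If `TRUE`, additionally correlate against permuted
#'   purities.
#' @param seed Seed for the permutation (required when `shuffle = TRUE`).
#' @return A `data.frame`: `gene_id`, `rho`, `degenerate` (constant
#'   expression row, `rho` recorded as 0), and `rho_shuffled` when
#'   `shuffle = TRUE`.
#' @export
purity_correlation <- function(expr_tumor, purities, shuffle = FALSE,
                               seed = NULL) {
  expr_tumor <- as.matrix(expr_tumor)
  if (ncol(expr_tumor) < 3L) stop("need at least 3 tumor samples")
  if (length(purities) != ncol(expr_tumor)) {
    stop("purities misaligned with expression columns")
  }
  if (is.null(rownames(expr_tumor))) {
    rownames(expr_tumor) <- paste0("gene_", seq_len(nrow(expr_tumor)))
  }
  res <- data.frame(gene_id = rownames(expr_tumor),
                    rho = spearman_rows(expr_tumor, purities),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$degenerate <- is.na(res$rho)
  res$rho[res$degenerate] <- 0
  if (shuffle) {
    if (is.null(seed)) stop("a seed is required for the purity shuffle")
    perm <- with_seed(seed, sample.int(length(purities)))
    rs <- spearman_rows(expr_tumor, purities[perm])
    res$rho_shuffled <- ifelse(is.na(rs), 0, rs)
  }
  res
}

# Row-wise Spearman rho against one covariate; NA for constant rows.
spearman_rows <- function(m, v) {
  rv <- rank(v, ties.method = "average")
  rm_ <- t(apply(m, 1, rank, ties.method = "average"))
  suppressWarnings(drop(stats::cor(t(rm_), rv, method = "pearson")))
}

#' Group genes into bins by a test statistic
#'
#' Splits genes into `n_groups` nearly equal-size bins by the rank of their
#' statistic (ties broken by gene ID for determinism) and summarizes the
#' purity correlations within each bin. Rising mean correlation across bins
#' is the signature of purity confounding.
#'
#' @param rhos Per-gene correlation values.
#' @param statistics Per-gene test statistics, aligned with `rhos`.
#' @param gene_ids Gene identifiers (used for deterministic tie-breaking);
#'   defaults to position.
#' @param n_groups Number of bins (default 10).
#' @return A list with `assignment` (a `data.frame`: gene_id, statistic,
#'   rho, group) and `summary` (per-group n, mean_rho, mean_abs_rho).
#' @export
group_by_statistic <- function(rhos, statistics, gene_ids = NULL,
                               n_groups = 10L) {
  n <- length(rhos)
  if (length(statistics) != n) stop("rhos and statistics misaligned")
  if (n < n_groups) stop("fewer genes than groups")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(n))
  ord <- order(statistics, gene_ids)
  # nearly equal bin sizes (difference at most 1), in statistic order
  sizes <- rep(n %/% n_groups, n_groups) +
    c(rep(1L, n %% n_groups), rep(0L, n_groups - n %% n_groups))
  group <- integer(n)
  group[ord] <- rep(seq_len(n_groups), times = sizes)
  assignment <- data.frame(gene_id = gene_ids, statistic = statistics,
                           rho = rhos, group = group,
                           stringsAsFactors = FALSE, row.names = NULL)
  summary <- data.frame(
    group = seq_len(n_groups),
    n = as.integer(tabulate(group, n_groups)),
    mean_rho = as.numeric(tapply(rhos, group, mean)),
    mean_abs_rho = as.numeric(tapply(abs(rhos), group, mean)),
    row.names = NULL)
  list(assignment = assignment, summary = summary)
}

#' Mean absolute purity correlation of top-ranked genes
#'
#' For each n in `n_grid`, the mean of |rho| over the n best-ranked genes
#' (rank 1 = most significant). Used to ask whether a caller's top
#' differential genes are the purity-associated ones.
#'
#' @param rhos Per-gene correlation values.
#' @param ranks Per-gene ranks (a permutation of 1..n_genes), aligned with
#'   `rhos`.
#' @param n_grid Integer vector of top-n values; entries beyond the gene
#'   count are truncated with a warning.
#' @return A `data.frame` with columns `n` and `mean_abs_rho`.
#' @export
top_n_correlation_curve <- function(rhos, ranks, n_grid) {
  n_genes <- length(rhos)
  if (length(ranks) != n_genes) stop("rhos and ranks misaligned")
  if (any(n_grid > n_genes)) {
    warning("n values beyond the gene count truncated")
    n_grid <- pmin(n_grid, n_genes)
  }
  n_grid <- as.integer(n_grid)
  if (any(n_grid < 1L)) stop("n values must be positive")
  cum <- cumsum(abs(rhos)[order(ranks)])
  data.frame(n = n_grid, mean_abs_rho = cum[n_grid] / n_grid,
             row.names = NULL)
}

#' Write a purity-correlation report
#'
#' One row per gene: gene_id, rho, rho_shuffled (if present), statistic and
#' decile group (if provided).
#'
#' @param report A [purity_correlation()] result, optionally augmented with
#'   `statistic` and `decile` columns.
#' @param path Output TSV path.
#' @export
write_correlation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
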