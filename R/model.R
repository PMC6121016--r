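#' Build the purity design matrix
#'
#' The design for the purity-weighted linear model has an intercept column of
#' ones and a purity column that is 0 for normal samples and the tumor purity
#' \eqn{\lambda_s \in (0, 1]} for tumor samples (normal rows first). Under the
#' mixture model \eqn{Y'_{is} = (1-\lambda_s) X_{is} + \lambda_s Y_{is}}, the
#' observed tumor mean is \eqn{m_i + \lambda_s \mu_i}, so the purity-column
#' coefficient is the pure-tumor effect \eqn{\mu_i} and the intercept is the
#' normal mean \eqn{m_i}.
#'
#' Group sizes of at least 3 are required on each side because the group-wise
#' residual variances use \eqn{n - 2} denominators.
#'
#' @param n_normal Number of normal samples.
#' @param purities Numeric vector of tumor purities, each in (0, 1], one per
#'   tumor sample. A purity of 0 is rejected: such a sample carries no tumor
#'   signal and makes the effect column degenerate.
#' @return An object of class `dectp_design`: a list with elements `W`
#'   (the (n0+n1) x 2 matrix), `n_normal`, `n_tumor`, and `purities`.
#' @examples
#' design <- build_design_matrix(3, c(0.4, 0.6, 0.9))
#' design$W
#' @export
build_design_matrix <- function(n_normal, purities) {
  n_normal <- as.integer(n_normal)
  purities <- as.numeric(purities)
  n_tumor <- length(purities)
  if (anyNA(purities)) stop("purities contain missing values")
  if (any(purities <= 0 | purities > 1)) {
    stop("tumor purities must lie in (0, 1]")
  }
  if (n_normal < 3L || n_tumor < 3L) {
    stop("need at least 3 samples per group (n - 2 variance denominators)")
  }
  W <- cbind(intercept = rep(1, n_normal + n_tumor),
             purity = c(rep(0, n_normal), purities))
  structure(list(W = W, n_normal = n_normal, n_tumor = n_tumor,
                 purities = purities),
            class = "dectp_design")
}

# Hat-type matrix H = (W'W)^{-1} W' and the constants reused across genes.
design_hat <- function(design) {
  W <- design$W
  H <- solve(crossprod(W), t(W))
  normal_idx <- seq_len(design$n_normal)
  tumor_idx <- design$n_normal + seq_len(design$n_tumor)
  list(H = H,
       normal_idx = normal_idx,
       tumor_idx = tumor_idx,
       # sandwich weights: var(beta_hat) = s2n * (H1 H1') + s2t * (H2 H2')
       A_normal = tcrossprod(H[, normal_idx, drop = FALSE]),
       A_tumor = tcrossprod(H[, tumor_idx, drop = FALSE]))
}

#' Least-squares fit of one gene
#'
#' Fits \eqn{Z = W\beta + \epsilon} by ordinary least squares,
#' \eqn{\hat\beta = (W'W)^{-1} W' Z}, and returns the coefficient vector
#' (normal mean, pure-tumor effect) and residuals.
#'
#' @param z Numeric expression vector of length `n_normal + n_tumor`,
#'   normal samples first.
#' @param design A [build_design_matrix()] result.
#' @return List with `beta` (length 2, named) and `residuals`.
#' @export
fit_gene <- function(z, design) {
  stopifnot(inherits(design, "dectp_design"))
  z <- as.numeric(z)
  if (length(z) != nrow(design$W)) {
    stop("expression vector length does not match the design")
  }
  if (any(!is.finite(z))) stop("expression values must be finite")
  beta <- drop(solve(crossprod(design$W), crossprod(design$W, z)))
  names(beta) <- c("normal_mean", "tumor_effect")
  list(beta = beta, residuals = z - drop(design$W %*% beta))
}

#' Group-wise residual variances
#'
#' Residual variances are estimated separately in the two groups, with the
#' model's \eqn{n - 2} denominators on each side:
#' \eqn{\hat\sigma^2 = \sum_{normal} \hat\epsilon^2 / (n_0 - 2)} and
#' \eqn{\hat\sigma'^2 = \sum_{tumor} \hat\epsilon^2 / (n_1 - 2)}.
#'
#' @param residuals Residual vector from [fit_gene()], normal samples first.
#' @param n_normal,n_tumor Group sizes.
#' @return Named numeric vector `c(sigma2_normal, sigma2_tumor)`.
#' @export
estimate_group_variances <- function(residuals, n_normal, n_tumor) {
  if (n_normal - 2L <= 0L || n_tumor - 2L <= 0L) {
    stop("need at least 3 samples per group (n - 2 variance denominators)")
  }
  if (length(residuals) != n_normal + n_tumor) {
    stop("residual length does not match group sizes")
  }
  r_n <- residuals[seq_len(n_normal)]
  r_t <- residuals[n_normal + seq_len(n_tumor)]
  c(sigma2_normal = sum(r_n^2) / (n_normal - 2),
    sigma2_tumor = sum(r_t^2) / (n_tumor - 2))
}

#' Shrink per-gene variances toward their geometric mean
#'
#' Small-sample per-gene variance estimates are noisy; pulling them toward a
#' cross-gene center stabilizes the Wald denominators. The rule is convex
#' shrinkage on the log scale,
#' \deqn{\log\tilde\sigma^2_i = (1 - w)\,\log\hat\sigma^2_i +
#'   w\,\overline{\log\hat\sigma^2},}
#' so `weight = 0` is the identity and `weight = 1` maps every gene to the
#' group geometric mean. Zero variances are floored at the 1st percentile of
#' the positive variances in the group (or 1e-8 if there are none) before
#' taking logs.
#'
#' @param variances Numeric vector of per-gene variances for one group.
#' @param weight Shrinkage weight in \[0, 1\]; default 0.5.
#' @return Shrunken variance vector of the same length.
#' @examples
#' shrink_variances(c(1, 4), weight = 1) # both at the geometric mean, 2
#' @export
shrink_variances <- function(variances, weight = 0.5) {
  if (length(weight) != 1L || is.na(weight) || weight < 0 || weight > 1) {
    stop("shrinkage weight must be a single value in [0, 1]")
  }
  v <- as.numeric(variances)
  if (any(v < 0, na.rm = TRUE)) stop("variances must be non-negative")
  if (length(v) == 0L) return(v)
  if (weight == 0) {
    names(v) <- names(variances)
    return(v)
  }
  pos <- v[v > 0]
  floor_v <- if (length(pos)) stats::quantile(pos, 0.01, names = FALSE) else 1e-8
  v[v == 0] <- floor_v
  lv <- log(v)
  out <- exp((1 - weight) * lv + weight * mean(lv))
  names(out) <- names(variances)
  out
}

#' Covariance of the coefficient estimate
#'
#' The residuals are heteroscedastic across groups (the tumor mixture inflates
#' tumor-sample variance), so the coefficient covariance is assembled from the
#' two group blocks:
#' \deqn{\mathrm{var}(\hat\beta) = H_1 \Sigma H_1' + H_2 \Sigma' H_2',}
#' where \eqn{H = (W'W)^{-1}W'} is split column-wise into the normal block
#' \eqn{H_1} and tumor block \eqn{H_2}, \eqn{\Sigma = \sigma^2 I_{n_0}} and
#' \eqn{\Sigma' = \sigma'^2 I_{n_1}}.
#'
#' @param design A [build_design_matrix()] result.
#' @param sigma2_normal,sigma2_tumor Group residual variances (possibly
#'   shrunken).
#' @return Symmetric 2 x 2 covariance matrix.
#' @export
beta_covariance <- function(design, sigma2_normal, sigma2_tumor) {
  stopifnot(inherits(design, "dectp_design"))
  if (sigma2_normal < 0 || sigma2_tumor < 0) stop("variances must be non-negative")
  hat <- design_hat(design)
  sigma2_normal * hat$A_normal + sigma2_tumor * hat$A_tumor
}

#' Wald test for the pure-tumor effect
#'
#' Tests \eqn{H_0: \mu_i = 0} with
#' \eqn{t = \hat\beta[2] / \sqrt{\mathrm{var}(\hat\beta)[2,2]}}, referred to a
#' t distribution with `df` = n0 + n1 - 2 degrees of freedom (two-sided).
#'
#' Degenerate variances are resolved deterministically: a zero variance with a
#' zero effect gives `t = 0, p = 1`; a zero variance with a non-zero effect
#' gives an infinite statistic and `p = 0`, with a warning.
#'
#' @param beta Length-2 coefficient vector from [fit_gene()].
#' @param var_beta 2 x 2 covariance from [beta_covariance()].
#' @param df Degrees of freedom.
#' @return List with `t` and `p_value`.
#' @export
wald_test <- function(beta, var_beta, df) {
  effect <- beta[[2L]]
  v <- var_beta[2L, 2L]
  if (v < 0) stop("negative effect variance")
  if (v == 0) {
    if (effect == 0) return(list(t = 0, p_value = 1))
    warning("zero effect variance with non-zero effect; p-value set to 0")
    return(list(t = sign(effect) * Inf, p_value = 0))
  }
  t <- effect / sqrt(v)
  list(t = t, p_value = 2 * stats::pt(-abs(t), df = df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone in p-rank, capped at 1),
#' with input validation.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values of the same length.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential expression with tumor-purity correction
#'
#' Runs the full per-gene pipeline on a normalized expression matrix in two
#' passes: (1) fit every gene by least squares and estimate group-wise
#' residual variances; (2) shrink the pooled variances toward their per-group
#' geometric mean, assemble the heteroscedastic coefficient covariance, and
#' Wald-test the pure-tumor effect, with BH FDR across genes.
#'
#' Tumor samples are the columns named in `purities`; remaining columns are
#' normal. Pass `group` to declare membership explicitly, in which case every
#' tumor sample must have a purity.
#'
#' @param expr Numeric matrix of normalized expression (genes x samples) with
#'   gene rownames and sample colnames.
#' @param purities Named numeric vector of tumor purities in (0, 1]; names are
#'   tumor sample IDs.
#' @param group Optional vector of `"normal"`/`"tumor"` labels, one per column
#'   of `expr`.
#' @param shrink_weight Variance-shrinkage weight in \[0, 1\] (default 0.5);
#'   0 disables shrinkage.
#' @return A `data.frame` with one row per gene, in input gene order:
#'   `gene_id`, `beta_normal_mean`, `beta_tumor_effect`, `sigma2_normal`,
#'   `sigma2_tumor`, `sigma2_normal_shrunk`, `sigma2_tumor_shrunk`, `wald_t`,
#'   `df`, `p_value`, `fdr`, `rank` (rank by FDR, ties broken by p-value then
#'   gene ID).
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 50, n_normal = 10,
#'                                           n_tumor = 10, seed = 1))
#' expr <- cbind(sim$X, sim$Y_prime)
#' res <- run_dectp(expr, sim$true_purities)
#' head(res)
#' @export
run_dectp <- function(expr, purities, group = NULL, shrink_weight = 0.5) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr))) stop("expression matrix needs sample colnames")
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("gene_", seq_len(nrow(expr)))
  }
  if (any(!is.finite(expr))) stop("expression values must be finite")
  if (is.null(names(purities))) stop("purities must be named by tumor sample ID")

  if (is.null(group)) {
    tumor_samples <- intersect(colnames(expr), names(purities))
    normal_samples <- setdiff(colnames(expr), tumor_samples)
  } else {
    group <- check_group(group, ncol(expr))
    tumor_samples <- colnames(expr)[group == "tumor"]
    normal_samples <- colnames(expr)[group == "normal"]
    missing <- setdiff(tumor_samples, names(purities))
    if (length(missing)) {
      stop("tumor sample(s) without a purity value: ",
           paste(missing, collapse = ", "))
    }
  }
  lambda <- purities[tumor_samples]
  design <- build_design_matrix(length(normal_samples), lambda)
  Z <- expr[, c(normal_samples, tumor_samples), drop = FALSE]

  hat <- design_hat(design)
  # pass 1: all genes at once; B is genes x 2, residuals genes x samples
  B <- Z %*% t(hat$H)
  R <- Z - B %*% t(design$W)
  s2n <- rowSums(R[, hat$normal_idx, drop = FALSE]^2) / (design$n_normal - 2)
  s2t <- rowSums(R[, hat$tumor_idx, drop = FALSE]^2) / (design$n_tumor - 2)

  # zap floating-point dust so exactly-degenerate genes (constant rows,
  # perfect fits) take the deterministic zero-variance path
  scale <- pmax(apply(abs(Z), 1L, max), 1)
  tol <- 1e-10 * scale
  B[abs(B[, 2L]) < tol, 2L] <- 0
  s2n[s2n < tol^2] <- 0
  s2t[s2t < tol^2] <- 0

  # pass 2: pool across genes, shrink, test
  s2n_sh <- shrink_variances(s2n, shrink_weight)
  s2t_sh <- shrink_variances(s2t, shrink_weight)
  v22 <- s2n_sh * hat$A_normal[2L, 2L] + s2t_sh * hat$A_tumor[2L, 2L]
  df <- design$n_normal + design$n_tumor - 2L

  effect <- B[, 2L]
  t_stat <- ifelse(v22 > 0, effect / sqrt(v22),
                   ifelse(effect == 0, 0, sign(effect) * Inf))
  if (any(v22 == 0 & effect != 0)) {
    warning("zero effect variance with non-zero effect for some genes")
  }
  p <- ifelse(is.infinite(t_stat), 0, 2 * stats::pt(-abs(t_stat), df = df))
  fdr <- benjamini_hochberg(p)

  res <- data.frame(
    gene_id = rownames(Z),
    beta_normal_mean = B[, 1L],
    beta_tumor_effect = effect,
    sigma2_normal = s2n,
    sigma2_tumor = s2t,
    sigma2_normal_shrunk = s2n_sh,
    sigma2_tumor_shrunk = s2t_sh,
    wald_t = t_stat,
    df = df,
    p_value = p,
    fdr = fdr,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  res$rank <- rank_results(res)
  res
}

# Rank by FDR, ties broken by raw p then gene_id; a permutation of 1..n.
rank_results <- function(res) {
  order(order(res$fdr, res$p_value, res$gene_id))
}

#' Write a differential-expression result table
#'
#' Tab-separated, one header row, full floating precision.
#'
#' @param res Result `data.frame` from [run_dectp()].
#' @param path Output file path.
#' @export
write_results <- function(res, path) {
  out <- res
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
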