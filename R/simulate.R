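#' Configuration for purity-confounded simulations
#'
#' Describes one simulated study: per-gene Gaussian expression in pure normal
#' and pure tumor cells, tumor purities drawn uniformly, observed tumor
#' profiles formed by cell-wise linear mixing, and ground-truth DEG labels by
#' thresholding the pure mean difference.
#'
#' Generative defaults (all configurable): pure-normal means
#' \eqn{m_i \sim N(8, 2^2)} and standard deviations
#' \eqn{\sigma_i = |N(0,1)| + 0.25} (drawn independently for the tumor side),
#' an effect \eqn{m'_i - m_i} that is 0 with probability
#' `1 - nonnull_fraction` and \eqn{N(0, \mathrm{effect\_sd}^2)} otherwise.
#' With `nonnull_fraction = 0.55` and `effect_sd = 2`, thresholds
#' `delta` = 1, 2, 3 label roughly 34%, 17%, and 7% of genes as true DEGs.
#'
#' @param n_genes Number of genes.
#' @param n_normal,n_tumor Samples per group (each at least 3).
#' @param delta Truth threshold: gene i is a true DEG iff
#'   \eqn{|m_i - m'_i| \ge \delta}.
#' @param purity_range Support of the uniform purity distribution,
#'   default `c(0.05, 0.95)`.
#' @param purity_noise_sd Standard deviation of Gaussian noise added to the
#'   true purities to form the reported purities (default 0, i.e. purities
#'   known exactly); noisy values are clipped into `purity_range`.
#' @param nonnull_fraction Fraction of genes with a non-zero effect.
#' @param effect_sd Standard deviation of the non-null effect distribution.
#' @param effect_fixed If non-`NULL`, every gene gets exactly this effect
#'   \eqn{m'_i - m_i} (degenerate effect distribution; overrides
#'   `nonnull_fraction`/`effect_sd`). Useful for calibration and
#'   effect-recovery studies.
#' @param sigma_fixed If non-`NULL`, every gene's pure-normal and pure-tumor
#'   standard deviation is exactly this value instead of a half-normal draw.
#' @param base_mean_mean,base_mean_sd Mean and sd of the pure-normal mean
#'   distribution.
#' @param sigma_floor Lower bound added to the half-normal per-gene sd draw.
#' @param seed Integer seed; mandatory, drives every random stream.
#' @return An object of class `dectp_sim_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 2000, n_normal = 50, n_tumor = 50,
                              delta = 2, purity_range = c(0.05, 0.95),
                              purity_noise_sd = 0, nonnull_fraction = 0.55,
                              effect_sd = 2, effect_fixed = NULL,
                              sigma_fixed = NULL, base_mean_mean = 8,
                              base_mean_sd = 2, sigma_floor = 0.25,
                              seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is required for reproducible simulation")
  }
  if (n_genes < 1L || n_normal < 3L || n_tumor < 3L) {
    stop("need n_genes >= 1 and at least 3 samples per group")
  }
  if (length(purity_range) != 2L || purity_range[1L] <= 0 ||
      purity_range[2L] >= 1 || purity_range[1L] > purity_range[2L]) {
    stop("purity_range must satisfy 0 < low <= high < 1")
  }
  if (purity_noise_sd < 0) stop("purity_noise_sd must be non-negative")
  if (nonnull_fraction < 0 || nonnull_fraction > 1) {
    stop("nonnull_fraction must lie in [0, 1]")
  }
  if (!is.null(sigma_fixed) && sigma_fixed <= 0) {
    stop("sigma_fixed must be positive")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_normal = as.integer(n_normal),
                 n_tumor = as.integer(n_tumor),
                 delta = delta, purity_range = purity_range,
                 purity_noise_sd = purity_noise_sd,
                 nonnull_fraction = nonnull_fraction,
                 effect_sd = effect_sd,
                 effect_fixed = effect_fixed,
                 sigma_fixed = sigma_fixed,
                 base_mean_mean = base_mean_mean,
                 base_mean_sd = base_mean_sd,
                 sigma_floor = sigma_floor,
                 seed = as.integer(seed)),
            class = "dectp_sim_config")
}

#' Draw per-gene generative parameters
#'
#' Draws, for each gene, the pure-normal mean and variance
#' \eqn{(m_i, \sigma_i^2)}, the pure-tumor mean and variance
#' \eqn{(m'_i, \sigma'^2_i)}, and the true-DEG label
#' \eqn{|m_i - m'_i| \ge \delta} (inclusive).
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` with columns `gene_id`, `m`, `sigma2`, `m_prime`,
#'   `sigma2_prime`, `is_deg`.
#' @export
sample_gene_params <- function(config) {
  stopifnot(inherits(config, "dectp_sim_config"))
  n <- config$n_genes
  with_seed(config$seed, {
    m <- stats::rnorm(n, config$base_mean_mean, config$base_mean_sd)
    sigma <- abs(stats::rnorm(n)) + config$sigma_floor
    sigma_prime <- abs(stats::rnorm(n)) + config$sigma_floor
    nonnull <- stats::runif(n) < config$nonnull_fraction
    effect <- ifelse(nonnull, stats::rnorm(n, 0, config$effect_sd), 0)
  })
  if (!is.null(config$sigma_fixed)) {
    sigma <- rep(config$sigma_fixed, n)
    sigma_prime <- rep(config$sigma_fixed, n)
  }
  if (!is.null(config$effect_fixed)) effect <- rep(config$effect_fixed, n)
  data.frame(gene_id = sprintf("gene_%05d", seq_len(n)),
             m = m, sigma2 = sigma^2,
             m_prime = m + effect, sigma2_prime = sigma_prime^2,
             is_deg = abs(effect) >= config$delta,
             stringsAsFactors = FALSE)
}

#' Simulate a purity-confounded expression dataset
#'
#' Generates pure-normal profiles \eqn{X_{ij} \sim N(m_i, \sigma_i^2)},
#' pure-tumor profiles \eqn{Y_{ij} \sim N(m'_i, \sigma'^2_i)}, tumor purities
#' \eqn{\lambda_j \sim U(\mathrm{purity\_range})}, and the observed tumor
#' profiles by cell-wise mixing
#' \deqn{Y'_{ij} = \lambda_j Y_{ij} + (1 - \lambda_j) X_{ij}.}
#' Reported purities add Gaussian estimation noise
#' (sd `purity_noise_sd`), clipped into `purity_range`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `dectp_simulation`: list with matrices `X`
#'   (genes x normal samples, the observed normal group), `Y` (pure-tumor
#'   profiles), `X_mix` (the pure-normal component of each tumor sample) and
#'   `Y_prime` (observed mixed tumor profiles), all genes x tumor samples
#'   except `X`; vectors `true_purities` and `reported_purities` (named by
#'   tumor sample); `truth` (the [sample_gene_params()] frame); and `config`.
#'   The identity `Y_prime == lambda * Y + (1 - lambda) * X_mix` holds exactly
#'   for every cell.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "dectp_sim_config"))
  params <- sample_gene_params(config)
  n <- config$n_genes
  normal_ids <- sprintf("normal_%03d", seq_len(config$n_normal))
  tumor_ids <- sprintf("tumor_%03d", seq_len(config$n_tumor))

  with_seed(config$seed + 1L, {
    X <- matrix(stats::rnorm(n * config$n_normal, mean = params$m,
                             sd = sqrt(params$sigma2)),
                nrow = n, dimnames = list(params$gene_id, normal_ids))
    # each tumor sample carries its own normal-cell contamination profile
    X_mix <- matrix(stats::rnorm(n * config$n_tumor, mean = params$m,
                                 sd = sqrt(params$sigma2)),
                    nrow = n, dimnames = list(params$gene_id, tumor_ids))
    Y <- matrix(stats::rnorm(n * config$n_tumor, mean = params$m_prime,
                             sd = sqrt(params$sigma2_prime)),
                nrow = n, dimnames = list(params$gene_id, tumor_ids))
    lambda <- stats::runif(config$n_tumor, config$purity_range[1L],
                           config$purity_range[2L])
    noise <- if (config$purity_noise_sd > 0) {
      stats::rnorm(config$n_tumor, 0, config$purity_noise_sd)
    } else rep(0, config$n_tumor)
  })
  names(lambda) <- tumor_ids
  reported <- pmin(pmax(lambda + noise, config$purity_range[1L]),
                   config$purity_range[2L])
  names(reported) <- tumor_ids

  Y_prime <- sweep(Y, 2, lambda, `*`) + sweep(X_mix, 2, 1 - lambda, `*`)

  structure(list(X = X, Y = Y, X_mix = X_mix, Y_prime = Y_prime,
                 true_purities = lambda, reported_purities = reported,
                 truth = params, config = config),
            class = "dectp_simulation")
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Write a simulated dataset to a directory
#'
#' Writes `expression.tsv` (normal plus mixed-tumor columns), `purity.tsv`
#' (sample, true and reported purity), `truth.tsv` (gene_id, is_deg, m,
#' m_prime), and `config.json`.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "dectp_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cbind(sim$X, sim$Y_prime),
                   file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample = names(sim$true_purities),
               true_purity = sprintf("%.17g", sim$true_purities),
               reported_purity = sprintf("%.17g", sim$reported_purities),
               stringsAsFactors = FALSE),
    file.path(dir, "purity.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    sim$truth[, c("gene_id", "is_deg", "m", "m_prime")],
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
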