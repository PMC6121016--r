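# Independent brute-force references used across the suite. These stay
# deliberately naive (loops, enumeration, lm()) so they cannot share a code
# path with the implementation they check.

# Normal-equation solve through R's QR-based lm(), coefficient-only.
oracle_ols <- function(z, W) {
  unname(stats::coef(stats::lm(z ~ W - 1)))
}

# BH step-up by the textbook definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# AUC by exhaustive pair enumeration, ties at half credit.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Pooled two-sample t by the textbook formula, tumor minus normal.
oracle_pooled_t <- function(x, y) {
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Small helper: one simulated dataset under fixed defaults.
tiny_simulation <- function(seed, n_genes = 200, n_normal = 10, n_tumor = 10,
                            ...) {
  simulate_dataset(simulation_config(n_genes = n_genes, n_normal = n_normal,
                                     n_tumor = n_tumor, seed = seed, ...))
}
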