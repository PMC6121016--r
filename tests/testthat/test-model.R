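test_that("design matrix has intercept and purity columns, normal rows first", {
  d <- build_design_matrix(3, c(0.5, 0.8, 1))
  expect_equal(unname(d$W[, 1]), rep(1, 6))
  expect_equal(unname(d$W[, 2]), c(0, 0, 0, 0.5, 0.8, 1))
  expect_equal(d$n_normal, 3L)
  expect_equal(d$n_tumor, 3L)

  # purities of 1 make the second column the tumor indicator
  d1 <- build_design_matrix(4, rep(1, 3))
  expect_equal(unname(d1$W[, 2]), c(0, 0, 0, 0, 1, 1, 1))

  expect_error(build_design_matrix(3, c(0.5, 1.2, 0.7)), "\\(0, 1\\]")
  expect_error(build_design_matrix(3, c(0.5, 0, 0.7)), "\\(0, 1\\]")
  expect_error(build_design_matrix(2, c(0.5, 0.6, 0.7)), "at least 3")
  expect_error(build_design_matrix(5, c(0.5, 0.6)), "at least 3")
})

test_that("least-squares fit reproduces hand-solved cases", {
  # lambda = 1: intercept = normal mean, effect = tumor mean - normal mean
  d <- build_design_matrix(3, rep(1, 3))
  fit <- fit_gene(c(0, 1, 2, 3, 4, 5), d)
  expect_equal(unname(fit$beta), c(1, 3))

  # exact fit through mixed purities
  d2 <- build_design_matrix(3, c(0.5, 1, 0.25))
  z <- c(0, 0, 0, 1, 2, 0.5)
  fit2 <- fit_gene(z, d2)
  expect_equal(unname(fit2$beta), c(0, 2))
  expect_equal(fit2$residuals, rep(0, 6))

  fit0 <- fit_gene(rep(0, 6), d2)
  expect_equal(unname(fit0$beta), c(0, 0))
  expect_equal(fit0$residuals, rep(0, 6))
})

test_that("fit agrees with an lm() oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n0 <- sample(3:10, 1)
    n1 <- sample(3:10, 1)
    lambda <- runif(n1, 0.05, 0.95)
    d <- build_design_matrix(n0, lambda)
    z <- rnorm(n0 + n1, 5, 2)
    fit <- fit_gene(z, d)
    expect_equal(unname(fit$beta), oracle_ols(z, d$W), tolerance = 1e-10)
  }
})

test_that("group variances use the n - 2 denominators", {
  v <- estimate_group_variances(c(-1, 0, 1, -1, 0, 1), 3, 3)
  expect_equal(unname(v), c(2, 2))
  expect_equal(unname(estimate_group_variances(rep(0, 8), 4, 4)), c(0, 0))
  expect_equal(unname(estimate_group_variances(c(1, 1, 1, 2, 0, 0, 0, 0), 4, 4)),
               c(7 / 2, 0))
  expect_error(estimate_group_variances(rep(0, 5), 2, 3), "at least 3")
})

test_that("variance shrinkage interpolates to the geometric mean on log scale", {
  expect_equal(shrink_variances(c(1, 4), weight = 1), c(2, 2))
  expect_equal(shrink_variances(c(1, 4), weight = 0), c(1, 4))
  expect_equal(shrink_variances(c(3, 3, 3), weight = 0.7), c(3, 3, 3))

  v <- c(0.5, 2, 8)
  w <- 0.3
  expect_equal(shrink_variances(v, w),
               exp((1 - w) * log(v) + w * mean(log(v))))

  # zero variances floored before log, never propagated as -Inf
  out <- shrink_variances(c(0, 1, 4), weight = 0.5)
  expect_true(all(is.finite(out) & out > 0))
  expect_error(shrink_variances(c(-1, 2)), "non-negative")
  expect_error(shrink_variances(c(1, 2), weight = 1.5), "\\[0, 1\\]")
})

test_that("coefficient covariance matches closed forms", {
  d <- build_design_matrix(4, rep(1, 5))
  v <- beta_covariance(d, 2, 3)
  # at lambda = 1 the effect variance is s2n/n0 + s2t/n1
  expect_equal(v[2, 2], 2 / 4 + 3 / 5, tolerance = 1e-12)

  d2 <- build_design_matrix(3, c(0.3, 0.6, 0.9))
  expect_equal(beta_covariance(d2, 0, 0), matrix(0, 2, 2),
               ignore_attr = TRUE)
  # homoscedastic case collapses to s * (W'W)^-1
  s <- 1.7
  expect_equal(beta_covariance(d2, s, s), s * solve(crossprod(d2$W)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # brute-force sandwich oracle on a random design
  set.seed(5)
  lam <- runif(4, 0.05, 0.95)
  d3 <- build_design_matrix(5, lam)
  H <- solve(crossprod(d3$W)) %*% t(d3$W)
  Sigma <- diag(c(rep(1.3, 5), rep(2.6, 4)))
  expect_equal(beta_covariance(d3, 1.3, 2.6), H %*% Sigma %*% t(H),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Wald test handles ordinary and degenerate variance cases", {
  expect_equal(wald_test(c(1, 0), diag(c(1, 2)), df = 8),
               list(t = 0, p_value = 1))
  res <- wald_test(c(1, 3), matrix(c(1, 0, 0, 2.25), 2), df = 10)
  expect_equal(res$t, 2)
  expect_equal(res$p_value, 2 * pt(-2, 10))

  expect_equal(wald_test(c(5, 0), matrix(0, 2, 2), df = 4),
               list(t = 0, p_value = 1))
  expect_warning(res0 <- wald_test(c(0, 2), matrix(0, 2, 2), df = 4),
                 "zero effect variance")
  expect_equal(res0$p_value, 0)
})

test_that("|t| is strictly increasing in the absolute effect", {
  v <- matrix(c(1, 0.2, 0.2, 0.9), 2)
  effects <- seq(0.1, 5, length.out = 25)
  ts <- vapply(effects, function(e) abs(wald_test(c(0, e), v, 10)$t),
               numeric(1))
  expect_true(all(diff(ts) > 0))
  expect_equal(vapply(effects, function(e) wald_test(c(0, -e), v, 10)$t,
                      numeric(1)),
               -vapply(effects, function(e) wald_test(c(0, e), v, 10)$t,
                       numeric(1)))
})

test_that("BH adjustment matches the step-up oracle and is order-invariant", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^2
    expect_equal(benjamini_hochberg(p), oracle_bh(p))
    perm <- sample(seq_along(p))
    expect_equal(benjamini_hochberg(p[perm]), benjamini_hochberg(p)[perm])
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_dectp reproduces the single-gene hand pipeline", {
  expr <- matrix(c(0, 1, 2, 3, 4, 5), nrow = 1,
                 dimnames = list("g1", c(paste0("n", 1:3), paste0("t", 1:3))))
  purities <- setNames(rep(1, 3), paste0("t", 1:3))
  res <- run_dectp(expr, purities, shrink_weight = 0)
  expect_equal(res$beta_normal_mean, 1)
  expect_equal(res$beta_tumor_effect, 3)
  expect_equal(res$sigma2_normal, 2)
  expect_equal(res$sigma2_tumor, 2)
  expect_equal(res$wald_t, 3 / sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-3 / sqrt(4 / 3), 4))
})

test_that("run_dectp handles degenerate genes and preserves gene order", {
  samples <- c(paste0("n", 1:3), paste0("t", 1:3))
  purities <- setNames(c(0.3, 0.6, 0.9), paste0("t", 1:3))
  expr <- rbind(flat = rep(2, 6),
                g2 = c(0, 1, 2, 1, 3, 2),
                g1 = c(5, 4, 6, 2, 1, 3))
  colnames(expr) <- samples
  res <- run_dectp(expr, purities, shrink_weight = 0)
  expect_equal(res$gene_id, c("flat", "g2", "g1"))
  expect_equal(res$p_value[1], 1)
  expect_equal(res$wald_t[1], 0)
  expect_true(all(sort(res$rank) == 1:3))

  # permuting input rows permutes output rows identically
  perm <- c(3, 1, 2)
  res2 <- run_dectp(expr[perm, ], purities, shrink_weight = 0)
  expect_equal(res2$gene_id, res$gene_id[perm])
  expect_equal(res2$p_value, res$p_value[perm])
})

test_that("run_dectp validates purity coverage and names offenders", {
  expr <- matrix(rnorm(24), 4, 6,
                 dimnames = list(paste0("g", 1:4),
                                 c(paste0("n", 1:3), paste0("t", 1:3))))
  purities <- setNames(c(0.4, 0.5), c("t1", "t2"))
  group <- rep(c("normal", "tumor"), each = 3)
  expect_error(run_dectp(expr, purities, group = group), "t3")
})

test_that("result table writes at full precision and round-trips", {
  sim <- tiny_simulation(21, n_genes = 20)
  res <- run_dectp(cbind(sim$X, sim$Y_prime), sim$true_purities)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- utils::read.delim(path)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-15)
  expect_equal(back$wald_t, res$wald_t, tolerance = 1e-15)
  expect_equal(back$gene_id, res$gene_id)
})
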