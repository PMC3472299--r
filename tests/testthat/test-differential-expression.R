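two_group_design <- function() {
  data.frame(array_id = paste0("a", 1:6),
             condition = rep(c("WT", "CA1"), each = 3),
             replicate = rep(1:3, 2), stringsAsFactors = FALSE)
}

test_that("group-means fit matches the hand-worked pooled variance", {
  d <- two_group_design()
  expr <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                 dimnames = list("g1", d$array_id))
  fit <- fit_group_means(expr, d)
  expect_equal(unname(fit$group_means["g1", c("WT", "CA1")]), c(2, 5))
  expect_equal(unname(fit$s2), 1.0) # (2 + 2) / 4
  expect_equal(fit$df, 4L)

  # identical replicates give zero residual variance
  same <- matrix(rep(c(1, 7), each = 3), 1, dimnames = list("g1", d$array_id))
  expect_equal(unname(fit_group_means(same, d)$s2), 0)

  # permutation invariance
  perm <- sample(ncol(expr))
  fit2 <- fit_group_means(expr[, perm, drop = FALSE], d)
  expect_equal(fit2$group_means, fit$group_means)
  expect_equal(fit2$s2, fit$s2)

  expect_error(fit_group_means(matrix(1, 1, 2,
                                      dimnames = list("g", c("zz", "a1"))), d),
               class = "uprflow_invalid")
})

test_that("prior estimation recovers hyperparameters and handles edge cases", {
  # equal variances: no dispersion, infinite prior df, common variance kept
  pr <- estimate_prior(rep(0.25, 50), 8)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.25, tolerance = 1e-12)

  # Monte-Carlo recovery under the full hierarchical model
  set.seed(11)
  d0 <- 4; s0 <- 0.05; n <- 20000; df <- 8
  s2 <- (s0 * d0 / rchisq(n, d0)) * rchisq(n, df) / df
  pr <- estimate_prior(s2, df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.10)

  expect_error(estimate_prior(rep(0, 20), 8), class = "uprflow_degenerate")
  expect_error(estimate_prior(c(0.1, 0.2), 8), class = "uprflow_invalid")

  # limma's empirical-Bayes fit as an independent cross-check
  skip_if_not_installed("limma")
  sq <- limma::squeezeVar(s2, df = df)
  expect_equal(pr$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(pr$s0_sq, sq$var.prior, tolerance = 0.05)
})

test_that("moderated t matches closed-form arithmetic and its limits", {
  d <- two_group_design()
  fit <- structure(list(
    group_means = matrix(c(2, 1), 1, dimnames = list("g1", c("CA1", "WT"))),
    s2 = c(g1 = 0.5), df = 8L, n_per_group = c(CA1 = 3L, WT = 3L),
    genes = "g1"), class = "linear_fit")
  prior <- list(d0 = 4, s0_sq = 0.25)
  res <- moderated_t(fit, prior, c("CA1", "WT"))
  expect_equal(res$log2fc, 1.0)
  s2_post <- (4 * 0.25 + 8 * 0.5) / 12
  expect_equal(s2_post, 5 / 12)
  expect_equal(res$t_mod, 1 / sqrt(s2_post * (2 / 3)), tolerance = 1e-12)
  expect_equal(res$t_mod, 1.897, tolerance = 1e-3)
  expect_equal(res$p_value, 2 * pt(-abs(res$t_mod), df = 12), tolerance = 1e-12)

  # d0 = 0: ordinary pooled two-sample t
  plain <- moderated_t(fit, list(d0 = 0, s0_sq = 1), c("CA1", "WT"))
  expect_equal(plain$t_mod, 1 / sqrt(0.5 * (2 / 3)), tolerance = 1e-12)

  # d0 = Inf: posterior variance pinned at s0^2, normal reference
  inf <- moderated_t(fit, list(d0 = Inf, s0_sq = 0.25), c("CA1", "WT"))
  expect_equal(inf$t_mod, 1 / sqrt(0.25 * (2 / 3)), tolerance = 1e-12)
  expect_equal(inf$p_value, 2 * pnorm(-abs(inf$t_mod)), tolerance = 1e-12)

  # zero mean difference
  fit$group_means[1, ] <- c(3, 3)
  null <- moderated_t(fit, prior, c("CA1", "WT"))
  expect_equal(null$t_mod, 0)
  expect_equal(null$p_value, 1)

  # zero posterior variance flagged degenerate, not p = 0
  fit$group_means[1, ] <- c(2, 1)
  fit$s2 <- c(g1 = 0)
  degen <- moderated_t(fit, list(d0 = 4, s0_sq = 0), c("CA1", "WT"))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p_value))
})

test_that("moderated t agrees with limma on simulated data", {
  skip_if_not_installed("limma")
  d <- default_design()
  sim <- sim_expression(d, n_genes = 300, n_de = 30, effect = 1.5, sd = 0.4,
                        seed = 21, both_signs = TRUE)
  fit <- fit_group_means(sim$expr, d)
  prior <- estimate_prior(fit$s2, fit$df)
  mine <- moderated_t(fit, prior, c("CA1", "WT"))

  design_mat <- model.matrix(~ 0 + factor(d$condition, levels = unique(d$condition)))
  colnames(design_mat) <- unique(d$condition)
  lf <- limma::lmFit(sim$expr, design_mat)
  cf <- limma::contrasts.fit(lf, limma::makeContrasts(CA1 - WT, levels = design_mat))
  eb <- limma::eBayes(cf)
  expect_equal(mine$t_mod, unname(eb$t[, 1]), tolerance = 1e-4)
  expect_equal(mine$p_value, unname(eb$p.value[, 1]), tolerance = 1e-4)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "uprflow_invalid")

  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # permutation equivariance and monotonicity in sorted-p order
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= min(p) - 1e-12 & q <= 1))
  }
})

test_that("signed linear fold change keeps |FC| >= 1 with the minus convention", {
  expect_equal(signed_linear_fold_change(c(1, -1, 0, 2, -2)),
               c(2, -2, 1, 4, -4))
  x <- seq(-5, 5, by = 0.25)
  expect_true(all(abs(signed_linear_fold_change(x)) >= 1))
})

test_that("classification is strict at the threshold and shrinkage is bounded", {
  tab <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(2, -1, 0.5),
                    t_mod = c(5, -4, 1), p_value = c(1e-6, 1e-5, 0.3),
                    degenerate = FALSE)
  tab$q_value <- c(0.005, 0.004, 0.3) # g1 exactly at threshold: stays 0
  out <- classify_de(tab, q_threshold = 0.005)
  expect_equal(out$direction, c(0, -1, 0))
  expect_equal(out$fold_change_linear, c(4, -2, sqrt(2)))

  # moderation shrinks: posterior variance between s_g^2 and s0^2
  s2 <- c(0.01, 0.1, 1, 10); d0 <- 4; s0 <- 0.25; df <- 8
  post <- (d0 * s0 + df * s2) / (d0 + df)
  expect_true(all(post >= pmin(s2, s0) & post <= pmax(s2, s0)))
})

test_that("planted effects are recovered and the all-null model stays quiet", {
  d <- default_design()
  sim <- sim_expression(d, n_genes = 600, n_de = 60, effect = 2, sd = 0.3,
                        seed = 31)
  res <- de_analysis(sim$expr, d)
  up1 <- res$tables[["CA1-WT"]]
  called <- up1$gene[up1$direction == 1]
  expect_gte(sum(sim$de_genes %in% called), 0.95 * length(sim$de_genes))

  null <- sim_expression(d, n_genes = 600, n_de = 0, effect = 0, sd = 0.3,
                         seed = 32)
  res0 <- de_analysis(null$expr, d)
  expect_lte(sum(res0$summary$total), 2) # FDR-controlled: ~0 false calls
})
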