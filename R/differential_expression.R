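# Moderated-t differential expression for the contrasts (CA1 - WT,
# CA2 - WT, CA3 - WT): one-way group-means fit with pooled residual
# variance, empirical-Bayes shrinkage of gene-wise variances toward a
# scaled inverse-chi-square prior, Benjamini-Hochberg FDR, and the signed
# linear fold-change reporting convention.

#' Fit per-gene group means and pooled residual variance
#'
#' One-way layout: per gene, the mean log2 expression of each condition's
#' replicates, and the pooled residual variance
#' `s_g^2 = sum(residuals^2) / d` with `d = n_arrays - n_conditions`
#' degrees of freedom (8 for the default 12-array, 4-condition design).
#'
#' @param expr log2 expression matrix (genes x arrays).
#' @param design design table; every column of `expr` must appear.
#' @return object of class `linear_fit`: `group_means` (genes x conditions),
#'   `s2` (residual variances), `df` (residual df), `n_per_group`.
#' @export
fit_group_means <- function(expr, design) {
  check_design(design)
  expr <- as.matrix(expr)
  missing <- setdiff(colnames(expr), design$array_id)
  if (length(missing)) stop_invalid("arrays missing from design: ",
                                    paste(missing, collapse = ", "))
  cond <- design$condition[match(colnames(expr), design$array_id)]
  conditions <- unique(design$condition[design$array_id %in% colnames(expr)])
  if (length(conditions) < 2L) stop_invalid("need >= 2 conditions")

  n_per_group <- stats::setNames(
    vapply(conditions, function(cc) sum(cond == cc), integer(1)), conditions)
  means <- vapply(conditions, function(cc) {
    rowMeans(expr[, cond == cc, drop = FALSE])
  }, numeric(nrow(expr)))
  if (nrow(expr) == 1L) means <- matrix(means, nrow = 1L,
                                        dimnames = list(rownames(expr), conditions))
  colnames(means) <- conditions

  fitted <- means[, cond, drop = FALSE]
  resid <- expr - fitted
  df <- ncol(expr) - length(conditions)
  if (df < 1L) stop_invalid("no residual degrees of freedom")
  s2 <- rowSums(resid^2) / df

  structure(list(group_means = means, s2 = s2, df = df,
                 n_per_group = n_per_group, genes = rownames(expr)),
            class = "linear_fit")
}

# Invert the trigamma function: find x > 0 with trigamma(x) = y.
# Newton iteration on the log scale with a bisection fallback.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100L) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y)) # trigamma(x) ~ 1/x^2 for x -> 0
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x_new <- x + dif
    if (x_new <= 0) { x_new <- x / 2 } # fallback keeps iterate positive
    if (abs(x_new - x) < tol * max(1, x)) return(x_new)
    x <- x_new
  }
  x
}

#' Estimate the variance prior (d0, s0^2) by method of moments
#'
#' Under the hierarchical model `s_g^2 ~ s0^2 * F(d, d0)`, the log variances
#' `z = ln s_g^2` satisfy `var(z) = trigamma(d/2) + trigamma(d0/2)` and
#' `E z = ln s0^2 + digamma(d/2) - digamma(d0/2) + ln(d0/d)`. Solving the
#' first for `d0` (infinite when `var(z) <= trigamma(d/2)`) and the second
#' for `s0^2` gives the empirical-Bayes hyperparameters used for shrinkage.
#' Variances of exactly zero enter through a small floor (1e-8 on the log2
#' scale) so `ln s^2` stays finite.
#'
#' @param s2 vector of >= 10 residual variances.
#' @param df residual degrees of freedom of each `s2`.
#' @return object of class `prior_estimate`: `d0` (possibly `Inf`), `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  if (length(s2) < 10L) stop_invalid("need >= 10 genes to estimate the prior")
  df <- check_count(df, "df")
  if (all(s2 == 0)) stop_degenerate("all residual variances are zero")
  z <- log(pmax(s2, 1e-8))
  vz <- stats::var(z)
  mz <- mean(z)
  rhs <- vz - trigamma(df / 2)
  if (vz == 0) {
    d0 <- Inf
    s0_sq <- exp(mz) # no dispersion observed: the common variance itself
  } else if (rhs <= 0) {
    d0 <- Inf
    s0_sq <- exp(mz - digamma(df / 2) + log(df / 2))
  } else {
    half_d0 <- trigamma_inverse(rhs)
    d0 <- min(2 * half_d0, 1e7)
    s0_sq <- exp(mz - digamma(df / 2) + digamma(d0 / 2) - log(d0 / df))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "prior_estimate")
}

#' Moderated t-statistic for one contrast
#'
#' Shrinks each gene's variance toward the prior,
#' `s_tilde^2 = (d0 s0^2 + d s_g^2) / (d0 + d)` (equal to `s0^2` when
#' `d0 = Inf`), and tests the mean difference of the two conditions on
#' `d0 + d` degrees of freedom (standard normal when infinite):
#' `t = (mean_A - mean_B) / sqrt(s_tilde^2 (1/n_A + 1/n_B))`.
#' Genes with zero posterior variance are flagged degenerate (`NA`
#' statistics) rather than given p = 0.
#'
#' @param fit a `linear_fit` from [fit_group_means()].
#' @param prior a `prior_estimate` (or list with `d0`, `s0_sq`).
#' @param contrast character pair `c(A, B)`; the effect reported is A - B.
#' @return data.frame with `gene`, `log2fc`, `t_mod`, `p_value`, `degenerate`.
#' @export
moderated_t <- function(fit, prior, contrast) {
  if (!inherits(fit, "linear_fit")) stop_invalid("fit must come from fit_group_means")
  if (length(contrast) != 2L || !all(contrast %in% colnames(fit$group_means))) {
    stop_invalid("contrast conditions not in fit: ", paste(contrast, collapse = ", "))
  }
  d0 <- prior$d0; s0 <- prior$s0_sq
  d <- fit$df
  s2_post <- if (is.infinite(d0)) rep(s0, length(fit$s2)) else
    (d0 * s0 + d * fit$s2) / (d0 + d)
  nA <- fit$n_per_group[[contrast[1L]]]
  nB <- fit$n_per_group[[contrast[2L]]]
  delta <- fit$group_means[, contrast[1L]] - fit$group_means[, contrast[2L]]
  degenerate <- s2_post <= 0
  t_mod <- ifelse(degenerate, NA_real_,
                  delta / sqrt(s2_post * (1 / nA + 1 / nB)))
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(gene = fit$genes %||% seq_along(delta), log2fc = unname(delta),
             t_mod = unname(t_mod), p_value = unname(p),
             degenerate = unname(degenerate), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1,
#' mapped back to the input order (ties share a q-value).
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed, passed through).
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_invalid("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Signed linear fold change
#'
#' The reporting convention for linear-scale fold changes: `2^log2fc` for
#' up-regulation, and the relative reduction expressed with a minus sign
#' (`-2^(-log2fc)`) for down-regulation, so `|fold change| >= 1` always and
#' a log2 fold change of 0 maps to 1.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @return signed linear fold changes.
#' @examples
#' signed_linear_fold_change(c(1, 0, -1)) # 2, 1, -2
#' @export
signed_linear_fold_change <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}

#' Classify genes as up/flat/down at an FDR threshold
#'
#' direction = sign(log2fc) when `q < q_threshold` (strict), else 0. No
#' minimal fold-change filter is applied. Degenerate genes stay 0.
#'
#' @param tab data.frame from [moderated_t()] with a `q_value` column
#'   (added here from `p_value` if absent).
#' @param q_threshold FDR threshold (default 0.005).
#' @return the table with `q_value`, `fold_change_linear` and `direction`
#'   columns added.
#' @export
classify_de <- function(tab, q_threshold = 0.005) {
  check_scalar_number(q_threshold, "q_threshold", 0, 1)
  if (is.null(tab$q_value)) tab$q_value <- bh_adjust(tab$p_value)
  tab$fold_change_linear <- signed_linear_fold_change(tab$log2fc)
  sig <- !is.na(tab$q_value) & tab$q_value < q_threshold & !tab$degenerate
  tab$direction <- ifelse(sig, sign(tab$log2fc), 0)
  tab
}

#' Run the full moderated-t analysis for a set of contrasts
#'
#' Fits group means, estimates the variance prior once from all genes, and
#' applies [moderated_t()], [bh_adjust()] (within each contrast) and
#' [classify_de()] per contrast.
#'
#' @param expr log2 expression matrix.
#' @param design design table.
#' @param contrasts list of condition pairs; default the three
#'   constitutive-vs-wild-type contrasts.
#' @param q_threshold FDR threshold (default 0.005).
#' @return object of class `de_result`: `tables` (named list of per-contrast
#'   data.frames), `prior`, `fit`, `summary` (up/down/total counts).
#' @export
de_analysis <- function(expr, design,
                        contrasts = list(c("CA1", "WT"), c("CA2", "WT"),
                                         c("CA3", "WT")),
                        q_threshold = 0.005) {
  fit <- fit_group_means(expr, design)
  prior <- estimate_prior(fit$s2, fit$df)
  tables <- lapply(contrasts, function(ct) {
    classify_de(moderated_t(fit, prior, ct), q_threshold = q_threshold)
  })
  names(tables) <- vapply(contrasts, function(ct) paste(ct, collapse = "-"),
                          character(1))
  summary <- data.frame(
    contrast = names(tables),
    up = vapply(tables, function(t) sum(t$direction == 1), integer(1)),
    down = vapply(tables, function(t) sum(t$direction == -1), integer(1)),
    total = vapply(tables, function(t) sum(t$direction != 0), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(tables = tables, prior = prior, fit = fit, summary = summary,
                 q_threshold = q_threshold), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("Moderated-t differential expression (q <", x$q_threshold, ")\n")
  cat("prior: d0 =", format(x$prior$d0), " s0^2 =", format(x$prior$s0_sq), "\n")
  print(x$summary)
  invisible(x)
}
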