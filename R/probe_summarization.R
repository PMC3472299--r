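# Probe-level preprocessing: optional normal+exponential background
# correction, quantile normalization across arrays, and Tukey median-polish
# summarization of perfect-match probes to probeset-level log2 expression.

#' Background-correct probe intensities (normal + exponential convolution)
#'
#' Models each observed intensity as X = S + B with signal
#' S ~ Exponential(mean `alpha`) and background B ~ Normal(`bg_mean`,
#' `bg_sd`^2). The corrected value is the conditional expectation
#' \deqn{E[S|X=x] = a + \sigma \phi(a/\sigma) / \Phi(a/\sigma), \quad
#'       a = x - \mu_{bg} - \sigma^2/\alpha,}
#' which is strictly positive for every x.
#'
#' When `params` is `NULL` the three parameters are estimated per array by
#' method of moments: the background mode via a histogram, `bg_sd` from the
#' spread of intensities below the mode, and `alpha` from the mean excess
#' above the mode.
#'
#' @param probes a probe-data object (or plain positive matrix).
#' @param params optional list(bg_mean, bg_sd, signal_mean) applied to all
#'   arrays; `NULL` to estimate per array.
#' @return same shape as the input with corrected, strictly positive values.
#' @export
background_correct <- function(probes, params = NULL) {
  m <- if (inherits(probes, "probe_data")) probes$values else as.matrix(probes)
  if (any(!is.finite(m)) || any(m <= 0)) stop_invalid("intensities must be positive and finite")
  if (!is.null(params)) {
    if (params$bg_sd <= 0) stop_invalid("bg_sd must be > 0")
    if (params$signal_mean <= 0) stop_invalid("signal_mean must be > 0")
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    p <- if (is.null(params)) estimate_background_params(x) else params
    out[, j] <- normexp_expectation(x, p$bg_mean, p$bg_sd, p$signal_mean)
  }
  if (inherits(probes, "probe_data")) {
    probes$values <- out
    probes
  } else {
    out
  }
}

# E[S | X = x] under the normal+exponential convolution, computed on the log
# scale of the Mills ratio for numerical stability far below the background.
normexp_expectation <- function(x, bg_mean, bg_sd, signal_mean) {
  a <- x - bg_mean - bg_sd^2 / signal_mean
  z <- a / bg_sd
  # phi(z)/Phi(z) via log densities; stable for z << 0
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  pmax(a + bg_sd * mills, .Machine$double.xmin)
}

estimate_background_params <- function(x) {
  h <- graphics::hist(x, breaks = 100L, plot = FALSE)
  mode <- h$mids[which.max(h$counts)]
  below <- x[x <= mode]
  # half-normal spread of the sub-mode tail; sqrt(2/pi) relates E|Z| to sd
  bg_sd <- sqrt(mean((below - mode)^2))
  if (!is.finite(bg_sd) || bg_sd <= 0) bg_sd <- stats::sd(x) / 10
  alpha <- mean(pmax(x - mode, 0))
  if (!is.finite(alpha) || alpha <= 0) alpha <- mean(x)
  list(bg_mean = mode, bg_sd = bg_sd, signal_mean = alpha)
}

#' Quantile-normalize a matrix across arrays
#'
#' Forces every column to the same reference distribution, the across-array
#' mean of the sorted columns, while preserving each column's rank order.
#' Tied input values receive the mean of the reference values their rank
#' span covers.
#'
#' @param m numeric matrix (probes x arrays), >= 2 columns, all finite.
#' @return matrix of the same shape and dimnames.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(3, 4, 5)))
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop_invalid("need at least 2 arrays")
  if (any(!is.finite(m))) stop_invalid("non-finite values in input")
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    v <- numeric(length(x))
    v[o] <- ref
    # ties: average the reference quantiles over each tied span
    out[, j] <- stats::ave(v, match(x, x))
  }
  out
}

# One median polish of a log2 probe matrix (probes x arrays). Row sweeps
# first; stops when the change in sum(|residual|) drops below tol.
# Returns overall + column effects = per-array expression.
polish_one <- function(lx, max_iter = 10L, tol = 0.01) {
  if (nrow(lx) == 1L) return(as.numeric(lx))
  overall <- 0
  row_eff <- numeric(nrow(lx))
  col_eff <- numeric(ncol(lx))
  r <- lx
  old <- sum(abs(r))
  for (it in seq_len(max_iter)) {
    rm <- apply(r, 1L, stats::median)
    r <- r - rm
    row_eff <- row_eff + rm
    cm <- stats::median(col_eff)
    col_eff <- col_eff - cm
    overall <- overall + cm

    cm <- apply(r, 2L, stats::median)
    r <- sweep(r, 2L, cm)
    col_eff <- col_eff + cm
    rm <- stats::median(row_eff)
    row_eff <- row_eff - rm
    overall <- overall + rm

    tot <- sum(abs(r))
    if (!is.finite(tot) || abs(old - tot) < tol) break
    old <- tot
  }
  overall + col_eff
}

#' Summarize probe intensities to probeset-level log2 expression
#'
#' log2-transforms the (optionally background-corrected and
#' quantile-normalized) probe intensities and fits, per probeset, the
#' additive model `log2 x_pa = overall + probe_p + array_a` by Tukey's
#' median polish (alternating row/column median sweeps). The reported
#' expression of a probeset on array a is `overall + array_a`.
#'
#' @param probes a probe-data object.
#' @param max_iter maximum polish sweeps (default 10).
#' @param tol convergence tolerance on the change in total absolute residual.
#' @return numeric matrix (probesets x arrays) of log2 expression.
#' @export
median_polish_summarize <- function(probes, max_iter = 10L, tol = 0.01) {
  if (!inherits(probes, "probe_data")) stop_invalid("probes must be a probe_data object")
  if (any(probes$values <= 0)) stop_invalid("intensities must be positive")
  lx <- log2(probes$values)
  sets <- split(seq_len(nrow(lx)), probes$probe_to_probeset[probes$probe_ids])
  if (any(lengths(sets) == 0L)) stop_invalid("empty probeset")
  expr <- matrix(NA_real_, nrow = length(sets), ncol = ncol(lx),
                 dimnames = list(names(sets), colnames(lx)))
  for (i in seq_along(sets)) {
    expr[i, ] <- polish_one(lx[sets[[i]], , drop = FALSE], max_iter, tol)
  }
  expr
}

#' Full probe-to-expression summarization pipeline
#'
#' Optional background correction, then quantile normalization on the raw
#' scale, then median-polish summarization on the log2 scale -- perfect-match
#' probes only (the input carries no mismatch probes by construction).
#'
#' @inheritParams median_polish_summarize
#' @param background logical; apply [background_correct()] first (default
#'   `FALSE`: the synthetic generator adds no additive background by default).
#' @return log2 expression matrix (probesets x arrays).
#' @export
summarize_expression <- function(probes, background = FALSE,
                                 max_iter = 10L, tol = 0.01) {
  if (!inherits(probes, "probe_data")) stop_invalid("probes must be a probe_data object")
  if (background) probes <- background_correct(probes)
  probes$values <- quantile_normalize(probes$values)
  median_polish_summarize(probes, max_iter = max_iter, tol = tol)
}

#' Replicate coefficient of variation on the linear scale
#'
#' Measures array reproducibility within one condition: per gene, the
#' anti-logged (2^x) expression values of the replicates give
#' CV = sd / mean; `mean_cv` is the unweighted mean over genes.
#'
#' @param expr log2 expression matrix (genes x arrays).
#' @param design design table mapping arrays to conditions.
#' @param condition condition label with >= 2 replicates.
#' @return list(per_gene_cv, mean_cv).
#' @export
replicate_cv <- function(expr, design, condition) {
  check_design(design)
  arrays <- design$array_id[design$condition == condition]
  arrays <- intersect(arrays, colnames(expr))
  if (length(arrays) < 2L) stop_invalid("need >= 2 replicates in condition ", condition)
  lin <- 2^expr[, arrays, drop = FALSE]
  cv <- apply(lin, 1L, stats::sd) / rowMeans(lin)
  list(per_gene_cv = cv, mean_cv = mean(cv))
}
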