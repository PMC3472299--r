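# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with known ground truth: probe-level intensities under an
# additive log2 model, promoter sets with planted motif instances, a layered
# GO DAG with a planted enriched term, and two-phase batch-culture curves.

#' Generate probe-level intensities with planted differential expression
#'
#' Simulates a probe x array intensity matrix under the additive log2 model
#' that median-polish summarization assumes:
#' \deqn{x_{pa} = 2^{\theta_{g(p),c(a)} + \phi_p + \varepsilon_{pa}} (+ B_{pa})}
#' where \eqn{\theta_{gc}} is the gene's true log2 mean in condition c,
#' \eqn{\phi_p} a per-probe affinity (drawn once, zero-centred within each
#' probeset), \eqn{\varepsilon} i.i.d. Normal(0, `noise_sd_log2`) noise, and
#' \eqn{B} an optional additive background on the raw scale (off by default).
#'
#' A fraction `de_fraction` of genes is planted as differentially expressed:
#' each receives a log2 offset of magnitude `effect_size_log2` (sign random
#' per gene, consistent across all non-reference conditions) added to its
#' condition means relative to the reference condition `WT`.
#'
#' The default `noise_sd_log2 = 0.6` is calibrated so that, after median-polish
#' summarization of 11 probes per probeset, triplicate arrays show a mean
#' linear-scale coefficient of variation of about 0.13, matching the
#' reproducibility the emulated platform achieves.
#'
#' @param design design table from [default_design()].
#' @param n_genes number of genes (probesets), >= 10.
#' @param probes_per_gene probes per probeset, >= 2 (platform default 11).
#' @param de_fraction fraction of genes with planted effects, in \[0, 1\].
#' @param effect_size_log2 magnitude of planted log2 effects.
#' @param noise_sd_log2 probe-level log2 noise standard deviation, > 0.
#' @param baseline_mean,baseline_sd distribution of true log2 gene means.
#' @param affinity_sd standard deviation of probe affinities (log2).
#' @param background optional list(mean, sd) of additive raw-scale background;
#'   `NULL` (default) disables it.
#' @param seed integer seed; identical seed gives identical output.
#' @return list with `probes` (a probe-data object: `values`, `probe_ids`,
#'   `array_ids`, `probe_to_probeset`) and `truth` (`de_genes`: named list
#'   gene -> per-condition true log2 effect vs WT).
#' @examples
#' sim <- generate_probe_data(default_design(), n_genes = 50, seed = 1)
#' dim(sim$probes$values)
#' @export
generate_probe_data <- function(design = default_design(),
                                n_genes = 1000L,
                                probes_per_gene = 11L,
                                de_fraction = 0.1,
                                effect_size_log2 = 2,
                                noise_sd_log2 = 0.6,
                                baseline_mean = 8,
                                baseline_sd = 1.5,
                                affinity_sd = 0.7,
                                background = NULL,
                                seed = 1L) {
  check_design(design)
  n_genes <- check_count(n_genes, "n_genes", min = 10L)
  probes_per_gene <- check_count(probes_per_gene, "probes_per_gene", min = 1L)
  check_scalar_number(de_fraction, "de_fraction", 0, 1)
  check_scalar_number(noise_sd_log2, "noise_sd_log2")
  if (noise_sd_log2 <= 0) stop_invalid("noise_sd_log2 must be > 0")
  seed <- check_count(seed, "seed", min = 0L)

  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  arrays <- design$array_id
  conditions <- unique(design$condition)
  ref <- conditions[1L]
  alt <- setdiff(conditions, ref)

  n_de <- round(n_genes * de_fraction)
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  signs <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)

  # true log2 mean per gene x condition
  base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  theta <- matrix(base, nrow = n_genes, ncol = length(conditions),
                  dimnames = list(genes, conditions))
  de_genes <- list()
  if (n_de > 0) {
    for (k in seq_along(de_idx)) {
      eff <- signs[k] * effect_size_log2
      theta[de_idx[k], alt] <- theta[de_idx[k], alt] + eff
      de_genes[[genes[de_idx[k]]]] <- stats::setNames(rep(eff, length(alt)), alt)
    }
  }

  probe_ids <- paste0(rep(genes, each = probes_per_gene), "_p",
                      rep(seq_len(probes_per_gene), times = n_genes))
  probe_to_probeset <- stats::setNames(rep(genes, each = probes_per_gene), probe_ids)

  # probe affinities, zero-centred within each probeset
  phi <- stats::rnorm(length(probe_ids), 0, affinity_sd)
  phi_mat <- matrix(phi, nrow = probes_per_gene)
  phi_mat <- sweep(phi_mat, 2, colMeans(phi_mat))
  phi <- as.vector(phi_mat)

  cond_of_array <- design$condition[match(arrays, design$array_id)]
  log2_mean <- theta[probe_to_probeset, cond_of_array, drop = FALSE] # probes x arrays
  eps <- matrix(stats::rnorm(length(probe_ids) * length(arrays), 0, noise_sd_log2),
                nrow = length(probe_ids))
  values <- 2^(log2_mean + phi + eps)
  if (!is.null(background)) {
    bg <- matrix(stats::rnorm(length(values), background$mean, background$sd),
                 nrow = nrow(values))
    values <- values + pmax(bg, 0)
  }
  dimnames(values) <- list(probe_ids, arrays)

  probes <- structure(list(values = values, probe_ids = probe_ids,
                           array_ids = arrays,
                           probe_to_probeset = probe_to_probeset),
                      class = "probe_data")
  truth <- list(de_genes = de_genes, genes = genes, reference = ref,
                theta = theta)
  list(probes = probes, truth = truth)
}

#' @export
print.probe_data <- function(x, ...) {
  cat("probe_data:", nrow(x$values), "probes x", ncol(x$values), "arrays;",
      length(unique(x$probe_to_probeset)), "probesets\n")
  invisible(x)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Generate promoter sequences with planted motif instances
#'
#' Background promoters are i.i.d. bases at the requested GC content. Each
#' planted gene additionally receives one exact motif instance, drawn
#' uniformly from the degenerate consensus expansion, written at a uniform
#' random position (background chance hits may still occur anywhere).
#'
#' @param n_genes number of genes.
#' @param length promoter length in bp (>= motif length).
#' @param gc_content background GC proportion in \[0, 1\].
#' @param planted_genes character vector of gene ids to plant (subset of the
#'   generated universe `g0001..`).
#' @param motif a [parse_iupac()] pattern or IUPAC string.
#' @param seed integer seed.
#' @return list with `promoters` (data.frame `gene`, `sequence`, `full_window`)
#'   and `truth` (`motif_genes`).
#' @export
generate_promoters <- function(n_genes = 500L, length = 400L, gc_content = 0.5,
                               planted_genes = character(0),
                               motif = parse_iupac("CANRNTGKCCT"),
                               seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  length <- check_count(length, "length")
  check_scalar_number(gc_content, "gc_content", 0, 1)
  if (is.character(motif)) motif <- parse_iupac(motif)
  if (length < motif$length) stop_invalid("promoter length shorter than motif")
  seed <- check_count(seed, "seed", min = 0L)

  genes <- sprintf("g%04d", seq_len(n_genes))
  planted_genes <- as.character(planted_genes)
  if (!all(planted_genes %in% genes)) {
    stop_invalid("planted_genes outside the generated gene universe")
  }
  set.seed(seed)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  seqs <- vapply(seq_len(n_genes), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- genes

  for (g in planted_genes) {
    word <- vapply(motif$allowed, function(s) s[sample.int(length(s), 1L)],
                   character(1))
    word <- paste(word, collapse = "")
    pos <- sample.int(length - motif$length + 1L, 1L)
    s <- seqs[[g]]
    substr(s, pos, pos + motif$length - 1L) <- word
    seqs[[g]] <- s
  }

  promoters <- data.frame(gene = genes, sequence = unname(seqs),
                          full_window = TRUE, stringsAsFactors = FALSE)
  list(promoters = promoters,
       truth = list(motif_genes = planted_genes, motif = motif$canonical))
}

#' Generate a layered GO DAG with a planted enriched term
#'
#' Terms `T001..T<n>` form a rooted DAG: `T001` is the root and every other
#' term draws 1-2 parents among earlier terms, so the graph is acyclic and
#' every term reaches the root. Each gene receives `annotations_per_gene`
#' direct annotations sampled uniformly from the non-root terms. When
#' `enrichment_boost > 1`, genes in `study_set` receive the enriched term
#' with probability `min(1, boost * p0)` where `p0` is the background
#' probability of carrying it; with `enrichment_boost = 1` nothing is planted.
#'
#' @param n_terms number of GO terms (>= 2).
#' @param n_genes number of genes.
#' @param annotations_per_gene direct annotations per gene.
#' @param enriched_term term id to enrich (must exist); default `NULL` uses
#'   the last term, which is always a leaf -- planting an interior term is
#'   legal but its signal dilutes upward through propagation.
#' @param study_set character vector of study gene ids.
#' @param enrichment_boost odds multiplier >= 1.
#' @param seed integer seed.
#' @return list with `graph` (a [go_graph()]), `annotations` (named list
#'   gene -> direct term ids) and `truth`.
#' @export
generate_go_universe <- function(n_terms = 100L, n_genes = 1000L,
                                 annotations_per_gene = 3L,
                                 enriched_term = NULL,
                                 study_set = character(0),
                                 enrichment_boost = 1,
                                 seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms", min = 2L)
  n_genes <- check_count(n_genes, "n_genes")
  annotations_per_gene <- check_count(annotations_per_gene, "annotations_per_gene")
  check_scalar_number(enrichment_boost, "enrichment_boost", lower = 1)
  seed <- check_count(seed, "seed", min = 0L)

  terms <- sprintf("T%03d", seq_len(n_terms))
  if (is.null(enriched_term)) enriched_term <- terms[n_terms]
  if (!enriched_term %in% terms) {
    stop_invalid("enriched_term ", enriched_term, " not among the ", n_terms, " terms")
  }
  set.seed(seed)
  child <- character(0); parent <- character(0)
  for (i in 2:n_terms) {
    k <- sample(1:2, 1L)
    pa <- sample.int(i - 1L, min(k, i - 1L))
    child <- c(child, rep(terms[i], length(pa)))
    parent <- c(parent, terms[pa])
  }
  graph <- go_graph(data.frame(child = child, parent = parent,
                               stringsAsFactors = FALSE))

  genes <- sprintf("g%04d", seq_len(n_genes))
  study_set <- as.character(study_set)
  if (!all(study_set %in% genes)) stop_invalid("study_set outside gene universe")
  pool <- terms[-1L] # root annotation alone is uninformative
  k <- min(annotations_per_gene, length(pool))
  p0 <- k / length(pool) # background chance a gene carries the enriched term
  annotations <- vector("list", n_genes)
  names(annotations) <- genes
  for (g in genes) {
    ann <- sample(pool, k)
    if (enrichment_boost > 1 && g %in% study_set) {
      if (stats::runif(1) < min(1, enrichment_boost * p0) &&
          !(enriched_term %in% ann)) {
        ann[sample.int(k, 1L)] <- enriched_term
      }
    }
    annotations[[g]] <- unique(ann)
  }
  truth <- list(enriched_term = if (enrichment_boost > 1) enriched_term else NULL,
                boost = enrichment_boost)
  list(graph = graph, annotations = annotations, truth = truth)
}

#' Generate a two-phase batch-culture time series
#'
#' Biomass grows exponentially at rate `mu` from `x0` until `t_break`, then
#' continues linearly with slope `linear_rate`, continuous at the break.
#' Glucose follows the mass balance `s0 - (X - x0)/yield_xs` (floored at 0,
#' density 1 kg/L assumed) and cumulative alkali addition is proportional to
#' biomass formed. Multiplicative lognormal noise with coefficient of
#' variation `noise_cv` is applied per observation (concentrations stay
#' positive); cumulative alkali is kept non-decreasing.
#'
#' @param mu specific growth rate, 1/h.
#' @param x0 inoculum biomass, g_DW/kg.
#' @param t_break time of the exponential-to-linear shift, h (`Inf` for a
#'   purely exponential culture).
#' @param linear_rate linear-phase slope, g_DW/kg/h.
#' @param yield_xs biomass yield on glucose, g/g.
#' @param s0 initial glucose, g/L.
#' @param alkali_per_biomass mol alkali per g biomass formed.
#' @param noise_cv multiplicative noise CV (0 for noiseless).
#' @param sample_times observation times, h (strictly increasing).
#' @param seed integer seed.
#' @return list with `culture` (data.frame `time_h`, `biomass_gdw_kg`,
#'   `alkali_cum_mol`, `glucose_g_l`) and `truth` (kinetic parameters).
#' @examples
#' sim <- generate_culture(noise_cv = 0, seed = 1)
#' head(sim$culture)
#' @export
generate_culture <- function(mu = 0.22, x0 = 0.03, t_break = 21,
                             linear_rate = 0.35, yield_xs = 0.53,
                             s0 = 11.6, alkali_per_biomass = 0.008,
                             noise_cv = 0.03,
                             sample_times = seq(2, 30, by = 1),
                             seed = 1L) {
  for (nm in c("mu", "x0", "linear_rate", "yield_xs", "s0", "alkali_per_biomass")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop_invalid(nm, " must be a non-negative number")
    }
  }
  check_scalar_number(noise_cv, "noise_cv", lower = 0)
  if (any(diff(sample_times) <= 0)) stop_invalid("sample_times must be strictly increasing")
  seed <- check_count(seed, "seed", min = 0L)

  x_true <- function(t) {
    ifelse(t <= t_break, x0 * exp(mu * t),
           x0 * exp(mu * t_break) + linear_rate * (t - t_break))
  }
  X <- x_true(sample_times)
  S <- pmax(s0 - (X - x0) / yield_xs, 0)
  A <- alkali_per_biomass * (X - x0)

  if (noise_cv > 0) {
    set.seed(seed)
    sig <- sqrt(log(1 + noise_cv^2))
    jitter <- function(v) v * exp(stats::rnorm(length(v), -sig^2 / 2, sig))
    X <- jitter(X); S <- jitter(S); A <- cummax(jitter(A))
  }

  culture <- data.frame(time_h = sample_times, biomass_gdw_kg = X,
                        alkali_cum_mol = A, glucose_g_l = S)
  truth <- list(mu = mu, x0 = x0, t_break = t_break, linear_rate = linear_rate,
                yield_xs = yield_xs, s0 = s0,
                alkali_per_biomass = alkali_per_biomass)
  list(culture = culture, truth = truth)
}
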