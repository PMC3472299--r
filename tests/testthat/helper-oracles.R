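# Independent oracles used across the suite. Each deliberately re-derives
# its quantity by the most literal route available (per-position loops,
# exhaustive sums, quadrature) so that it shares no code path with the
# package implementation it checks.

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rc_string <- function(s) paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")

# Per-offset, per-strand, per-position brute-force motif scan of one
# sequence. Returns data.frame(offset [0-based], strand).
oracle_scan_one <- function(seq, iupac, strands = "both") {
  chars <- strsplit(seq, "")[[1]]
  pats <- list("+" = strsplit(iupac, "")[[1]])
  if (strands == "both") {
    # reverse complement of the pattern: complement of an IUPAC code is the
    # code of the complemented base set
    code_of <- function(set) {
      set <- sort(set)
      names(IUPAC)[vapply(IUPAC, function(v) identical(sort(v), set), logical(1))][1]
    }
    rc <- vapply(rev(strsplit(iupac, "")[[1]]), function(cc)
      code_of(unname(COMP[IUPAC[[cc]]])), character(1))
    pats[["-"]] <- rc
  }
  L <- nchar(iupac)
  out <- list()
  for (st in names(pats)) {
    pat <- pats[[st]]
    for (off in seq_len(max(0, length(chars) - L + 1)) - 1) {
      hit <- TRUE
      for (j in seq_len(L)) {
        if (!(chars[off + j] %in% IUPAC[[pat[j]]])) { hit <- FALSE; break }
      }
      if (hit) out[[length(out) + 1]] <- data.frame(offset = off, strand = st)
    }
  }
  if (length(out) == 0) return(data.frame(offset = integer(0), strand = character(0)))
  do.call(rbind, out)
}

# Exhaustive hypergeometric upper tail for a 2x2 table (a,b,c,d): sum the
# point probabilities of every table with the same margins and first cell
# >= a, computed from binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; cpos <- a + c; n <- a + b + c + d
  ks <- max(0, r1 - (n - cpos)):min(r1, cpos)
  probs <- choose(cpos, ks) * choose(n - cpos, r1 - ks) / choose(n, r1)
  sum(probs[ks >= a])
}

# Literal step-up BH: q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Numerical quadrature for E[S | X = x] under X = S + B,
# S ~ Exp(mean alpha), B ~ Normal(mu, sigma^2).
oracle_normexp <- function(x, mu, sigma, alpha) {
  f <- function(s) exp(-s / alpha) * dnorm(x - s, mu, sigma)
  # the integrand is a narrow bump near s = x - mu; keep it inside the range
  upper <- max(x - mu, 0) + 50 * sigma
  num <- integrate(function(s) s * f(s), 0, upper, rel.tol = 1e-10,
                   subdivisions = 2000L)$value
  den <- integrate(f, 0, upper, rel.tol = 1e-10, subdivisions = 2000L)$value
  num / den
}

# Reachability closure of a child -> parent edge list by repeated boolean
# matrix expansion; returns a logical matrix reach[u, v] = v ancestor of u.
oracle_closure <- function(edges, terms) {
  n <- length(terms)
  adj <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  adj[cbind(match(edges$child, terms), match(edges$parent, terms))] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# Direct per-gene membership tally for a Venn partition.
oracle_venn_counts <- function(sets) {
  universe <- unique(unlist(sets))
  sig <- vapply(universe, function(g)
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = ""), character(1))
  table(sig)
}

# Simulate a log2 expression matrix directly at the array level: per-gene
# baseline, planted log2 effects in the non-reference conditions, i.i.d.
# Normal(0, sd) noise per array.
sim_expression <- function(design, n_genes, n_de, effect, sd, seed,
                           both_signs = FALSE) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  conds <- unique(design$condition)
  base <- rnorm(n_genes, 8, 1.5)
  theta <- matrix(base, n_genes, length(conds), dimnames = list(genes, conds))
  de <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  sgn <- if (both_signs && n_de > 0) sample(c(-1, 1), n_de, TRUE) else rep(1, n_de)
  alt <- setdiff(conds, conds[1])
  for (k in seq_along(de)) theta[de[k], alt] <- theta[de[k], alt] + sgn[k] * effect
  expr <- theta[, design$condition, drop = FALSE] +
    matrix(rnorm(n_genes * nrow(design), 0, sd), n_genes)
  colnames(expr) <- design$array_id
  rownames(expr) <- genes
  list(expr = expr, de_genes = genes[de], signs = sgn)
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), len, TRUE, prob = p), collapse = ""), character(1))
}

random_iupac <- function(len, codes = names(IUPAC)) {
  paste(sample(codes, len, TRUE), collapse = "")
}
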