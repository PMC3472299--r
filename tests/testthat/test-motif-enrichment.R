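test_that("IUPAC parsing normalizes slash and parenthesis alternations", {
  m <- parse_iupac("CAN(G/A)NTGT/GCCT")
  expect_equal(m$canonical, "CANRNTGKCCT")
  expect_equal(m$length, 11L)
  expect_equal(m$allowed[[4]], c("A", "G"))
  expect_equal(m$allowed[[8]], c("G", "T"))

  plain <- parse_iupac("ACGT")
  expect_true(all(lengths(plain$allowed) == 1))

  err <- tryCatch(parse_iupac("AXGT"), error = identity)
  expect_s3_class(err, "uprflow_invalid")
  expect_match(conditionMessage(err), "position 2")
})

test_that("promoter scanning matches hand-worked and palindromic cases", {
  motif <- parse_iupac("CANRNTGKCCT")
  prom <- data.frame(gene = "g1", sequence = "GGCAAGATGTCCTGG",
                     full_window = TRUE)
  sc <- scan_promoters(prom, motif, strands = "plus")
  expect_equal(sc$hits$offset, 2L)
  expect_equal(sc$hits$match, "CAAGATGTCCT")

  # reverse-complement instance: found on the minus strand only
  rc <- rc_string("CAAGATGTCCT")
  prom_rc <- data.frame(gene = "g1",
                        sequence = paste0("GG", rc, "GG"),
                        full_window = TRUE)
  both <- scan_promoters(prom_rc, motif, strands = "both")
  expect_equal(both$hits$strand, "-")
  expect_equal(both$hits$offset, 2L)
  expect_equal(nrow(scan_promoters(prom_rc, motif, strands = "plus")$hits), 0)

  # empty promoter and N never matching
  expect_equal(nrow(scan_promoters(data.frame(gene = "g", sequence = "",
                                              full_window = TRUE),
                                   motif)$hits), 0)
  with_n <- data.frame(gene = "g", sequence = "CANGATGTCCT", full_window = TRUE)
  expect_equal(nrow(scan_promoters(with_n, motif, strands = "plus")$hits), 0)
})

test_that("scanner equals the brute-force offset-by-strand oracle", {
  set.seed(33)
  for (i in 1:60) {
    seq <- random_dna(1, sample(20:200, 1))
    L <- sample(4:12, 1)
    # bias toward informative codes so hits actually occur
    iupac <- random_iupac(L, codes = c("A", "C", "G", "T", "R", "Y", "K",
                                       "M", "S", "W", "N", "N"))
    prom <- data.frame(gene = "g", sequence = seq, full_window = TRUE)
    got <- scan_promoters(prom, parse_iupac(iupac), strands = "both")$hits
    want <- oracle_scan_one(seq, iupac, strands = "both")
    got <- got[order(got$strand, got$offset), ]
    want <- want[order(want$strand, want$offset), ]
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("strand symmetry: reverse-complementing promoters swaps strands only", {
  set.seed(44)
  prom <- data.frame(gene = paste0("g", 1:30),
                     sequence = random_dna(30, 150), full_window = TRUE)
  motif <- parse_iupac("CANRNTGKCCT")
  fwd <- scan_promoters(prom, motif, strands = "both")
  prom_rc <- prom
  prom_rc$sequence <- vapply(prom$sequence, rc_string, character(1),
                             USE.NAMES = FALSE)
  rev <- scan_promoters(prom_rc, motif, strands = "both")
  expect_setequal(fwd$positive_genes$members, rev$positive_genes$members)
  expect_equal(nrow(fwd$hits), nrow(rev$hits))
})

test_that("upstream extraction honours strand, window and contig edges", {
  contig <- paste(rep("ACGT", 300), collapse = "") # 1200 bp
  genome <- c(chr1 = contig)
  ann <- data.frame(gene = c("plus_mid", "plus_short", "minus_mid"),
                    contig = "chr1", strand = c("+", "+", "-"),
                    start = c(401, 101, 201), end = c(700, 300, 600),
                    stringsAsFactors = FALSE)
  ps <- extract_upstream(genome, ann, window = 400)

  expect_equal(ps$sequence[ps$gene == "plus_mid"], substr(contig, 1, 400))
  expect_true(ps$full_window[ps$gene == "plus_mid"])

  expect_equal(ps$sequence[ps$gene == "plus_short"], substr(contig, 1, 100))
  expect_false(ps$full_window[ps$gene == "plus_short"])

  # minus gene: reverse complement of the 400 bp right of the coding end,
  # checked base-by-base against a brute-force extractor
  want <- rc_string(substr(contig, 601, 1000))
  expect_equal(ps$sequence[ps$gene == "minus_mid"], want)
  expect_true(ps$full_window[ps$gene == "minus_mid"])

  # minus gene clipped at the contig end
  clip <- extract_upstream(genome, data.frame(
    gene = "minus_edge", contig = "chr1", strand = "-",
    start = 900, end = 1100), window = 400)
  expect_equal(clip$sequence, rc_string(substr(contig, 1101, 1200)))
  expect_false(clip$full_window)

  expect_error(extract_upstream(genome, data.frame(
    gene = "g", contig = "chrX", strand = "+", start = 500, end = 600)),
    class = "uprflow_missing_sequence")
  expect_warning(extract_upstream(genome, data.frame(
    gene = "g0", contig = "chr1", strand = "+", start = 1, end = 100)),
    "empty upstream")
})

test_that("one-sided Fisher test equals the exhaustive hypergeometric sum", {
  ft <- fisher_exact_one_sided(2, 0, 0, 2)
  expect_equal(ft$p, 1 / 6, tolerance = 1e-12)
  expect_identical(ft$odds_ratio, Inf)

  # a = 0: whole support, p = 1
  expect_equal(fisher_exact_one_sided(0, 5, 3, 7)$p, 1, tolerance = 1e-12)

  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    repeat {
      cuts <- sort(sample(0:n, 3, replace = TRUE))
      a <- cuts[1]; b <- cuts[2] - cuts[1]
      c <- cuts[3] - cuts[2]; d <- n - cuts[3]
      if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) break
    }
    got <- fisher_exact_one_sided(a, b, c, d)
    expect_equal(got$p, oracle_fisher_p(a, b, c, d), tolerance = 1e-10)
    expect_equal(got$p,
                 fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                             alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_one_sided(-1, 2, 3, 4), class = "uprflow_invalid")
  expect_error(fisher_exact_one_sided(0, 0, 3, 4), class = "uprflow_invalid")
})

test_that("planted promoters give overwhelming enrichment; nulls are calibrated", {
  planted <- sprintf("g%04d", 1:50)
  study <- sprintf("g%04d", 1:100) # 50 planted + 50 unplanted study genes
  sim <- generate_promoters(n_genes = 600, planted_genes = planted, seed = 7)
  enr <- motif_enrichment(sim$promoters, study)
  expect_gte(enr$positives_in_set, 50)
  expect_lt(enr$p, 1e-6)

  # extreme table: every study gene positive, zero background positives
  prom <- generate_promoters(n_genes = 30, planted_genes = sprintf("g%04d", 1:5),
                             gc_content = 0, seed = 2)$promoters
  # gc 0 background (all A/T) cannot contain the GC-rich consensus core
  enr2 <- motif_enrichment(prom, sprintf("g%04d", 1:5))
  expect_equal(enr2$table["not_in_set", "positive"], 0)
  expect_equal(enr2$p, 1 / choose(30, 5), tolerance = 1e-12)

  expect_error(motif_enrichment(prom, character(0)), class = "uprflow_invalid")
  expect_error(motif_enrichment(prom, "absent_gene"), class = "uprflow_invalid")
})

test_that("null study sets give uniform enrichment p-values", {
  sim <- generate_promoters(n_genes = 400, planted_genes = character(0),
                            seed = 19)
  set.seed(55)
  ps <- replicate(120, {
    study <- sample(sim$promoters$gene, 80)
    motif_enrichment(sim$promoters, study)$p
  })
  # discrete p-values are stochastically >= uniform; KS against the uniform
  # should not reject in the anti-conservative direction
  ks <- suppressWarnings(ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})
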