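# UPRE promoter-motif analysis: parse a degenerate IUPAC consensus, extract
# upstream windows from a genome + annotation, scan promoters on both
# strands, and test study-set enrichment with a one-sided Fisher exact test.
#
# The default motif is the HacA-binding UPR element consensus
# 5'-CAN(G/A)NTGT/GCCT-3', i.e. CANRNTGKCCT as an 11-mer IUPAC string.

#' Parse a degenerate motif into per-position allowed base sets
#'
#' Accepts plain IUPAC strings and the common slash/parenthesis alternation
#' notations: `(G/A)` and a bare `X/Y` both denote a single position allowing
#' either base, so `"CAN(G/A)NTGT/GCCT"` normalizes to `"CANRNTGKCCT"`.
#'
#' @param pattern motif string.
#' @return object of class `motif_pattern`: `canonical` (IUPAC string),
#'   `length`, `allowed` (list of character vectors per position).
#' @examples
#' parse_iupac("CAN(G/A)NTGT/GCCT")$canonical # "CANRNTGKCCT"
#' @export
parse_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    stop_invalid("pattern must be a non-empty string")
  }
  chars <- strsplit(toupper(pattern), "")[[1L]]
  allowed <- list()
  i <- 1L
  base_set <- function(ch, pos) {
    s <- IUPAC_SETS[[ch]]
    if (is.null(s)) stop_invalid("invalid IUPAC code '", ch, "' at position ", pos)
    s
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i
      while (j <= length(chars) && chars[j] != ")") j <- j + 1L
      if (j > length(chars)) stop_invalid("unclosed '(' at position ", i)
      inner <- chars[(i + 1L):(j - 1L)]
      bases <- inner[inner != "/"]
      allowed[[length(allowed) + 1L]] <-
        sort(unique(unlist(lapply(seq_along(bases),
                                  function(k) base_set(bases[k], i + k)))))
      i <- j + 1L
    } else if (ch == "/") {
      # bare X/Y alternation: merge with the previous position
      if (length(allowed) == 0L || i == length(chars)) {
        stop_invalid("misplaced '/' at position ", i)
      }
      nxt <- base_set(chars[i + 1L], i + 1L)
      allowed[[length(allowed)]] <- sort(unique(c(allowed[[length(allowed)]], nxt)))
      i <- i + 2L
    } else {
      allowed[[length(allowed) + 1L]] <- base_set(ch, i)
      i <- i + 1L
    }
  }
  canonical <- vapply(allowed, function(s) {
    hit <- vapply(IUPAC_SETS, function(v) identical(sort(v), s), logical(1))
    names(IUPAC_SETS)[which(hit)[1L]]
  }, character(1))
  structure(list(canonical = paste(canonical, collapse = ""),
                 length = length(allowed), allowed = allowed),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern", x$canonical, "(", x$length, "bp )\n")
  invisible(x)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

reverse_complement <- function(s) {
  vapply(s, function(x) {
    paste(rev(DNA_COMPLEMENT[strsplit(x, "")[[1L]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract upstream promoter windows from a genome
#'
#' Returns, for each annotated gene, the `window` bases immediately 5' of
#' its coding start, read 5'->3' toward the start codon: for plus-strand
#' genes the window left of `start` on the plus strand, for minus-strand
#' genes the reverse complement of the window right of `end`. Windows are
#' truncated at contig edges (`full_window = FALSE`); genes whose window is
#' empty are omitted with a warning.
#'
#' @param genome named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param annotation data.frame with `gene`, `contig`, `strand` (`+`/`-`),
#'   `start`, `end` (1-based inclusive, GFF3 convention).
#' @param window upstream window size in bp (default 400).
#' @return promoter set: data.frame `gene`, `sequence`, `full_window`.
#' @export
extract_upstream <- function(genome, annotation, window = 400L) {
  window <- check_count(window, "window")
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  need <- c("gene", "contig", "strand", "start", "end")
  if (!all(need %in% names(annotation))) {
    stop_invalid("annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(annotation$strand %in% c("+", "-"))) stop_invalid("strand must be + or -")
  absent <- setdiff(unique(annotation$contig), names(genome))
  if (length(absent)) {
    stop(errorCondition(paste0("contigs absent from genome: ",
                               paste(absent, collapse = ", ")),
                        class = c("uprflow_missing_sequence", "error")))
  }
  out <- vector("list", nrow(annotation))
  dropped <- character(0)
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    contig <- genome[[a$contig]]
    len <- nchar(contig)
    if (a$strand == "+") {
      to <- a$start - 1L
      from <- max(1L, a$start - window)
      if (to < from) { dropped <- c(dropped, a$gene); next }
      s <- substr(contig, from, to)
    } else {
      from <- a$end + 1L
      to <- min(len, a$end + window)
      if (to < from) { dropped <- c(dropped, a$gene); next }
      s <- reverse_complement(substr(contig, from, to))
    }
    out[[i]] <- data.frame(gene = a$gene, sequence = toupper(s),
                           full_window = nchar(s) == window,
                           stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("omitted ", length(dropped), " gene(s) with empty upstream window: ",
            paste(dropped, collapse = ", "))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# All plus-strand match offsets (0-based) of a motif's allowed sets in one
# sequence. N (or any non-ACGT letter) in the sequence matches nothing.
match_offsets <- function(seq, allowed) {
  L <- length(allowed)
  n <- nchar(seq)
  if (n < L) return(integer(0))
  chars <- strsplit(seq, "")[[1L]]
  n_off <- n - L + 1L
  ok <- rep(TRUE, n_off)
  for (j in seq_len(L)) {
    ok <- ok & (chars[j:(j + n_off - 1L)] %in% allowed[[j]])
    if (!any(ok)) return(integer(0))
  }
  which(ok) - 1L
}

#' Scan promoters for a degenerate motif
#'
#' Reports every offset (0-based, on the stored plus-strand promoter
#' sequence) where the motif matches. With `strands = "both"` the reverse
#' complement of the motif is also matched against the stored sequence and
#' reported as a minus-strand hit. Overlapping hits are all reported; a
#' sequence `N` matches no motif position.
#'
#' @param promoters promoter set data.frame (`gene`, `sequence`).
#' @param motif [motif_pattern][parse_iupac()] or IUPAC string.
#' @param strands `"both"` (default) or `"plus"`.
#' @return list: `hits` (data.frame `gene`, `offset`, `strand`, `match`),
#'   `positive_genes` ([gene_set()] of genes with >= 1 hit).
#' @export
scan_promoters <- function(promoters, motif, strands = c("both", "plus")) {
  strands <- match.arg(strands)
  if (is.character(motif)) motif <- parse_iupac(motif)
  rc_allowed <- rev(lapply(motif$allowed, function(s)
    sort(unname(DNA_COMPLEMENT[s]))))
  hits <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    s <- promoters$sequence[i]
    g <- promoters$gene[i]
    off_p <- match_offsets(s, motif$allowed)
    rows <- list()
    if (length(off_p)) {
      rows[[1L]] <- data.frame(gene = g, offset = off_p, strand = "+",
                               match = substring(s, off_p + 1L, off_p + motif$length),
                               stringsAsFactors = FALSE)
    }
    if (strands == "both") {
      off_m <- match_offsets(s, rc_allowed)
      if (length(off_m)) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene = g, offset = off_m, strand = "-",
                     match = substring(s, off_m + 1L, off_m + motif$length),
                     stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) hits[[i]] <- do.call(rbind, rows)
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(gene = character(0), offset = integer(0),
                       strand = character(0), match = character(0),
                       stringsAsFactors = FALSE)
  }
  list(hits = hits,
       positive_genes = gene_set("motif_positive", unique(hits$gene)))
}

#' One-sided Fisher's exact test for a 2x2 contingency table
#'
#' Rows are in-set / not-in-set, columns motif-positive / motif-negative.
#' The p-value is the hypergeometric upper tail: the probability of
#' observing at least `a` positives among the in-set draws given fixed
#' margins. The odds ratio is the cross-product `a*d / (b*c)` (`Inf` when
#' `b*c = 0`).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list(p, odds_ratio, table).
#' @examples
#' fisher_exact_one_sided(2, 0, 0, 2) # p = 1/6
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_invalid("cell counts must be non-negative integers")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop_invalid("all table margins must be positive")
  }
  # P(X >= a), X ~ Hypergeom(white = a+c, black = b+d, draws = a+b)
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  list(p = p, odds_ratio = or, table = matrix(cells, 2L, 2L, byrow = TRUE,
       dimnames = list(c("in_set", "not_in_set"), c("positive", "negative"))))
}

#' Motif enrichment of a study gene set among all promoters
#'
#' Scans every promoter for the motif and tests whether motif-positive genes
#' are over-represented in the study set relative to all remaining genes
#' with retrievable promoters (one-sided Fisher exact test).
#'
#' @param promoters promoter set covering the whole gene universe.
#' @param study_set [gene_set()] or character vector, subset of the
#'   promoter genes.
#' @param motif motif pattern or IUPAC string.
#' @param strands passed to [scan_promoters()].
#' @return list: `table` (2x2 matrix), `p`, `odds_ratio`,
#'   `positives_in_set`, `hits` (per-gene hit report).
#' @export
motif_enrichment <- function(promoters, study_set,
                             motif = parse_iupac("CANRNTGKCCT"),
                             strands = "both") {
  members <- if (inherits(study_set, "gene_set")) study_set$members else
    unique(as.character(study_set))
  if (length(members) == 0L) stop_invalid("study set is empty")
  if (!all(members %in% promoters$gene)) {
    stop_invalid("study set contains genes without promoters")
  }
  scan <- scan_promoters(promoters, motif, strands = strands)
  pos <- scan$positive_genes$members
  in_set <- promoters$gene %in% members
  is_pos <- promoters$gene %in% pos
  a <- sum(in_set & is_pos); b <- sum(in_set & !is_pos)
  c <- sum(!in_set & is_pos); d <- sum(!in_set & !is_pos)
  ft <- fisher_exact_one_sided(a, b, c, d)
  list(table = ft$table, p = ft$p, odds_ratio = ft$odds_ratio,
       positives_in_set = a, hits = scan$hits)
}
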