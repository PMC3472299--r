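# Gene-set mechanics: Venn partitioning of 2-3 sets (the per-timepoint
# up/down diagrams) and consistency sets across contrasts.

#' Construct a labelled gene set
#'
#' @param label set label.
#' @param members character vector of gene ids (deduplicated).
#' @return object of class `gene_set`.
#' @export
gene_set <- function(label, members) {
  structure(list(label = as.character(label),
                 members = unique(as.character(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set", x$label, "(", length(x$members), "genes )\n")
  invisible(x)
}

#' Venn partition of 2 or 3 gene sets
#'
#' Partitions the union of the input sets into the 2^k - 1 disjoint regions
#' of the k-set Venn diagram. Regions are keyed by a membership signature of
#' "1"/"0" characters, one per input set in order (e.g. `"110"` = in sets 1
#' and 2 only).
#'
#' @param sets list of 2 or 3 [gene_set()] objects (plain character vectors
#'   are accepted and wrapped).
#' @return data.frame with `signature`, `count` and a list-column `members`;
#'   region counts sum to the size of the union.
#' @examples
#' venn_partition(list(a = c("x", "y"), b = c("y", "z")))
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L) {
    stop_invalid("venn_partition supports 2 or 3 sets, got ", length(sets))
  }
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) s else
      gene_set(names(sets)[i] %||% paste0("set", i), s)
  })
  universe <- unique(unlist(lapply(sets, `[[`, "members")))
  member <- vapply(sets, function(s) universe %in% s$members,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  signature <- apply(member, 1L, function(row) paste(as.integer(row), collapse = ""))
  k <- length(sets)
  all_sigs <- apply(as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE],
                    1L, paste, collapse = "")
  all_sigs <- setdiff(all_sigs, strrep("0", k))
  out <- data.frame(signature = all_sigs, count = 0L, stringsAsFactors = FALSE)
  out$members <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    g <- universe[signature == out$signature[i]]
    out$count[i] <- length(g)
    out$members[[i]] <- g
  }
  attr(out, "labels") <- vapply(sets, `[[`, character(1), "label")
  out
}

#' Genes consistently up- or down-regulated across all contrasts
#'
#' From per-contrast classified results (see [classify_de()]), the genes
#' with direction +1 in every contrast (`up_all`) and -1 in every contrast
#' (`down_all`). Genes flagged degenerate in any contrast are excluded.
#'
#' @param tables named list of classified per-contrast data.frames over the
#'   same gene universe.
#' @return list of two [gene_set()]s: `up_all`, `down_all` (disjoint).
#' @export
consistent_de_sets <- function(tables) {
  if (length(tables) < 1L) stop_invalid("no contrast tables supplied")
  genes <- tables[[1L]]$gene
  for (t in tables) {
    if (!identical(sort(t$gene), sort(genes))) {
      stop_invalid("contrast tables cover different gene universes")
    }
  }
  dirs <- vapply(tables, function(t) t$direction[match(genes, t$gene)],
                 numeric(length(genes)))
  degen <- vapply(tables, function(t) t$degenerate[match(genes, t$gene)],
                  logical(length(genes)))
  if (length(genes) == 1L) {
    dirs <- matrix(dirs, nrow = 1L); degen <- matrix(degen, nrow = 1L)
  }
  ok <- !apply(degen, 1L, any)
  up <- ok & apply(dirs == 1, 1L, all)
  down <- ok & apply(dirs == -1, 1L, all)
  list(up_all = gene_set("up_all", genes[up]),
       down_all = gene_set("down_all", genes[down]))
}
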