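# GO-term over-representation in the FetGOat style: true-path propagation of
# gene annotations up the DAG, a one-sided Fisher test per term, BH FDR at
# q < 0.05, and a transitive-reduction network of the enriched terms.

#' Construct a GO DAG from a child -> parent edge list
#'
#' `is_a` and `part_of` edges are treated identically. The constructor
#' validates acyclicity (topological sort) and precomputes each term's
#' ancestor set.
#'
#' @param edges data.frame with columns `child`, `parent`.
#' @param terms optional character vector of term ids (defaults to all ids
#'   appearing in `edges`).
#' @return object of class `go_graph`: `terms`, `edges`, `parents` (named
#'   list), `ancestors` (named list, term excluded), `roots`.
#' @export
go_graph <- function(edges, terms = NULL) {
  if (!all(c("child", "parent") %in% names(edges))) {
    stop_invalid("edges must have columns child, parent")
  }
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  if (is.null(terms)) terms <- unique(c(edges$child, edges$parent))
  terms <- as.character(terms)
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  parents <- lapply(parents, unique)

  # Kahn topological order over child -> parent edges; cycle check
  order <- character(0)
  out_deg <- lengths(parents) # edges still pointing to unprocessed parents
  children_of <- split(edges$child, factor(edges$parent, levels = terms))
  queue <- terms[out_deg == 0L] # roots first
  deg <- out_deg
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    order <- c(order, t)
    for (ch in children_of[[t]]) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(terms)) stop_invalid("graph contains a cycle")

  ancestors <- stats::setNames(vector("list", length(terms)), terms)
  for (t in order) { # parents are processed before children
    pa <- parents[[t]]
    ancestors[[t]] <- unique(c(pa, unlist(ancestors[pa], use.names = FALSE)))
  }
  structure(list(terms = terms, edges = edges, parents = parents,
                 ancestors = ancestors, roots = terms[out_deg == 0L]),
            class = "go_graph")
}

#' @export
print.go_graph <- function(x, ...) {
  cat("go_graph:", length(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

#' Propagate gene annotations up the DAG (true-path rule)
#'
#' Each gene's propagated annotation set is its direct terms plus all their
#' ancestors; the operation is idempotent.
#'
#' @param graph a [go_graph()].
#' @param direct named list gene -> character vector of directly annotated
#'   term ids.
#' @return named list gene -> propagated term ids.
#' @export
propagate_annotations <- function(graph, direct) {
  if (!inherits(graph, "go_graph")) stop_invalid("graph must be a go_graph")
  unknown <- setdiff(unique(unlist(direct)), graph$terms)
  if (length(unknown)) {
    stop_invalid("annotations to unknown terms: ", paste(unknown, collapse = ", "))
  }
  lapply(direct, function(tt) {
    unique(c(tt, unlist(graph$ancestors[tt], use.names = FALSE)))
  })
}

#' GO-term over-representation analysis
#'
#' For every term carrying at least one study gene (after propagation), a
#' one-sided Fisher exact test of over-representation among study genes
#' versus the annotated population, with BH q-values over the tested terms.
#'
#' @param study [gene_set()] or character vector, subset of `population`.
#' @param population character vector of all annotated genes (defaults to
#'   `names(propagated)`).
#' @param propagated named list gene -> propagated term ids (see
#'   [propagate_annotations()]).
#' @param q_threshold enrichment threshold (default 0.05).
#' @return data.frame (`term`, `study_count`, `pop_count`, `p`, `q`,
#'   `enriched`), sorted by p.
#' @export
term_enrichment <- function(study, propagated, population = names(propagated),
                            q_threshold = 0.05) {
  members <- if (inherits(study, "gene_set")) study$members else
    unique(as.character(study))
  if (!all(members %in% population)) {
    stop_invalid("study set contains genes outside the annotated population")
  }
  propagated <- propagated[population]
  N <- length(population)
  n <- length(members)
  gene_terms <- propagated[members]
  study_counts <- table(unlist(gene_terms, use.names = FALSE))
  tested <- names(study_counts)
  pop_counts <- table(factor(unlist(propagated, use.names = FALSE), levels = tested))
  p <- vapply(seq_along(tested), function(i) {
    a <- as.integer(study_counts[i])           # study genes with the term
    K <- as.integer(pop_counts[i])             # population genes with the term
    stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  }, numeric(1))
  q <- bh_adjust(p)
  out <- data.frame(term = tested,
                    study_count = as.integer(study_counts),
                    pop_count = as.integer(pop_counts),
                    p = p, q = q, enriched = q < q_threshold,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Network of enriched terms by transitive reduction
#'
#' Restricted to the enriched terms, draws an edge u -> v whenever v is an
#' ancestor of u and no other enriched term lies between them (i.e. the
#' transitive reduction of the ancestor relation on the enriched set).
#'
#' @param enriched character vector of enriched term ids.
#' @param graph a [go_graph()].
#' @return data.frame with columns `from`, `to`.
#' @export
enrichment_network <- function(enriched, graph) {
  if (!inherits(graph, "go_graph")) stop_invalid("graph must be a go_graph")
  enriched <- unique(as.character(enriched))
  if (!all(enriched %in% graph$terms)) stop_invalid("enriched terms not in graph")
  from <- character(0); to <- character(0)
  for (u in enriched) {
    anc <- intersect(graph$ancestors[[u]], enriched)
    for (v in anc) {
      # drop u -> v if an enriched w sits on a path u ->* w ->* v
      between <- any(vapply(setdiff(anc, v), function(w)
        v %in% graph$ancestors[[w]], logical(1)))
      if (!between) { from <- c(from, u); to <- c(to, v) }
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}
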