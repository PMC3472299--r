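# Readers and writers for the pipeline's plain-text interchange formats:
# TSV probe matrix + probe map, design TSV, promoter FASTA, GO DAG and
# annotation TSVs, culture CSV, and JSON for truth/summaries.

#' Write and read probe-level data
#'
#' The probe matrix is a TSV with a `probe_id` first column and one column
#' per array; the probe map is a two-column TSV (`probe_id`, `probeset_id`).
#'
#' @param probes a probe-data object.
#' @param matrix_path,map_path output file paths.
#' @return (write) invisibly the paths; (read) a probe-data object.
#' @export
write_probe_data <- function(probes, matrix_path, map_path) {
  df <- data.frame(probe_id = probes$probe_ids, probes$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(probe_id = probes$probe_ids,
                    probeset_id = unname(probes$probe_to_probeset[probes$probe_ids]))
  utils::write.table(map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, map_path))
}

#' @rdname write_probe_data
#' @export
read_probe_data <- function(matrix_path, map_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  structure(list(values = values, probe_ids = df[[1L]],
                 array_ids = colnames(values),
                 probe_to_probeset = stats::setNames(map$probeset_id, map$probe_id)),
            class = "probe_data")
}

#' Write/read a design table as TSV
#' @param design design table; @param path file path.
#' @return (read) the design data.frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  check_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write/read an expression matrix as TSV (probeset x array, log2)
#' @param expr expression matrix; @param path file path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probeset_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write/read a promoter set as FASTA
#'
#' Headers carry the gene id and a `partial` flag when the full upstream
#' window was not retrievable.
#'
#' @param promoters promoter set data.frame; @param path FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters$sequence)
  names(x) <- ifelse(promoters$full_window, promoters$gene,
                     paste(promoters$gene, "partial"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- names(x)
  data.frame(gene = sub("\\s.*$", "", ids),
             sequence = toupper(as.character(x)),
             full_window = !grepl("\\spartial$", ids),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write/read GO DAG edges and gene annotations as two-column TSVs
#' @param graph a [go_graph()]; @param annotations named list gene -> terms.
#' @param path file path.
#' @export
write_go_graph <- function(graph, path) {
  utils::write.table(graph$edges[, c("child", "parent")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_go_graph
#' @export
read_go_graph <- function(path) {
  go_graph(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname write_go_graph
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(gene = rep(names(annotations), lengths(annotations)),
                   term = unlist(annotations, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_go_graph
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df$term, df$gene), unique)
}

#' Write/read a culture time series as CSV
#'
#' Columns `time_h`, `biomass_gdw_kg`, `alkali_cum_mol`, `glucose_g_l`;
#' empty cells denote unobserved (sparse) signals.
#'
#' @param culture culture data.frame; @param path CSV path.
#' @export
write_culture_csv <- function(culture, path) {
  utils::write.csv(culture, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_culture_csv
#' @export
read_culture_csv <- function(path) {
  ts <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(diff(ts$time_h) <= 0)) stop_invalid("time must be strictly increasing")
  ts
}
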