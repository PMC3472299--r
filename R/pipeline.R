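# End-to-end orchestration: a validated configuration object, a run_pipeline()
# driver that executes summarize -> DE -> sets -> motif -> GO -> kinetics and
# writes a machine-readable manifest, and a one-command all-synthetic demo.

#' Build and validate a pipeline configuration
#'
#' @param probe_matrix,probe_map,design paths to the probe TSVs and design TSV.
#' @param promoters path to a promoter FASTA (gene ids in headers).
#' @param go_dag,go_annotations paths to the GO edge and annotation TSVs.
#' @param culture path to the culture CSV (optional).
#' @param fdr_de FDR threshold for differential expression (default 0.005).
#' @param fdr_go FDR threshold for GO enrichment (default 0.05).
#' @param motif IUPAC motif string (default the UPRE consensus
#'   `"CANRNTGKCCT"`).
#' @param window upstream window in bp (default 400).
#' @param strands `"both"` or `"plus"`.
#' @param background apply background correction during summarization.
#' @param seed root seed; all stage seeds derive from it.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(probe_matrix, probe_map, design, promoters = NULL,
                            go_dag = NULL, go_annotations = NULL,
                            culture = NULL, fdr_de = 0.005, fdr_go = 0.05,
                            motif = "CANRNTGKCCT", window = 400L,
                            strands = "both", background = FALSE, seed = 42L) {
  check_scalar_number(fdr_de, "fdr_de", 0, 1)
  check_scalar_number(fdr_go, "fdr_go", 0, 1)
  if (fdr_de <= 0 || fdr_de >= 1) stop_invalid("fdr_de must be in (0,1)")
  if (fdr_go <= 0 || fdr_go >= 1) stop_invalid("fdr_go must be in (0,1)")
  window <- check_count(window, "window")
  seed <- check_count(seed, "seed", min = 0L)
  cfg <- list(probe_matrix = probe_matrix, probe_map = probe_map,
              design = design, promoters = promoters, go_dag = go_dag,
              go_annotations = go_annotations, culture = culture,
              fdr_de = fdr_de, fdr_go = fdr_go, motif = motif,
              window = window, strands = strands, background = background,
              seed = seed)
  for (field in c("probe_matrix", "probe_map", "design", "promoters",
                  "go_dag", "go_annotations", "culture")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop_invalid("config field '", field, "': file not found: ", p)
    }
  }
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " INFO ", paste0(...))
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage, writes all artifacts (TSV/JSON) under
#' `out_dir`, and finishes with a manifest (`manifest.json`) recording the
#' parameters and the MD5 checksum of every output, so a rerun with the same
#' inputs and seed is byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (!inherits(cfg, "pipeline_config")) stop_invalid("cfg must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  stage <- function(name, fun) {
    log_msg(log_path, "stage ", name, " started")
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_msg(log_path, "stage ", name, " done")
    res
  }

  # --- summarize ---------------------------------------------------------
  design <- read_design(cfg$design)
  expr <- stage("summarize", function() {
    probes <- read_probe_data(cfg$probe_matrix, cfg$probe_map)
    e <- summarize_expression(probes, background = cfg$background)
    write_expression(e, emit(file.path(out_dir, "expression.tsv")))
    e
  })

  # --- differential expression ------------------------------------------
  de <- stage("de", function() {
    res <- de_analysis(expr, design, q_threshold = cfg$fdr_de)
    for (nm in names(res$tables)) {
      utils::write.table(res$tables[[nm]],
                         emit(file.path(out_dir, paste0("de_", nm, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(res$summary,
                         emit(file.path(out_dir, "de_summary.json")))
    res
  })

  # --- consistency sets --------------------------------------------------
  sets <- stage("venn", function() {
    cs <- consistent_de_sets(de$tables)
    up_sets <- lapply(de$tables, function(t) t$gene[t$direction == 1])
    venn <- venn_partition(up_sets)
    jsonlite::write_json(
      list(up_all = cs$up_all$members, down_all = cs$down_all$members,
           venn_up = stats::setNames(as.list(venn$count), venn$signature)),
      emit(file.path(out_dir, "sets.json")))
    cs
  })

  # --- motif enrichment --------------------------------------------------
  if (!is.null(cfg$promoters)) {
    stage("upre-scan", function() {
      promoters <- read_promoters_fasta(cfg$promoters)
      study <- intersect(sets$up_all$members, promoters$gene)
      if (length(study) == 0L) {
        log_msg(log_path, "upre-scan skipped: no up-regulated genes with promoters")
        return(NULL)
      }
      enr <- motif_enrichment(promoters, study, motif = cfg$motif,
                              strands = cfg$strands)
      utils::write.table(enr$hits, emit(file.path(out_dir, "upre_hits.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(table = as.vector(enr$table), p = enr$p,
             odds_ratio = enr$odds_ratio,
             positives_in_set = enr$positives_in_set),
        emit(file.path(out_dir, "upre_enrichment.json")), auto_unbox = TRUE)
      enr
    })
  }

  # --- GO enrichment -----------------------------------------------------
  if (!is.null(cfg$go_dag) && !is.null(cfg$go_annotations)) {
    stage("go-enrich", function() {
      graph <- read_go_graph(cfg$go_dag)
      direct <- read_annotations(cfg$go_annotations)
      propagated <- propagate_annotations(graph, direct)
      study <- intersect(sets$up_all$members, names(propagated))
      if (length(study) == 0L) {
        log_msg(log_path, "go-enrich skipped: no annotated up-regulated genes")
        return(NULL)
      }
      tab <- term_enrichment(study, propagated, q_threshold = cfg$fdr_go)
      utils::write.table(tab, emit(file.path(out_dir, "go_enrichment.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      net <- enrichment_network(tab$term[tab$enriched], graph)
      utils::write.table(net, emit(file.path(out_dir, "go_network.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  # --- growth kinetics ---------------------------------------------------
  if (!is.null(cfg$culture)) {
    stage("kinetics", function() {
      ts <- read_culture_csv(cfg$culture)
      gf <- growth_kinetics(ts)
      jsonlite::write_json(unclass(gf),
                           emit(file.path(out_dir, "growth_fit.json")),
                           auto_unbox = TRUE, digits = NA)
      gf
    })
  }

  manifest <- list(
    package = "uprflow",
    version = as.character(utils::packageVersion("uprflow")),
    parameters = unclass(cfg),
    inputs = lapply(Filter(Negate(is.null),
                           cfg[c("probe_matrix", "probe_map", "design",
                                 "promoters", "go_dag", "go_annotations",
                                 "culture")]),
                    function(p) unname(tools::md5sum(p))),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg(log_path, "pipeline complete: ", length(outputs), " artifacts")
  invisible(manifest)
}

#' One-command synthetic end-to-end demo
#'
#' Generates a full synthetic study (probe data with planted differential
#' expression, promoters with planted UPRE instances, a GO universe with a
#' planted enriched term, and a two-phase culture curve), writes the inputs
#' in the pipeline's interchange formats, and runs [run_pipeline()] on them.
#' Deterministic for a given seed: all stage seeds derive from the root seed.
#'
#' @param out_dir output directory.
#' @param seed root seed (default 42).
#' @param n_genes genes in the synthetic universe (default 600, enough for
#'   a stable variance prior while keeping the demo fast).
#' @return invisibly, the pipeline manifest.
#' @export
run_demo <- function(out_dir, seed = 42L, n_genes = 600L) {
  seed <- check_count(seed, "seed", min = 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)

  design <- default_design()
  sim <- generate_probe_data(design, n_genes = n_genes,
                             seed = derive_seed(seed, 1L))
  write_probe_data(sim$probes, file.path(in_dir, "probes.tsv"),
                   file.path(in_dir, "probe_map.tsv"))
  write_design(design, file.path(in_dir, "design.tsv"))

  planted <- names(sim$truth$de_genes)
  up_planted <- planted[vapply(sim$truth$de_genes,
                               function(e) all(e > 0), logical(1))]
  prom <- generate_promoters(n_genes = n_genes,
                             planted_genes = up_planted,
                             seed = derive_seed(seed, 2L))
  write_promoters_fasta(prom$promoters, file.path(in_dir, "promoters.fasta"))

  go <- generate_go_universe(n_genes = n_genes, study_set = up_planted,
                             enrichment_boost = 20,
                             seed = derive_seed(seed, 3L))
  write_go_graph(go$graph, file.path(in_dir, "go_dag.tsv"))
  write_annotations(go$annotations, file.path(in_dir, "go_annotations.tsv"))

  cult <- generate_culture(seed = derive_seed(seed, 4L))
  write_culture_csv(cult$culture, file.path(in_dir, "culture.csv"))

  jsonlite::write_json(
    list(de_genes = sim$truth$de_genes, motif_genes = prom$truth$motif_genes,
         enriched_term = go$truth$enriched_term,
         kinetics = cult$truth),
    file.path(in_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  cfg <- pipeline_config(
    probe_matrix = file.path(in_dir, "probes.tsv"),
    probe_map = file.path(in_dir, "probe_map.tsv"),
    design = file.path(in_dir, "design.tsv"),
    promoters = file.path(in_dir, "promoters.fasta"),
    go_dag = file.path(in_dir, "go_dag.tsv"),
    go_annotations = file.path(in_dir, "go_annotations.tsv"),
    culture = file.path(in_dir, "culture.csv"),
    seed = seed)
  run_pipeline(cfg, out_dir)
}
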