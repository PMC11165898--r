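#' Pipeline run configuration
#'
#' Bundles every input path and threshold of the full analysis. Inputs are
#' the fixture-bundle formats: expression / biotype / groups TSVs, a
#' miRNA-target TSV, and a GMT collection (see [write_fixture_bundle()]).
#'
#' @param expression,biotypes,groups,mir_targets,gene_sets input file paths.
#' @param out_dir output directory for all stage files and the run report.
#' @param fc_threshold,alpha differential-expression gates (log2 fold
#'   change, BH level); defaults 1.5 and 0.05.
#' @param r_threshold,p_threshold co-expression edge thresholds (defaults
#'   0.9 and 0.01).
#' @param diffk_threshold |DiffK| flag threshold (default 0.7).
#' @param top_fraction,pair_p ceRNA pair percentile and correlation-p gates
#'   (defaults 0.05, 0.05).
#' @param cerna_scope `"all"` (default): candidate pairs are all lncRNA x
#'   mRNA pairs; `"de"`: only differentially expressed lncRNAs/mRNAs.
#' @param degree_min,bc_reference hub rule (degree strictly above
#'   `degree_min`, betweenness strictly above the `bc_reference` statistic);
#'   defaults 5 and `"median"`.
#' @param soft_powers,min_module_size,merge_threshold,cut_height module
#'   detection controls; defaults 1:20, 5, 0.3, 0.99.
#' @param seed integer recorded in the report (all analysis stages are
#'   deterministic; randomness lives only in the synthetic generator).
#' @return A `run_config` list.
#' @export
run_config <- function(expression, biotypes, groups, mir_targets,
                       gene_sets, out_dir,
                       fc_threshold = 1.5, alpha = 0.05,
                       r_threshold = 0.9, p_threshold = 0.01,
                       diffk_threshold = 0.7,
                       top_fraction = 0.05, pair_p = 0.05,
                       cerna_scope = c("all", "de"),
                       degree_min = 5, bc_reference = "median",
                       soft_powers = 1:20, min_module_size = 5,
                       merge_threshold = 0.3, cut_height = 0.99,
                       seed = 1) {
  cfg <- list(expression = expression, biotypes = biotypes, groups = groups,
              mir_targets = mir_targets, gene_sets = gene_sets,
              out_dir = out_dir,
              fc_threshold = fc_threshold, alpha = alpha,
              r_threshold = r_threshold, p_threshold = p_threshold,
              diffk_threshold = diffk_threshold,
              top_fraction = top_fraction, pair_p = pair_p,
              cerna_scope = match.arg(cerna_scope),
              degree_min = degree_min, bc_reference = bc_reference,
              soft_powers = soft_powers,
              min_module_size = min_module_size,
              merge_threshold = merge_threshold, cut_height = cut_height,
              seed = as.integer(seed))
  stopifnot(cfg$alpha >= 0, cfg$alpha <= 1,
            cfg$top_fraction >= 0, cfg$top_fraction <= 1,
            cfg$r_threshold >= 0, cfg$diffk_threshold >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; missing keys take the
#' defaults. Relative input paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (f in c("expression", "biotypes", "groups", "mir_targets",
              "gene_sets", "out_dir")) {
    if (!is.null(vals[[f]]) && !grepl("^(/|[A-Za-z]:)", vals[[f]]))
      vals[[f]] <- file.path(base, vals[[f]])
  }
  do.call(run_config, vals)
}

run_stage <- function(name, fun) {
  tryCatch(fun(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full regulatory-network pipeline
#'
#' Executes the stages in dependency order — load, differential expression,
#' condition-specific co-expression networks, DiffK, ceRNA pair/triple
#' discovery, hub calling, module detection, gene-set enrichment — writing
#' each stage's outputs before the next starts, and ends with a
#' machine-readable run report (`report.json`). All stages are
#' deterministic: two runs on identical inputs produce byte-identical
#' outputs except for the report's isolated `timestamp` field.
#'
#' @param config a [run_config()].
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("expression", "biotypes", "groups", "mir_targets",
              "gene_sets"))
    if (!file.exists(config[[f]]))
      stop("config error: input '", f, "' not found at ", config[[f]])
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  stages <- character(0)
  counts <- list()

  dataset <- run_stage("load", function()
    read_expression(config$expression, config$biotypes, config$groups))
  mir_targets <- run_stage("load", function()
    read_mir_targets(config$mir_targets))
  gene_sets <- run_stage("load", function() read_gmt(config$gene_sets))
  stages <- c(stages, "load")

  ## differential expression
  de <- run_stage("de", function()
    call_degs(dataset, config$fc_threshold, config$alpha))
  run_stage("de", function() {
    lines <- c("gene_id\tbiotype\tlog2fc\tp_raw\tp_adj\tcall",
               paste(de$gene_id, de$biotype, fmt_num(de$log2fc),
                     fmt_num(de$p_raw), fmt_num(de$p_adj), de$call,
                     sep = "\t"))
    writeLines(lines, out("de.tsv"))
  })
  stages <- c(stages, "de")
  for (bt in c("mRNA", "lncRNA", "miRNA")) {
    counts[[paste0("n_de_up_", bt)]] <-
      sum(de$call == "up" & de$biotype == bt)
    counts[[paste0("n_de_down_", bt)]] <-
      sum(de$call == "down" & de$biotype == bt)
  }

  ## condition-specific co-expression networks over lncRNA + mRNA
  coexpr_nodes <- genes_by_biotype(dataset, c("mRNA", "lncRNA"))
  nets <- run_stage("coexpr", function() {
    lapply(c(control = "control", case = "case"), function(gr) {
      net <- build_network(dataset, coexpr_nodes,
                           r_threshold = config$r_threshold,
                           p_threshold = config$p_threshold, group = gr)
      write_edge_table(net, out(paste0("coexpr_", gr, "_edges.tsv")))
      write_network_sif(net, out(paste0("coexpr_", gr, ".sif")))
      net
    })
  })
  stages <- c(stages, "coexpr")
  counts$n_edges_control <- nrow(nets$control$edges)
  counts$n_edges_case <- nrow(nets$case$edges)

  ## DiffK
  dk <- run_stage("diffk", function() {
    tb <- diffk_table(nets$control, nets$case, config$diffk_threshold)
    writeLines(c("gene_id\tk_control\tk_case\tdiffk\tflagged",
                 paste(tb$gene_id, fmt_num(tb$k_control),
                       fmt_num(tb$k_case), fmt_num(tb$diffk),
                       tolower(tb$flagged), sep = "\t")),
               out("diffk.tsv"))
    tb
  })
  stages <- c(stages, "diffk")
  counts$n_diffk_flagged <- sum(dk$flagged)

  ## ceRNA pairs, triples, graph
  cand_lnc <- if (config$cerna_scope == "de")
    de$gene_id[de$biotype == "lncRNA" & de$call != "unchanged"]
  else genes_by_biotype(dataset, "lncRNA")
  cand_mrna <- if (config$cerna_scope == "de")
    de$gene_id[de$biotype == "mRNA" & de$call != "unchanged"]
  else genes_by_biotype(dataset, "mRNA")
  cerna <- run_stage("cerna", function() {
    if (length(cand_lnc) == 0 || length(cand_mrna) == 0) {
      pairs <- data.frame(lncrna = character(0), mrna = character(0),
                          pcc = numeric(0), p = numeric(0),
                          pcc_rank_fraction = numeric(0))
    } else {
      pairs <- codysregulated_pairs(cand_lnc, cand_mrna, dataset,
                                    top_fraction = config$top_fraction,
                                    p_threshold = config$pair_p)
    }
    triples <- confirm_triples(pairs, mir_targets)
    writeLines(c("lncrna\tmrna\tpcc\tp\tpcc_rank_fraction",
                 if (nrow(pairs))
                   paste(pairs$lncrna, pairs$mrna, fmt_num(pairs$pcc),
                         fmt_num(pairs$p),
                         fmt_num(pairs$pcc_rank_fraction), sep = "\t")),
               out("cerna_pairs.tsv"))
    writeLines(c("lncrna\tmirna\tmrna",
                 if (nrow(triples))
                   paste(triples$lncrna, triples$mirna, triples$mrna,
                         sep = "\t")),
               out("cerna_triples.tsv"))
    graph <- assemble_cerna_graph(triples)
    write_network_sif(graph, out("cerna.sif"))
    list(pairs = pairs, triples = triples, graph = graph)
  })
  stages <- c(stages, "cerna")
  counts$n_pairs <- nrow(cerna$pairs)
  counts$n_triples <- nrow(cerna$triples)

  ## hubs on the ceRNA graph
  hubs <- run_stage("hubs", function() {
    if (length(cerna$graph$nodes) == 0) {
      hb <- data.frame(node = character(0), degree = integer(0),
                       betweenness = numeric(0), is_hub = logical(0))
    } else {
      hb <- call_hubs(cerna$graph, degree_min = config$degree_min,
                      bc_reference = config$bc_reference)
    }
    writeLines(c("node\tdegree\tbetweenness\tis_hub",
                 if (nrow(hb))
                   paste(hb$node, hb$degree, fmt_num(hb$betweenness),
                         tolower(hb$is_hub), sep = "\t")),
               out("hubs.tsv"))
    hb
  })
  stages <- c(stages, "hubs")
  counts$n_hubs <- sum(hubs$is_hub)

  ## co-expression modules over lncRNA + mRNA genes
  wg <- run_stage("wgcna", function() {
    expr <- dataset$values[coexpr_nodes, , drop = FALSE]
    st <- pick_soft_threshold(expr, candidates = config$soft_powers)
    adj <- adjacency_matrix(expr, st$power)
    tom <- tom_similarity(adj)
    labels <- detect_modules(1 - tom,
                             min_module_size = config$min_module_size,
                             cut_height = config$cut_height)
    merged <- merge_close_modules(expr, labels,
                                  dissim_threshold = config$merge_threshold)
    trait <- as.numeric(dataset$group[colnames(expr)] == "case")
    mt <- module_trait_correlation(expr, merged$labels, trait)
    writeLines(c("power\tr2\tmean_k",
                 paste(st$scan$power, fmt_num(st$scan$r2),
                       fmt_num(st$scan$mean_k), sep = "\t")),
               out("soft_threshold.tsv"))
    writeLines(c("gene_id\tmodule",
                 paste(names(merged$labels), merged$labels, sep = "\t")),
               out("modules.tsv"))
    eg <- merged$eigengenes
    writeLines(c(paste(c("sample_id", colnames(eg)), collapse = "\t"),
                 vapply(seq_len(nrow(eg)), function(i)
                   paste(c(colnames(expr)[i], fmt_num(eg[i, ])),
                         collapse = "\t"), "")),
               out("eigengenes.tsv"))
    writeLines(c("module\tr\tp",
                 if (nrow(mt)) paste(mt$module, fmt_num(mt$r),
                                     fmt_num(mt$p), sep = "\t")),
               out("module_trait.tsv"))
    list(power = st$power, labels = merged$labels, trait_cor = mt)
  })
  stages <- c(stages, "wgcna")
  counts$n_modules <- length(setdiff(unique(wg$labels), "grey"))

  ## over-representation of DE genes against the gene-set collection
  enr <- run_stage("enrich", function() {
    query <- de$gene_id[de$call != "unchanged"]
    res <- hypergeom_enrich(query, gene_sets,
                            universe_genes = de$gene_id)
    writeLines(
      c("set\toverlap\tk\tn\tK\tN\tp\tp_adj\todds_ratio\tcombined_score",
        if (nrow(res))
          paste(res$set, res$overlap, res$k, res$n, res$K, res$N,
                fmt_num(res$p), fmt_num(res$p_adj), fmt_num(res$odds_ratio),
                fmt_num(res$combined_score), sep = "\t")),
      out("enrichment.tsv"))
    res
  })
  stages <- c(stages, "enrich")
  counts$n_enriched <- sum(enr$p_adj <= 0.05)

  report <- list(
    config = config[setdiff(names(config), "out_dir")],
    counts = counts,
    stages = stages,
    soft_power = wg$power,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(report$config) <- NULL
  write_report_json(report, out("report.json"))
  invisible(report)
}
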