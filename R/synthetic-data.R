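#' Simulation configuration for the synthetic two-condition generator
#'
#' Parameters of the generative model used by [generate_dataset()]. The model
#' emulates a two-group microarray-style study on the log2-intensity scale:
#' Gaussian baselines, latent-factor co-expression modules, planted
#' differential expression, planted ceRNA (lncRNA--miRNA--mRNA) repression
#' triples, and between-condition network rewiring.
#'
#' @param n_mrna,n_lncrna,n_mirna gene counts per biotype.
#' @param n_case,n_control sample counts per group.
#' @param frac_de fraction of genes planted as differentially expressed,
#'   in \[0, 1\].
#' @param de_shift log2-unit shift added to case samples of DE genes
#'   (sign alternating, so both up- and down-regulated truth exists).
#' @param noise_sd standard deviation of i.i.d. Gaussian noise (log2 units).
#' @param n_modules,module_size number and size of planted co-expression
#'   modules; each module shares a per-sample latent factor.
#' @param loading factor loading of module genes on their latent factor.
#' @param n_triples number of planted ceRNA triples. Each triple's miRNA
#'   carries a dedicated unit-variance latent activity; its lncRNA and mRNA
#'   targets subtract `repression_gamma` times the centered miRNA profile,
#'   inducing miRNA--target anticorrelation and lncRNA--mRNA positive
#'   correlation.
#' @param repression_gamma repression strength (unitless).
#' @param n_rewired number of genes whose co-expression is condition
#'   specific: they load on module 1's factor (or a dedicated factor when
#'   `n_modules == 0`) in control samples only, so their network degree
#'   collapses in the case network.
#' @param seed integer RNG seed; identical configs give bit-identical output.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mrna = 200, n_lncrna = 30, n_mirna = 20,
                       n_case = 10, n_control = 10,
                       frac_de = 0.1, de_shift = 2, noise_sd = 0.3,
                       n_modules = 3, module_size = 30, loading = 1,
                       n_triples = 5, repression_gamma = 1.5,
                       n_rewired = 5, seed = 1) {
  cfg <- list(n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_case = n_case, n_control = n_control,
              frac_de = frac_de, de_shift = de_shift, noise_sd = noise_sd,
              n_modules = n_modules, module_size = module_size,
              loading = loading, n_triples = n_triples,
              repression_gamma = repression_gamma,
              n_rewired = n_rewired, seed = as.integer(seed))
  counts <- c("n_mrna", "n_lncrna", "n_mirna", "n_case", "n_control",
              "n_modules", "module_size", "n_triples", "n_rewired")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop("'", f, "' must be a single non-negative count")
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop("'frac_de' must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (cfg$n_modules > 0 && cfg$module_size < 3)
    stop("'module_size' must be >= 3 when modules are planted")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic two-condition dataset with known ground truth
#'
#' Draws a log2 expression matrix under the model described in
#' [sim_config()], together with the ground truth needed to score every
#' downstream stage and a miRNA-target interaction table (planted edges plus
#' decoys at a 2:1 ratio).
#'
#' Generative steps, in order: baseline `b_g ~ N(8, 2)`; module genes add
#' `loading * f[m, s]` with `f[m, s] ~ N(0, 1)` shared per module and sample;
#' rewired genes add the same term in control samples only; DE genes add
#' `de_shift` (alternating sign) to case samples; each planted miRNA adds a
#' dedicated `N(0, 1)` activity; i.i.d. `N(0, noise_sd)` noise everywhere;
#' finally each triple's lncRNA and mRNA subtract
#' `repression_gamma * (miRNA profile - mean)`.
#'
#' Triple lncRNA/mRNA members are enrolled first into the DE set (both
#' shifted up; their miRNA down) so the ceRNA stage is reachable from the DE
#' screen; remaining DE slots are filled from genes outside all planted
#' structures. Decoy target edges are drawn only from miRNAs not in any
#' triple, and each decoy miRNA targets a single biotype, so no decoy triple
#' (a non-planted lncRNA/mRNA pair sharing a miRNA) can arise.
#'
#' @param config a [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{dataset}{an [expression_dataset()]}
#'     \item{truth}{list: `de` (data.frame gene_id, shift), `module_map`
#'       (named character gene -> module label), `triples` (data.frame
#'       lncrna, mirna, mrna), `rewired` (character vector), `config`}
#'     \item{mir_targets}{data.frame mirna_id, target_id, source}
#'   }
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(seed = 1))
#' dim(sim$dataset$values)
#' head(sim$truth$triples)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_genes <- cfg$n_mrna + cfg$n_lncrna + cfg$n_mirna
  n_samples <- cfg$n_case + cfg$n_control
  if (n_genes < 1) stop("config infeasible: no genes")
  if (n_samples < 4) stop("config infeasible: need >= 4 samples")
  if (cfg$n_triples > min(cfg$n_lncrna, cfg$n_mirna, cfg$n_mrna))
    stop("config infeasible: n_triples exceeds available genes of some biotype")
  n_structured_mrna <- cfg$n_modules * cfg$module_size + cfg$n_rewired +
    cfg$n_triples
  if (n_structured_mrna > cfg$n_mrna)
    stop("config infeasible: modules + rewired + triples need ",
         n_structured_mrna, " mRNAs but only ", cfg$n_mrna, " available")

  pad <- function(prefix, n) {
    if (n == 0) return(character(0))
    sprintf("%s_%0*d", prefix, max(3L, nchar(n)), seq_len(n))
  }
  mrna_ids <- pad("mRNA", cfg$n_mrna)
  lnc_ids <- pad("lnc", cfg$n_lncrna)
  mir_ids <- pad("miR", cfg$n_mirna)
  genes <- c(mrna_ids, lnc_ids, mir_ids)
  biotype <- stats::setNames(
    rep(c("mRNA", "lncRNA", "miRNA"),
        c(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna)), genes)
  samples <- c(pad("case", cfg$n_case), pad("ctrl", cfg$n_control))
  group <- stats::setNames(
    rep(c("case", "control"), c(cfg$n_case, cfg$n_control)), samples)
  is_case <- group == "case"

  ## deterministic layout: modules, then rewired, then triple mRNAs, within
  ## the mRNA block; triple lncRNAs/miRNAs lead their blocks
  module_map <- character(0)
  module_genes <- character(0)
  if (cfg$n_modules > 0) {
    module_genes <- mrna_ids[seq_len(cfg$n_modules * cfg$module_size)]
    module_map <- stats::setNames(
      rep(paste0("M", seq_len(cfg$n_modules)), each = cfg$module_size),
      module_genes)
  }
  rewired <- if (cfg$n_rewired > 0)
    mrna_ids[cfg$n_modules * cfg$module_size + seq_len(cfg$n_rewired)]
  else character(0)
  triples <- if (cfg$n_triples > 0) {
    data.frame(
      lncrna = lnc_ids[seq_len(cfg$n_triples)],
      mirna = mir_ids[seq_len(cfg$n_triples)],
      mrna = mrna_ids[cfg$n_modules * cfg$module_size + cfg$n_rewired +
                        seq_len(cfg$n_triples)],
      stringsAsFactors = FALSE)
  } else {
    data.frame(lncrna = character(0), mirna = character(0),
               mrna = character(0), stringsAsFactors = FALSE)
  }

  set.seed(cfg$seed)
  baseline <- stats::rnorm(n_genes, mean = 8, sd = 2)
  expr <- matrix(baseline, n_genes, n_samples,
                 dimnames = list(genes, samples))

  if (cfg$n_modules > 0) {
    factors <- matrix(stats::rnorm(cfg$n_modules * n_samples),
                      cfg$n_modules, n_samples)
    for (m in seq_len(cfg$n_modules)) {
      idx <- which(module_map == paste0("M", m))
      expr[module_genes[idx], ] <- expr[module_genes[idx], , drop = FALSE] +
        cfg$loading * matrix(factors[m, ], length(idx), n_samples,
                             byrow = TRUE)
    }
  }
  if (length(rewired)) {
    rew_factor <- if (cfg$n_modules > 0) factors[1, ]
      else stats::rnorm(n_samples)
    ctrl_factor <- ifelse(is_case, 0, rew_factor)
    expr[rewired, ] <- expr[rewired, , drop = FALSE] +
      cfg$loading * matrix(ctrl_factor, length(rewired), n_samples,
                           byrow = TRUE)
  }

  ## DE truth: triple members first (lncRNA/mRNA up, miRNA down), then a
  ## random draw from unstructured genes, signs alternating
  n_de <- round(cfg$frac_de * n_genes)
  de_genes <- character(0)
  de_shifts <- numeric(0)
  if (n_de > 0 && cfg$de_shift != 0) {
    triple_members <- as.vector(rbind(triples$lncrna, triples$mrna,
                                      triples$mirna))
    triple_sign <- rep(c(1, 1, -1), times = nrow(triples))
    take <- min(length(triple_members), n_de)
    de_genes <- triple_members[seq_len(take)]
    de_shifts <- cfg$de_shift * triple_sign[seq_len(take)]
    n_extra <- n_de - take
    if (n_extra > 0) {
      pool <- setdiff(genes, c(module_genes, rewired, triple_members))
      if (n_extra > length(pool))
        stop("config infeasible: not enough unstructured genes for frac_de")
      extra <- sample(pool, n_extra)
      de_genes <- c(de_genes, extra)
      de_shifts <- c(de_shifts,
                     cfg$de_shift * rep_len(c(1, -1), n_extra))
    }
    expr[de_genes, is_case] <- expr[de_genes, is_case, drop = FALSE] +
      de_shifts
  }

  ## planted miRNA latent activity (unit variance) before noise
  if (cfg$n_triples > 0) {
    activity <- matrix(stats::rnorm(cfg$n_triples * n_samples),
                       cfg$n_triples, n_samples)
    expr[triples$mirna, ] <- expr[triples$mirna, , drop = FALSE] + activity
  }

  expr <- expr + matrix(stats::rnorm(n_genes * n_samples, sd = cfg$noise_sd),
                        n_genes, n_samples)

  ## repression: targets subtract gamma * centered miRNA profile
  if (cfg$n_triples > 0) {
    for (i in seq_len(cfg$n_triples)) {
      mprof <- expr[triples$mirna[i], ]
      centered <- mprof - mean(mprof)
      expr[triples$lncrna[i], ] <- expr[triples$lncrna[i], ] -
        cfg$repression_gamma * centered
      expr[triples$mrna[i], ] <- expr[triples$mrna[i], ] -
        cfg$repression_gamma * centered
    }
  }

  dataset <- expression_dataset(expr, biotype, group)
  truth <- list(
    de = data.frame(gene_id = de_genes, shift = de_shifts,
                    stringsAsFactors = FALSE),
    module_map = module_map,
    triples = triples,
    rewired = rewired,
    config = cfg)
  mir_targets <- build_mir_targets(triples, lnc_ids, mir_ids, mrna_ids)
  list(dataset = dataset, truth = truth, mir_targets = mir_targets)
}

## Planted edges (miRNA -> its lncRNA and mRNA) plus decoys at 2:1.
## Decoys use only non-planted miRNAs and each decoy miRNA targets a single
## biotype, so no non-planted (lncRNA, mRNA) pair ever shares a miRNA.
build_mir_targets <- function(triples, lnc_ids, mir_ids, mrna_ids) {
  planted <- data.frame(
    mirna_id = rep(triples$mirna, each = 2),
    target_id = as.vector(rbind(triples$lncrna, triples$mrna)),
    source = rep("planted", 2 * nrow(triples)), stringsAsFactors = FALSE)
  free_mirs <- setdiff(mir_ids, triples$mirna)
  n_decoy <- 2 * nrow(planted)
  if (n_decoy == 0 || length(free_mirs) == 0) {
    decoy <- planted[0, ]
  } else {
    mir <- free_mirs[(seq_len(n_decoy) - 1) %% length(free_mirs) + 1]
    lnc_pool <- setdiff(lnc_ids, triples$lncrna)
    mrna_pool <- setdiff(mrna_ids, triples$mrna)
    target <- character(n_decoy)
    use_lnc <- (match(mir, free_mirs) %% 2 == 1) & length(lnc_pool) > 0
    k_l <- cumsum(use_lnc)
    k_m <- cumsum(!use_lnc)
    for (j in seq_len(n_decoy)) {
      target[j] <- if (use_lnc[j])
        lnc_pool[(k_l[j] - 1) %% length(lnc_pool) + 1]
      else mrna_pool[(k_m[j] - 1) %% length(mrna_pool) + 1]
    }
    decoy <- data.frame(mirna_id = mir, target_id = target,
                        source = "decoy", stringsAsFactors = FALSE)
    decoy <- decoy[!duplicated(decoy[c("mirna_id", "target_id")]), ]
  }
  out <- rbind(planted, decoy)
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to a self-contained fixture bundle
#'
#' Writes the expression matrix, sample groups, gene biotypes, miRNA-target
#' table, module gene sets (GMT) and ground truth (JSON) to plain-text files,
#' plus a manifest. Repeated calls with the same inputs produce byte-identical
#' files.
#'
#' @param sim result of [generate_dataset()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest list (files written and seed).
#' @export
write_fixture_bundle <- function(sim, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir)
  ds <- sim$dataset
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    biotypes = file.path(out_dir, "biotypes.tsv"),
    mir_targets = file.path(out_dir, "mir_targets.tsv"),
    gene_sets = file.path(out_dir, "modules.gmt"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.json"))

  write_expression(ds, paths$expression, paths$biotypes, paths$groups)
  write_mir_targets(sim$mir_targets, paths$mir_targets)

  mm <- sim$truth$module_map
  sets <- lapply(split(names(mm), mm), sort)
  write_gmt(sets, paths$gene_sets,
            descriptions = stats::setNames(
              rep("planted co-expression module", length(sets)), names(sets)))

  truth_json <- list(
    de = sim$truth$de,
    module_map = as.list(mm),
    triples = sim$truth$triples,
    rewired = sim$truth$rewired,
    seed = sim$truth$config$seed)
  write_report_json(truth_json, paths$truth)

  manifest <- list(files = sort(vapply(paths[setdiff(names(paths),
                                                     "manifest")],
                                       basename, "")),
                   seed = sim$truth$config$seed)
  write_report_json(manifest, paths$manifest)
  invisible(manifest)
}
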