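#' Co-dysregulated lncRNA-mRNA pairs by top-percentile correlation
#'
#' Computes the Pearson correlation for every (lncRNA, mRNA) candidate pair
#' and keeps pairs whose PCC is strictly above the `1 - top_fraction`
#' quantile of all candidate PCCs and whose correlation p-value is below
#' `p_threshold`. Under the default `ranking = "signed"` the percentile is
#' taken over signed PCCs, so only strong positive co-expression survives
#' (the ceRNA expectation); `ranking = "absolute"` ranks by |PCC|.
#'
#' @param de_lncrnas,de_mrnas non-empty character vectors of candidate
#'   lncRNA and mRNA ids (e.g. the differentially expressed lists).
#' @param dataset an [expression_dataset()].
#' @param top_fraction retained upper tail of the PCC distribution
#'   (default 0.05, i.e. top 5 percent).
#' @param p_threshold correlation p-value cutoff (default 0.05).
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return data.frame with columns `lncrna`, `mrna`, `pcc`, `p`,
#'   `pcc_rank_fraction` (fraction of candidates with PCC >= this pair's),
#'   sorted by PCC descending.
#' @export
codysregulated_pairs <- function(de_lncrnas, de_mrnas, dataset,
                                 top_fraction = 0.05, p_threshold = 0.05,
                                 ranking = c("signed", "absolute")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  ranking <- match.arg(ranking)
  if (length(de_lncrnas) == 0 || length(de_mrnas) == 0)
    stop("empty candidate set: both DE lists must be non-empty")
  unknown <- setdiff(c(de_lncrnas, de_mrnas), rownames(dataset$values))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  de_lncrnas <- sort(unique(de_lncrnas))
  de_mrnas <- sort(unique(de_mrnas))
  n <- ncol(dataset$values)
  cm <- suppressWarnings(stats::cor(
    t(dataset$values[de_lncrnas, , drop = FALSE]),
    t(dataset$values[de_mrnas, , drop = FALSE])))
  cm[is.na(cm)] <- 0
  pairs <- expand.grid(lncrna = de_lncrnas, mrna = de_mrnas,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs$pcc <- as.vector(cm)
  pairs$p <- cor_pvalue(pairs$pcc, n)
  score <- if (ranking == "absolute") abs(pairs$pcc) else pairs$pcc
  cutoff <- stats::quantile(score, 1 - top_fraction, names = FALSE)
  rank_frac <- (rank(-score, ties.method = "min")) / nrow(pairs)
  ## strict-quantile rule; top_fraction = 1 keeps every candidate
  keep <- (if (top_fraction >= 1) rep(TRUE, nrow(pairs)) else score > cutoff) &
    pairs$p < p_threshold
  out <- pairs[keep, , drop = FALSE]
  out$pcc_rank_fraction <- rank_frac[keep]
  out <- out[order(-out$pcc, out$lncrna, out$mrna), ]
  rownames(out) <- NULL
  out
}

#' Confirm ceRNA triples by shared miRNA targeting
#'
#' For each co-dysregulated (lncRNA, mRNA) pair, emits one triple per miRNA
#' that targets both members in the interaction table; pairs with no shared
#' miRNA emit nothing.
#'
#' @param pairs data.frame from [codysregulated_pairs()] (columns `lncrna`,
#'   `mrna`, and optionally `pcc`, `p`).
#' @param mir_targets data.frame with columns `mirna_id`, `target_id` (as
#'   from [read_mir_targets()]).
#' @return data.frame with columns `lncrna`, `mirna`, `mrna` plus the pair's
#'   `pcc`/`p` when available, sorted by (lncrna, mirna, mrna).
#' @export
confirm_triples <- function(pairs, mir_targets) {
  by_target <- split(mir_targets$mirna_id, mir_targets$target_id)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    shared <- sort(intersect(by_target[[pairs$lncrna[i]]],
                             by_target[[pairs$mrna[i]]]))
    if (length(shared)) {
      row <- data.frame(lncrna = pairs$lncrna[i], mirna = shared,
                        mrna = pairs$mrna[i], stringsAsFactors = FALSE)
      if ("pcc" %in% names(pairs)) row$pcc <- pairs$pcc[i]
      if ("p" %in% names(pairs)) row$p <- pairs$p[i]
      res[[i]] <- row
    }
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    out <- data.frame(lncrna = character(0), mirna = character(0),
                      mrna = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the tripartite ceRNA graph
#'
#' Nodes are typed by biotype; edges are lncRNA--miRNA and miRNA--mRNA from
#' the confirmed triples (deduplicated). No direct lncRNA--mRNA edges are
#' added: that evidence lives on the triple records.
#'
#' @param triples data.frame from [confirm_triples()].
#' @return An object of class `cerna_graph`: list with `nodes`, `biotype`
#'   (named: lncRNA/miRNA/mRNA), and `edges` (data.frame `a`, `interaction`,
#'   `b`).
#' @export
assemble_cerna_graph <- function(triples) {
  nodes <- c(unique(triples$lncrna), unique(triples$mirna),
             unique(triples$mrna))
  biotype <- stats::setNames(
    rep(c("lncRNA", "miRNA", "mRNA"),
        c(length(unique(triples$lncrna)), length(unique(triples$mirna)),
          length(unique(triples$mrna)))),
    nodes)
  e1 <- unique(data.frame(a = triples$lncrna,
                          interaction = rep("lncRNA-miRNA", nrow(triples)),
                          b = triples$mirna, stringsAsFactors = FALSE))
  e2 <- unique(data.frame(a = triples$mirna,
                          interaction = rep("miRNA-mRNA", nrow(triples)),
                          b = triples$mrna, stringsAsFactors = FALSE))
  edges <- rbind(e1, e2)
  if (nrow(edges)) {
    edges <- edges[order(edges$a, edges$b), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = sort(nodes), biotype = biotype[sort(nodes)],
                 edges = edges),
            class = "cerna_graph")
}

#' @export
print.cerna_graph <- function(x, ...) {
  cat("cerna_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Call topological hubs by degree and betweenness
#'
#' A node is a hub when its degree is strictly above `degree_min` (the
#' "more than five connections" convention) and its exact betweenness
#' centrality is strictly above a network-level reference (by default the
#' median betweenness).
#'
#' @param graph a `cerna_graph`, `coexpr_network`, or igraph object.
#' @param degree_min minimum degree, exclusive (default 5).
#' @param bc_reference `"median"`, `"mean"`, or a numeric value.
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `is_hub`, sorted by degree descending then node id.
#' @export
call_hubs <- function(graph, degree_min = 5, bc_reference = "median") {
  g <- as_ncreg_igraph(graph)
  if (igraph::vcount(g) == 0) stop("graph is empty")
  deg <- igraph::degree(g)
  bc <- betweenness_centrality(g)
  ref <- if (is.numeric(bc_reference)) bc_reference
    else switch(match.arg(bc_reference, c("median", "mean")),
                median = stats::median(bc), mean = mean(bc))
  out <- data.frame(node = names(deg), degree = unname(deg),
                    betweenness = unname(bc),
                    is_hub = unname(deg > degree_min & bc > ref),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), ]
  rownames(out) <- NULL
  out
}
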