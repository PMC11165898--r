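#' Two-condition expression dataset
#'
#' Container for a log2-scale expression matrix (genes x samples) together
#' with a gene biotype map (mRNA / lncRNA / miRNA) and a sample group map
#' (case / control). All downstream stages — differential expression,
#' co-expression networks, ceRNA discovery, module detection — operate on
#' this object.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale, all finite.
#' @param biotype named character vector mapping every gene id to one of
#'   `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param group named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `biotype`, `group`.
#' @export
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(c("g1", "g2", "l1"), paste0("s", 1:4)))
#' ds <- expression_dataset(m,
#'   biotype = c(g1 = "mRNA", g2 = "mRNA", l1 = "lncRNA"),
#'   group = c(s1 = "case", s2 = "case", s3 = "control", s4 = "control"))
#' dim(ds$values)
expression_dataset <- function(values, biotype, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  genes <- rownames(values)
  samples <- colnames(values)
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite expression values present")

  missing_bt <- setdiff(genes, names(biotype))
  if (length(missing_bt))
    stop("genes without biotype: ", paste(missing_bt, collapse = ", "))
  biotype <- biotype[genes]
  bad_bt <- unique(biotype[!biotype %in% c("mRNA", "lncRNA", "miRNA")])
  if (length(bad_bt))
    stop("unknown biotype value(s): ", paste(bad_bt, collapse = ", "))

  missing_gr <- setdiff(samples, names(group))
  if (length(missing_gr))
    stop("samples without group: ", paste(missing_gr, collapse = ", "))
  group <- group[samples]
  bad_gr <- unique(group[!group %in% c("case", "control")])
  if (length(bad_gr))
    stop("unknown group value(s): ", paste(bad_gr, collapse = ", "))

  structure(list(values = values, biotype = biotype, group = group),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  bt <- table(factor(x$biotype, levels = c("mRNA", "lncRNA", "miRNA")))
  gr <- table(factor(x$group, levels = c("case", "control")))
  cat("ExpressionDataset:", nrow(x$values), "genes x",
      ncol(x$values), "samples (log2)\n")
  cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = " "), "\n")
  cat("  groups:  ", paste(names(gr), gr, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Select gene ids by biotype
#'
#' @param dataset an [expression_dataset()].
#' @param biotype one or more of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @return character vector of gene ids, in matrix order.
#' @export
genes_by_biotype <- function(dataset, biotype) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  names(dataset$biotype)[dataset$biotype %in% biotype]
}

#' Select sample ids by group
#'
#' @param dataset an [expression_dataset()].
#' @param group `"case"`, `"control"`, or both.
#' @return character vector of sample ids, in matrix order.
#' @export
samples_by_group <- function(dataset, group) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  names(dataset$group)[dataset$group %in% group]
}
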