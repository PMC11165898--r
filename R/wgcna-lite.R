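## Compact weighted co-expression module detection: soft-threshold scan,
## adjacency, topological overlap (TOM), fixed-height tree cut with minimum
## module size, eigengene computation, eigengene-based module merging, and
## module-trait correlation.

#' Soft-threshold (scale-free fit) scan
#'
#' For each candidate power beta, forms the adjacency `|cor(i, j)|^beta`
#' (or the signed variant), computes connectivities `k_i = sum_j a_ij`, bins
#' `log10(k)` into at most 10 equal-occupancy bins, and scores the linear
#' fit of `log10(frequency)` on `log10(mean k)`. Fits with non-negative
#' slope score 0 (an anti-scale-free fit is not rewarded). The chosen power
#' is the smallest candidate reaching `r2_target`, else the argmax R^2.
#'
#' @param dataset an [expression_dataset()] or a genes x samples matrix with
#'   >= 20 genes and >= 4 samples.
#' @param candidates integer powers to scan (default 1:20).
#' @param r2_target scale-free fit target (default 0.8).
#' @param type `"unsigned"` (default) or `"signed"` adjacency.
#' @return list with `scan` (data.frame `power`, `r2`, `mean_k`) and
#'   `power` (chosen beta).
#' @export
pick_soft_threshold <- function(dataset, candidates = 1:20,
                                r2_target = 0.8,
                                type = c("unsigned", "signed")) {
  type <- match.arg(type)
  expr <- if (inherits(dataset, "ExpressionDataset")) dataset$values
    else dataset
  if (nrow(expr) < 20) stop("need >= 20 genes for a soft-threshold scan")
  if (ncol(expr) < 4) stop("need >= 4 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene row(s): ",
         paste(rownames(expr)[sds == 0], collapse = ", "))
  cm <- stats::cor(t(expr))
  base <- if (type == "unsigned") abs(cm) else (1 + cm) / 2
  diag(base) <- 0
  scan <- data.frame(power = candidates, r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidates)) {
    a <- base^candidates[i]
    k <- rowSums(a)
    scan$mean_k[i] <- mean(k)
    scan$r2[i] <- scale_free_r2(k)
  }
  hit <- which(scan$r2 >= r2_target)
  chosen <- if (length(hit)) scan$power[hit[1]]
    else scan$power[which.max(scan$r2)]
  list(scan = scan, power = chosen)
}

## Scale-free topology fit: R^2 of log10(freq) ~ log10(mean k) over <= 10
## equal-width bins of connectivity (the standard scale-free fit index),
## zeroed when the fitted slope is non-negative so anti-scale-free degree
## distributions are never rewarded.
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 4) return(0)
  n_bins <- min(n_bins, length(unique(k)))
  if (n_bins < 3) return(0)
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 3) return(0)
  x <- log10(mean_k[ok])
  y <- log10(freq[ok] / length(k))
  fit <- stats::lm(y ~ x)
  if (stats::coef(fit)[2] >= 0) return(0)
  summary(fit)$r.squared
}

#' Weighted adjacency matrix
#'
#' `a_ij = |cor(i, j)|^power` (unsigned, default) or
#' `((1 + cor) / 2)^power` (signed), zero diagonal.
#'
#' @param dataset an [expression_dataset()] or genes x samples matrix.
#' @param power soft-threshold exponent.
#' @param type `"unsigned"` or `"signed"`.
#' @return symmetric gene x gene matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
adjacency_matrix <- function(dataset, power,
                             type = c("unsigned", "signed")) {
  type <- match.arg(type)
  expr <- if (inherits(dataset, "ExpressionDataset")) dataset$values
    else dataset
  cm <- stats::cor(t(expr))
  a <- if (type == "unsigned") abs(cm)^power else ((1 + cm) / 2)^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix (TOM)
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; diagonal 1. The
#' associated dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric numeric matrix, zero diagonal, entries in
#'   \[0, 1\].
#' @return TOM matrix (same dimnames), symmetric with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules by tree cut of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a fixed
#' height; clusters smaller than `min_module_size` are relabeled `"grey"`
#' (unassigned). Modules are labeled `"M1"`, `"M2"`, ... by decreasing size
#' (ties by first gene id), deterministically.
#'
#' @param dissimilarity square matrix, typically `1 - tom_similarity(a)`.
#' @param min_module_size smallest retained module (default 5).
#' @param cut_height tree cut height (default 0.99).
#' @return named character vector gene -> module label.
#' @export
detect_modules <- function(dissimilarity, min_module_size = 5,
                           cut_height = 0.99) {
  d <- dissimilarity
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("dissimilarity must be a square matrix")
  genes <- rownames(d)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(d)))
  if (nrow(d) == 1) return(stats::setNames("M1", genes))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- stats::setNames(rep("grey", length(cl)), genes)
  if (length(keep)) {
    first_gene <- vapply(keep, function(cid)
      genes[which(cl == as.integer(cid))[1]], "")
    ord <- keep[order(-sizes[keep], first_gene)]
    for (j in seq_along(ord))
      labels[cl == as.integer(ord[j])] <- paste0("M", j)
  }
  labels
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix
#' across samples, scaled to unit variance, sign fixed so its correlation
#' with the module's mean standardized profile is non-negative.
#'
#' @param dataset an [expression_dataset()] or genes x samples matrix.
#' @param module_genes >= 2 gene ids in the module.
#' @return named numeric per-sample vector with `sd = 1`.
#' @export
module_eigengene <- function(dataset, module_genes) {
  expr <- if (inherits(dataset, "ExpressionDataset")) dataset$values
    else dataset
  if (length(module_genes) < 2) stop("module needs >= 2 genes")
  x <- expr[module_genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0)) stop("module submatrix is constant")
  x <- x[sds > 0, , drop = FALSE]
  xs <- t(scale(t(x))) # standardize genes
  pc <- stats::prcomp(t(xs), center = FALSE, scale. = FALSE)
  me <- pc$x[, 1]
  me <- me / stats::sd(me)
  if (stats::cor(me, colMeans(xs)) < 0) me <- -me
  stats::setNames(me, colnames(expr))
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - cor(ME_i, ME_j)` while it is below `dissim_threshold`,
#' recomputing eigengenes after each merge. Grey (unassigned) genes are
#' never merged.
#'
#' @param dataset an [expression_dataset()] or genes x samples matrix.
#' @param labels named character vector from [detect_modules()].
#' @param dissim_threshold merge threshold on `1 - cor` (default 0.3).
#' @return list with `labels` (relabeled `"M1"`... by size), `eigengenes`
#'   (samples x modules matrix), and `merged_from` (list of merge events).
#' @export
merge_close_modules <- function(dataset, labels, dissim_threshold = 0.3) {
  expr <- if (inherits(dataset, "ExpressionDataset")) dataset$values
    else dataset
  history <- list()
  repeat {
    mods <- sort(setdiff(unique(labels), "grey"))
    if (length(mods) < 2) break
    me <- vapply(mods, function(m)
      module_eigengene(expr, names(labels)[labels == m]),
      numeric(ncol(expr)))
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[idx[1], idx[2]] >= dissim_threshold) break
    keep <- mods[min(idx)]
    drop <- mods[max(idx)]
    labels[labels == drop] <- keep
    history[[length(history) + 1]] <-
      list(merged = drop, into = keep,
           dissimilarity = d[idx[1], idx[2]])
  }
  ## relabel by size, deterministic
  mods <- setdiff(unique(labels), "grey")
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(labels == m), 0)
    first_gene <- vapply(mods, function(m)
      names(labels)[labels == m][1], "")
    ord <- mods[order(-sizes, first_gene)]
    new <- stats::setNames(paste0("M", seq_along(ord)), ord)
    labels[labels != "grey"] <- new[labels[labels != "grey"]]
  }
  mods <- sort(setdiff(unique(labels), "grey"))
  eig <- if (length(mods))
    vapply(mods, function(m)
      module_eigengene(expr, names(labels)[labels == m]),
      numeric(ncol(expr)))
  else matrix(numeric(0), ncol(expr), 0)
  list(labels = labels, eigengenes = eig, merged_from = history)
}

#' Module-trait correlation
#'
#' Pearson r and p of each module eigengene against a per-sample trait
#' (a case/control contrast coded 1/0, or any numeric covariate). Grey
#' genes are excluded.
#'
#' @param dataset an [expression_dataset()] or genes x samples matrix.
#' @param labels named character vector gene -> module label.
#' @param trait numeric vector, one value per sample (column).
#' @return data.frame with columns `module`, `r`, `p`.
#' @export
module_trait_correlation <- function(dataset, labels, trait) {
  expr <- if (inherits(dataset, "ExpressionDataset")) dataset$values
    else dataset
  if (length(trait) != ncol(expr))
    stop("trait length must equal sample count")
  if (stats::sd(trait) == 0) stop("trait is constant")
  mods <- sort(setdiff(unique(labels), "grey"))
  res <- lapply(mods, function(m) {
    me <- module_eigengene(expr, names(labels)[labels == m])
    ct <- stats::cor.test(me, trait)
    data.frame(module = m, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res)
    else data.frame(module = character(0), r = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}
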