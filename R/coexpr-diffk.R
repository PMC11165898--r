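#' Pearson correlation with a t-transform p-value
#'
#' Sample Pearson r with the two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom (the same
#' p [stats::cor.test()] reports). A constant vector yields r = 0, p = 1.
#'
#' @param x_values,y_values numeric vectors of equal length n >= 3, finite.
#' @return list with elements `r` and `p`.
#' @export
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8
pearson_with_p <- function(x_values, y_values) {
  n <- length(x_values)
  if (length(y_values) != n) stop("vectors must have equal length")
  if (n < 3) stop("need n >= 3 observations")
  if (!all(is.finite(x_values)) || !all(is.finite(y_values)))
    stop("values must be finite")
  if (stats::sd(x_values) == 0 || stats::sd(y_values) == 0)
    return(list(r = 0, p = 1))
  r <- stats::cor(x_values, y_values)
  list(r = r, p = cor_pvalue(r, n))
}

## two-sided p for a Pearson r at sample size n (vectorized)
cor_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- numeric(length(r))
  exact <- abs(r) >= 1
  p[exact] <- 0
  t <- abs(r[!exact]) * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(-t, n - 2)
  p
}

#' Build a thresholded co-expression network
#'
#' Computes Pearson correlations for every unordered pair of the requested
#' genes (optionally restricted to one sample group) and keeps edges with
#' `|r| >= r_threshold` and `p < p_threshold` (mode `"absolute"`), or
#' `r >= r_threshold` only (mode `"positive"`). The signed r is retained on
#' the edge; isolated nodes are kept.
#'
#' @param dataset an [expression_dataset()].
#' @param node_ids genes to include (must exist in the dataset).
#' @param r_threshold correlation threshold (default 0.9).
#' @param p_threshold correlation-test p threshold (default 0.01).
#' @param group optional `"case"` or `"control"` to use only that group's
#'   samples; `NULL` uses all samples.
#' @param mode `"absolute"` (default) or `"positive"` thresholding.
#' @return An object of class `coexpr_network`: list with `nodes`,
#'   `biotype`, `edges` (data.frame `a`, `b`, `pcc`, `p`; a < b), and the
#'   thresholds used.
#' @export
build_network <- function(dataset, node_ids, r_threshold = 0.9,
                          p_threshold = 0.01, group = NULL,
                          mode = c("absolute", "positive")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  mode <- match.arg(mode)
  unknown <- setdiff(node_ids, rownames(dataset$values))
  if (length(unknown))
    stop("unknown node id(s): ", paste(unknown, collapse = ", "))
  samples <- if (is.null(group)) colnames(dataset$values)
    else samples_by_group(dataset, group)
  if (length(samples) < 3) stop("need >= 3 samples in scope")
  node_ids <- sort(unique(node_ids))
  x <- t(dataset$values[node_ids, samples, drop = FALSE])
  n <- length(samples)
  cm <- suppressWarnings(stats::cor(x))
  cm[is.na(cm)] <- 0 # constant genes: no co-expression evidence

  keep <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[keep]
  p <- cor_pvalue(r, n)
  pass <- if (mode == "absolute") abs(r) >= r_threshold & p < p_threshold
    else r >= r_threshold & p < p_threshold
  edges <- data.frame(
    a = node_ids[keep[pass, 1]],
    b = node_ids[keep[pass, 2]],
    pcc = r[pass], p = p[pass], stringsAsFactors = FALSE)
  if (nrow(edges)) {
    swap <- edges$a > edges$b
    tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
    edges <- edges[order(edges$a, edges$b), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = node_ids,
                 biotype = dataset$biotype[node_ids],
                 edges = edges,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 mode = mode, group = group),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("coexpr_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (|r| >=", x$r_threshold, ", p <", x$p_threshold, ")\n")
  invisible(x)
}

#' Normalized degree of every node
#'
#' Degree divided by the network's maximum degree, in \[0, 1\]; all zeros
#' for an edgeless network.
#'
#' @param network a `coexpr_network` (or any list with `nodes` and an
#'   `edges` data.frame with columns `a`, `b`).
#' @return named numeric vector over `network$nodes`.
#' @export
normalized_degree <- function(network) {
  deg <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$a, network$edges$b))
    deg[names(tab)] <- as.numeric(tab)
  }
  mx <- max(deg)
  if (mx == 0) return(deg)
  deg / mx
}

#' Differential connectivity (DiffK) between condition networks
#'
#' For every node in the union of the two networks, DiffK is the case
#' normalized degree minus the control normalized degree; nodes absent from
#' one network contribute degree 0 there. Records are sorted by |DiffK|
#' descending (ties by gene id) and flagged when `|DiffK| > diffk_threshold`.
#'
#' @param network_control,network_case `coexpr_network` objects.
#' @param diffk_threshold flagging threshold (default 0.7).
#' @return data.frame with columns `gene_id`, `k_control`, `k_case`,
#'   `diffk`, `flagged`.
#' @export
diffk_table <- function(network_control, network_case,
                        diffk_threshold = 0.7) {
  nodes <- sort(union(network_control$nodes, network_case$nodes))
  k_ctrl <- stats::setNames(numeric(length(nodes)), nodes)
  k_case <- k_ctrl
  kc <- normalized_degree(network_control)
  k_ctrl[names(kc)] <- kc
  ka <- normalized_degree(network_case)
  k_case[names(ka)] <- ka
  diffk <- k_case - k_ctrl
  out <- data.frame(gene_id = nodes,
                    k_control = unname(k_ctrl), k_case = unname(k_case),
                    diffk = unname(diffk),
                    flagged = unname(abs(diffk) > diffk_threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$diffk), out$gene_id), ]
  rownames(out) <- NULL
  out
}
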