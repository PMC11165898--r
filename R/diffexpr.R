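#' Log2 fold change between two groups
#'
#' Mean(case) - mean(control) on the (already log2) expression scale.
#'
#' @param case_values,control_values numeric vectors, both non-empty.
#' @return log2 fold change (log2 units).
#' @export
#' @examples
#' log2_fold_change(c(9, 11), c(7, 9)) # 2
log2_fold_change <- function(case_values, control_values) {
  if (length(case_values) == 0 || length(control_values) == 0)
    stop("both groups must be non-empty")
  mean(case_values) - mean(control_values)
}

#' Two-sided Welch t-test p-value
#'
#' Unequal-variance two-sample test. When both groups are constant with
#' equal means the p-value is 1 (no evidence of a difference); constant
#' groups with different means give p = 0.
#'
#' @param case_values,control_values numeric vectors of length >= 2.
#' @return two-sided p-value.
#' @export
welch_t_pvalue <- function(case_values, control_values) {
  if (length(case_values) < 2 || length(control_values) < 2)
    stop("each group needs >= 2 values")
  v1 <- stats::var(case_values)
  v2 <- stats::var(control_values)
  if (v1 == 0 && v2 == 0) {
    return(if (mean(case_values) == mean(control_values)) 1 else 0)
  }
  stats::t.test(case_values, control_values, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with respect to input positions
#' and capped at 1. Shared by the differential-expression and enrichment
#' stages.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.005))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes
#'
#' Per-gene Welch t-test between case and control samples, BH adjustment
#' across genes, and fold-change gating. A gene is called `up` when
#' `log2fc > fc_threshold` and `p_adj <= alpha` (strict fold-change
#' inequality), `down` symmetrically, otherwise `unchanged`.
#'
#' Note on the fold-change scale: the screen this mirrors states its cutoff
#' ambiguously ("log 1.5 fold change (log2FC) > 1.5"); here the threshold is
#' on the log2 scale and is configurable.
#'
#' @param dataset an [expression_dataset()] with both groups present.
#' @param fc_threshold absolute log2 fold-change threshold (default 1.5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame with columns `gene_id`, `biotype`, `log2fc`, `p_raw`,
#'   `p_adj`, `call`, one row per gene in matrix order.
#' @export
call_degs <- function(dataset, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  case_ids <- samples_by_group(dataset, "case")
  ctrl_ids <- samples_by_group(dataset, "control")
  if (length(case_ids) < 2 || length(ctrl_ids) < 2)
    stop("each group needs >= 2 samples")
  x <- dataset$values[, case_ids, drop = FALSE]
  y <- dataset$values[, ctrl_ids, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  log2fc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               1)
  p_raw <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df),
                  ifelse(log2fc == 0, 1, 0))
  p_adj <- bh_adjust(p_raw)
  call <- ifelse(log2fc > fc_threshold & p_adj <= alpha, "up",
                 ifelse(log2fc < -fc_threshold & p_adj <= alpha, "down",
                        "unchanged"))
  data.frame(gene_id = rownames(dataset$values),
             biotype = unname(dataset$biotype),
             log2fc = unname(log2fc), p_raw = unname(p_raw),
             p_adj = unname(p_adj), call = unname(call),
             stringsAsFactors = FALSE)
}
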