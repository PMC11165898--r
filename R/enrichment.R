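#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under random draws from the universe. With overlap k, query size
#' n, set size K (after intersection with the universe) and universe size N,
#' the p-value is the upper hypergeometric tail `P(X >= k)`. The odds ratio
#' comes from the 2x2 table `(a = k, b = n - k, c = K - k,
#' d = N - n - K + k)`, with 0.5 added to every cell when any cell is zero
#' (Haldane correction); the combined score is `-ln(p) * OR`, an
#' Enrichr-style composite. BH adjustment is applied across sets.
#'
#' @param query_genes character vector, a subset of `universe_genes`
#'   (may be empty: every set then scores p = 1).
#' @param collection named list of gene sets, as from [read_gmt()] (each
#'   element a character vector or a list with a `genes` element).
#' @param universe_genes non-empty character vector of background genes.
#' @return data.frame with columns `set`, `overlap` (semicolon-joined
#'   genes), `k`, `n`, `K`, `N`, `p`, `p_adj`, `odds_ratio`,
#'   `combined_score`, sorted by p ascending (ties by set name).
#' @export
#' @examples
#' universe <- paste0("g", 1:20)
#' sets <- list(S = paste0("g", 1:5))
#' hypergeom_enrich(paste0("g", 1:5), sets, universe) # p = 1 / choose(20, 5)
hypergeom_enrich <- function(query_genes, collection, universe_genes) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0) stop("universe is empty")
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe_genes)
  if (length(outside))
    stop("query genes outside the universe: ",
         paste(outside, collapse = ", "))
  N <- length(universe_genes)
  n <- length(query_genes)
  rows <- lapply(names(collection), function(nm) {
    members <- collection[[nm]]
    if (is.list(members)) members <- members$genes
    members <- intersect(unique(members), universe_genes)
    K <- length(members)
    overlap <- sort(intersect(query_genes, members))
    k <- length(overlap)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c_ <- K - k; d <- N - n - K + k
    if (min(a, b, c_, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    }
    or <- (a * d) / (b * c_)
    data.frame(set = nm, overlap = paste(overlap, collapse = ";"),
               k = k, n = n, K = K, N = N, p = p,
               odds_ratio = or,
               combined_score = -log(p) * or,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), overlap = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      odds_ratio = numeric(0), combined_score = numeric(0)))
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$set),
             c("set", "overlap", "k", "n", "K", "N", "p", "p_adj",
               "odds_ratio", "combined_score")]
  rownames(out) <- NULL
  out
}
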