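## Independent brute-force oracles and small fixture builders used across
## the suite. Everything here is deliberately naive: BFS layer-by-layer path
## counting for betweenness, all-subsets clique checks for MCC, step-up by
## hand for BH, triple loops for TOM, exhaustive draws for the
## hypergeometric tail.

## ---- random graphs ---------------------------------------------------------

## Erdos-Renyi adjacency matrix with letter node names
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  a
}

igraph_from_adj <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

edges_from_adj <- function(a) {
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  data.frame(a = rownames(a)[idx[, 1]], b = rownames(a)[idx[, 2]],
             stringsAsFactors = FALSE)
}

## ---- shortest-path oracles -------------------------------------------------

## BFS distances from source s (index), Inf when unreachable
bfs_dist <- function(a, s) {
  n <- nrow(a)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(a[v, ] > 0)
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

## number of shortest s->t paths, by DP over distance layers
count_shortest <- function(a, d_s) {
  n <- nrow(a)
  sigma <- numeric(n)
  sigma[d_s == 0] <- 1
  for (dist in sort(unique(d_s[is.finite(d_s) & d_s > 0]))) {
    for (v in which(d_s == dist)) {
      preds <- which(a[v, ] > 0 & d_s == dist - 1)
      sigma[v] <- sum(sigma[preds])
    }
  }
  sigma
}

## unnormalized betweenness over unordered pairs, naive pair-by-pair
brute_betweenness <- function(a) {
  n <- nrow(a)
  bc <- numeric(n)
  dmat <- t(vapply(seq_len(n), function(s) bfs_dist(a, s), numeric(n)))
  smat <- t(vapply(seq_len(n), function(s)
    count_shortest(a, dmat[s, ]), numeric(n)))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dmat[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dmat[s, v]) && is.finite(dmat[v, t]) &&
          dmat[s, v] + dmat[v, t] == dmat[s, t]) {
        bc[v] <- bc[v] + smat[s, v] * smat[v, t] / smat[s, t]
      }
    }
  }
  stats::setNames(bc, rownames(a))
}

brute_closeness <- function(a) {
  n <- nrow(a)
  cl <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs_dist(a, v)
    d <- d[-v]
    reach <- sum(is.finite(d))
    cl[v] <- if (reach > 0) reach / sum(d[is.finite(d)]) else 0
  }
  stats::setNames(cl, rownames(a))
}

## ---- clique / MCC oracle ---------------------------------------------------

## all maximal cliques of size >= 2 by checking every vertex subset
brute_maximal_cliques <- function(a) {
  n <- nrow(a)
  is_clique <- function(s) {
    if (length(s) < 2) return(TRUE)
    all(a[s, s][upper.tri(diag(length(s)))] > 0)
  }
  subsets <- lapply(seq_len(2^n - 1), function(m)
    which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  cliques <- Filter(is_clique, subsets)
  keys <- vapply(cliques, function(s) paste(s, collapse = ","), "")
  maximal <- Filter(function(s) {
    !any(vapply(cliques, function(t)
      length(t) > length(s) && all(s %in% t), TRUE))
  }, cliques)
  Filter(function(s) length(s) >= 2, maximal)
}

brute_mcc <- function(a) {
  mcc <- stats::setNames(numeric(nrow(a)), rownames(a))
  for (cl in brute_maximal_cliques(a)) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  mcc
}

## ---- BH step-up oracle -----------------------------------------------------

bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  sorted <- p[ord]
  for (i in seq_len(n)) {
    adj[i] <- min(sorted[i:n] * n / (i:n))
  }
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

## ---- TOM triple-loop oracle ------------------------------------------------

tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

## ---- misc fixtures ---------------------------------------------------------

## tiny handmade dataset: ng genes x ns samples, half case / half control
toy_dataset <- function(ng = 6, ns = 8, seed = 42) {
  set.seed(seed)
  v <- matrix(rnorm(ng * ns, 8), ng, ns,
              dimnames = list(paste0("g", seq_len(ng)),
                              paste0("s", seq_len(ns))))
  bt <- rep_len(c("mRNA", "lncRNA", "miRNA"), ng)
  expression_dataset(
    v,
    biotype = stats::setNames(bt, rownames(v)),
    group = stats::setNames(rep(c("case", "control"), each = ns / 2),
                            colnames(v)))
}

## small module-structured expression matrix: n_mod blocks sharing a latent
## factor, plus noise genes; labels recoverable via truth_labels()
module_expr <- function(n_mod = 3, block = 20, n_noise = 20, n_samples = 20,
                        loading = 1, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  genes <- c(paste0("b", rep(seq_len(n_mod), each = block), "_",
                    rep(seq_len(block), n_mod)),
             if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  ## per-gene baseline, constant across samples
  v <- matrix(rnorm(length(genes), 8, 2), length(genes), n_samples,
              dimnames = list(genes, paste0("s", seq_len(n_samples))))
  for (m in seq_len(n_mod)) {
    f <- rnorm(n_samples)
    idx <- grep(paste0("^b", m, "_"), genes)
    v[idx, ] <- v[idx, ] + loading * matrix(f, length(idx), n_samples,
                                            byrow = TRUE)
  }
  v + matrix(rnorm(length(v), sd = noise_sd), nrow(v))
}

truth_labels <- function(genes) {
  ifelse(grepl("^b", genes), sub("_.*", "", genes), "grey")
}

## adjusted Rand index between two label vectors (pair-counting form)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- sum_i * sum_j / n2
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
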