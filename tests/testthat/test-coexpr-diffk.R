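test_that("Pearson r and p follow the t transform", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(6, 4, 2))$r, -1)
  res <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  ct <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$p, ct$p.value)
  ## constant vector convention
  expect_equal(pearson_with_p(rep(2, 5), 1:5), list(r = 0, p = 1))
  expect_error(pearson_with_p(1:2, 1:2), "n >= 3")
})

test_that("network construction applies both thresholds and keeps isolates", {
  ## 3 genes: g1~g2 strongly, g3 noise
  set.seed(9)
  f <- rnorm(20)
  v <- rbind(g1 = 8 + f + rnorm(20, sd = 0.1),
             g2 = 8 + f + rnorm(20, sd = 0.1),
             g3 = 8 + rnorm(20))
  colnames(v) <- paste0("s", 1:20)
  ds <- expression_dataset(
    v, stats::setNames(c("mRNA", "mRNA", "lncRNA"), rownames(v)),
    stats::setNames(rep(c("case", "control"), each = 10), colnames(v)))
  net <- build_network(ds, rownames(v), r_threshold = 0.9)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(c(net$edges$a, net$edges$b)), c("g1", "g2"))
  expect_length(net$nodes, 3) # isolate kept
  ## impossible threshold empties the edge set
  net2 <- build_network(ds, rownames(v), r_threshold = 1.01)
  expect_equal(nrow(net2$edges), 0)
  expect_error(build_network(ds, c("g1", "nope")), "nope")
  ## input order invariance
  net3 <- build_network(ds, rev(rownames(v)), r_threshold = 0.9)
  expect_identical(net$edges, net3$edges)
})

test_that("a planted module forms a single connected component", {
  sim <- generate_dataset(sim_config(
    n_mrna = 60, n_lncrna = 5, n_mirna = 5, n_modules = 1,
    module_size = 30, loading = 1, noise_sd = 0.2, frac_de = 0,
    n_triples = 0, n_rewired = 0, seed = 12))
  mod_genes <- names(sim$truth$module_map)
  net <- build_network(sim$dataset, mod_genes, r_threshold = 0.9)
  g <- igraph::graph_from_data_frame(net$edges[c("a", "b")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  expect_equal(igraph::count_components(g), 1)
})

test_that("normalized degree follows the max-degree convention", {
  star <- list(nodes = c("c", "l1", "l2", "l3", "l4"),
               edges = data.frame(a = "c", b = paste0("l", 1:4)))
  k <- normalized_degree(star)
  expect_equal(unname(k["c"]), 1)
  expect_equal(unname(k[paste0("l", 1:4)]), rep(0.25, 4))
  ## edgeless network: all zeros
  empty <- list(nodes = c("a", "b"), edges = data.frame(a = character(0),
                                                        b = character(0)))
  expect_equal(unname(normalized_degree(empty)), c(0, 0))
  ## 5-cycle: all degrees equal, all k = 1
  cyc <- list(nodes = letters[1:5],
              edges = data.frame(a = letters[1:5],
                                 b = letters[c(2:5, 1)]))
  expect_equal(unname(normalized_degree(cyc)), rep(1, 5))
})

test_that("DiffK is antisymmetric, sorted, and flags extreme rewiring", {
  n1 <- list(nodes = c("a", "b", "c"),
             edges = data.frame(a = c("a", "a"), b = c("b", "c")))
  n2 <- list(nodes = c("a", "b", "c"),
             edges = data.frame(a = "b", b = "c"))
  tb <- diffk_table(n1, n2)
  ## node a: k_control 1 -> k_case 0
  expect_equal(tb$diffk[tb$gene_id == "a"], -1)
  expect_true(tb$flagged[tb$gene_id == "a"])
  ## sorted by |diffk| descending
  expect_equal(tb$gene_id[1], "a")
  ## antisymmetry under exchanging the networks
  tb_swap <- diffk_table(n2, n1)
  m <- merge(tb, tb_swap, by = "gene_id")
  expect_equal(m$diffk.x, -m$diffk.y)
  ## identical networks: all zero, none flagged
  tb0 <- diffk_table(n1, n1)
  expect_true(all(tb0$diffk == 0))
  expect_false(any(tb0$flagged))
})

test_that("adding an edge never decreases the endpoints' normalized degree", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_adjacency(7, 0.4, seed = 100 + i)
    net <- list(nodes = rownames(a), edges = edges_from_adj(a))
    k0 <- normalized_degree(net)
    free <- which(upper.tri(a) & a == 0, arr.ind = TRUE)
    if (nrow(free) == 0) next
    pick <- free[1, ]
    a2 <- a
    a2[pick[1], pick[2]] <- a2[pick[2], pick[1]] <- 1L
    k1 <- normalized_degree(list(nodes = rownames(a2),
                                 edges = edges_from_adj(a2)))
    u <- rownames(a)[pick[1]]; v <- rownames(a)[pick[2]]
    expect_gte(k1[u], k0[u] - 1e-12)
    expect_gte(k1[v], k0[v] - 1e-12)
  }
})

test_that("rewired genes dominate the DiffK ranking on synthetic data", {
  sim <- generate_dataset(sim_config(loading = 1, noise_sd = 0.2,
                                     frac_de = 0, n_triples = 0, seed = 1))
  nodes <- genes_by_biotype(sim$dataset, c("mRNA", "lncRNA"))
  nc <- build_network(sim$dataset, nodes, group = "control")
  na <- build_network(sim$dataset, nodes, group = "case")
  tb <- diffk_table(nc, na)
  top <- tb$gene_id[seq_along(sim$truth$rewired)]
  expect_setequal(top, sim$truth$rewired)
  expect_true(all(tb$flagged[tb$gene_id %in% sim$truth$rewired]))
})
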