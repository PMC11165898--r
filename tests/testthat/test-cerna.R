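## dataset in which pair correlations are fully controlled
controlled_pair_dataset <- function(n_lnc, n_mrna, n_samples = 20,
                                    seed = 1) {
  set.seed(seed)
  ids <- c(paste0("L", seq_len(n_lnc)), paste0("M", seq_len(n_mrna)))
  v <- matrix(rnorm(length(ids) * n_samples, 8), length(ids), n_samples,
              dimnames = list(ids, paste0("s", seq_len(n_samples))))
  expression_dataset(
    v,
    biotype = stats::setNames(rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna)),
                              ids),
    group = stats::setNames(rep(c("case", "control"),
                                each = n_samples / 2),
                            colnames(v)))
}

test_that("the strict percentile rule keeps exactly the top tail", {
  ## 100 candidate pairs with distinct PCCs -> exactly 5 survive at top 5%
  ds <- controlled_pair_dataset(10, 10, seed = 2)
  pairs <- codysregulated_pairs(paste0("L", 1:10), paste0("M", 1:10), ds,
                                top_fraction = 0.05, p_threshold = 1)
  cm <- cor(t(ds$values[paste0("L", 1:10), ]),
            t(ds$values[paste0("M", 1:10), ]))
  expect_equal(length(unique(as.vector(cm))), 100) # distinct PCCs
  expect_equal(nrow(pairs), 5)
  ## survivors are the 5 largest PCCs, by a sort-based oracle
  expect_setequal(pairs$pcc, sort(as.vector(cm), decreasing = TRUE)[1:5])
})

test_that("top_fraction = 1 with open p threshold keeps every candidate", {
  ds <- controlled_pair_dataset(4, 6, seed = 3)
  pairs <- codysregulated_pairs(paste0("L", 1:4), paste0("M", 1:6), ds,
                                top_fraction = 1, p_threshold = 1)
  expect_equal(nrow(pairs), 24)
  expect_error(codysregulated_pairs(character(0), "M1", ds), "empty")
})

test_that("pair discovery is invariant to candidate order", {
  ds <- controlled_pair_dataset(6, 6, seed = 4)
  p1 <- codysregulated_pairs(paste0("L", 1:6), paste0("M", 1:6), ds,
                             top_fraction = 0.2, p_threshold = 1)
  p2 <- codysregulated_pairs(rev(paste0("L", 1:6)), rev(paste0("M", 1:6)),
                             ds, top_fraction = 0.2, p_threshold = 1)
  expect_identical(p1, p2)
})

test_that("shared-miRNA confirmation enumerates exactly the shared targets", {
  targets <- data.frame(
    mirna_id = c("miR-a", "miR-a", "miR-b", "miR-c", "miR-c"),
    target_id = c("L1", "M1", "M1", "L1", "M1"),
    source = "db", stringsAsFactors = FALSE)
  pair <- data.frame(lncrna = "L1", mrna = "M1", stringsAsFactors = FALSE)
  tr <- confirm_triples(pair, targets)
  ## two miRNAs (a, c) target both members -> exactly two triples
  expect_equal(nrow(tr), 2)
  expect_equal(tr$mirna, c("miR-a", "miR-c"))
  ## no shared miRNA -> nothing
  t2 <- data.frame(mirna_id = c("miR-a", "miR-b"),
                   target_id = c("L1", "M1"), source = "db")
  expect_equal(nrow(confirm_triples(pair, t2)), 0)
})

test_that("confirm_triples equals brute-force triple enumeration", {
  set.seed(17)
  for (rep in 1:10) {
    n_pairs <- sample(5:50, 1)
    lnc <- paste0("L", 1:12); mrna <- paste0("M", 1:12)
    mir <- paste0("miR-", 1:8)
    pairs <- unique(data.frame(
      lncrna = sample(lnc, n_pairs, TRUE),
      mrna = sample(mrna, n_pairs, TRUE), stringsAsFactors = FALSE))
    n_edges <- sample(20:200, 1)
    targets <- unique(data.frame(
      mirna_id = sample(mir, n_edges, TRUE),
      target_id = sample(c(lnc, mrna), n_edges, TRUE),
      source = "db", stringsAsFactors = FALSE))
    got <- confirm_triples(pairs, targets)
    ## brute force over the full cross product
    brute <- list()
    for (i in seq_len(nrow(pairs))) for (m in mir) {
      if (any(targets$mirna_id == m & targets$target_id == pairs$lncrna[i]) &&
          any(targets$mirna_id == m & targets$target_id == pairs$mrna[i]))
        brute[[length(brute) + 1]] <-
          paste(pairs$lncrna[i], m, pairs$mrna[i])
    }
    expect_setequal(paste(got$lncrna, got$mirna, got$mrna),
                    unlist(brute))
  }
})

test_that("the ceRNA graph is tripartite with deduplicated edges", {
  tr1 <- data.frame(lncrna = "L1", mirna = "miR-a", mrna = "M1")
  g1 <- assemble_cerna_graph(tr1)
  expect_length(g1$nodes, 3)
  expect_equal(nrow(g1$edges), 2)
  ## two triples sharing one miRNA -> 5 nodes, 4 edges
  tr2 <- rbind(tr1, data.frame(lncrna = "L2", mirna = "miR-a", mrna = "M2"))
  g2 <- assemble_cerna_graph(tr2)
  expect_length(g2$nodes, 5)
  expect_equal(nrow(g2$edges), 4)
  ## no direct lncRNA-mRNA edges
  bt <- g2$biotype
  expect_false(any(bt[g2$edges$a] == "lncRNA" & bt[g2$edges$b] == "mRNA"))
  ## empty triple list -> empty graph
  g0 <- assemble_cerna_graph(tr1[0, ])
  expect_length(g0$nodes, 0)
  expect_equal(nrow(g0$edges), 0)
})

test_that("hub calls require both high degree and above-reference betweenness", {
  ## star K1,9: center degree 9, BC choose(9,2) = 36 -> unique hub
  star <- list(nodes = c("c", paste0("l", 1:9)),
               edges = data.frame(a = "c", b = paste0("l", 1:9)))
  hb <- call_hubs(star, degree_min = 5)
  expect_equal(hb$betweenness[hb$node == "c"], 36)
  expect_equal(hb$node[hb$is_hub], "c")
  ## complete graph K7: all BC = 0, none strictly above the median
  a <- matrix(1, 7, 7); diag(a) <- 0
  dimnames(a) <- list(LETTERS[1:7], LETTERS[1:7])
  hb7 <- call_hubs(list(nodes = LETTERS[1:7], edges = edges_from_adj(a)),
                   degree_min = 5)
  expect_false(any(hb7$is_hub))
  ## path P10: max degree 2, no hubs at degree_min = 5
  p10 <- list(nodes = letters[1:10],
              edges = data.frame(a = letters[1:9], b = letters[2:10]))
  expect_false(any(call_hubs(p10, degree_min = 5)$is_hub))
})

test_that("planted triples survive pair screening and confirmation", {
  sim <- generate_dataset(sim_config(noise_sd = 0.3, seed = 8))
  ds <- sim$dataset
  pairs <- codysregulated_pairs(genes_by_biotype(ds, "lncRNA"),
                                genes_by_biotype(ds, "mRNA"), ds)
  planted_keys <- paste(sim$truth$triples$lncrna, sim$truth$triples$mrna)
  expect_true(all(planted_keys %in% paste(pairs$lncrna, pairs$mrna)))
  tr <- confirm_triples(pairs, sim$mir_targets)
  expect_identical(paste(tr$lncrna, tr$mirna, tr$mrna),
                   paste(sim$truth$triples$lncrna, sim$truth$triples$mirna,
                         sim$truth$triples$mrna))
})
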