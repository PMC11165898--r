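test_that("TOM matches hand evaluation and the triple-loop oracle", {
  ## all-zero adjacency -> all off-diagonal TOM = 0
  z <- matrix(0, 4, 4)
  tz <- tom_similarity(z)
  expect_equal(tz[upper.tri(tz)], rep(0, 6))
  expect_equal(diag(tz), rep(1, 4))
  ## all-one 3x3 off-diagonal -> TOM = (1+1)/(2+1-1) = 1
  o <- matrix(1, 3, 3); diag(o) <- 0
  expect_equal(tom_similarity(o)[1, 2], 1)
  ## random matrices vs brute force
  for (i in 1:20) {
    set.seed(300 + i)
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(tom_similarity(a), tom_oracle(a), tolerance = 1e-12)
  }
  expect_error(tom_similarity(matrix(runif(9), 3, 3)), "symmetric")
  a_bad <- matrix(0, 3, 3); a_bad[1, 2] <- a_bad[2, 1] <- 2
  expect_error(tom_similarity(a_bad), "\\[0, 1\\]")
})

test_that("TOM stays in [0, 1] for random valid adjacencies", {
  for (i in 1:50) {
    set.seed(500 + i)
    n <- sample(3:10, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tom_similarity(a)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("soft-threshold scan prefers scale-free fits and honors forcing", {
  v <- module_expr(seed = 5)
  st <- pick_soft_threshold(v)
  expect_true(st$power %in% st$scan$power)
  expect_true(all(st$scan$r2 >= 0 & st$scan$r2 <= 1))
  ## structured data fits markedly better at the chosen power than at 1
  expect_gt(st$scan$r2[st$scan$power == st$power], st$scan$r2[1])
  ## mean connectivity decreases monotonically in the power
  expect_true(all(diff(st$scan$mean_k) < 0))
  ## single candidate is always chosen
  expect_equal(pick_soft_threshold(v, candidates = 6)$power, 6)
  ## uncorrelated noise at beta = 1: near-uniform connectivity, poor fit
  set.seed(6)
  noise <- matrix(rnorm(100 * 20), 100, 20,
                  dimnames = list(paste0("g", 1:100), paste0("s", 1:20)))
  st_noise <- pick_soft_threshold(noise, candidates = 1)
  expect_lt(st_noise$scan$r2[1], 0.8)
  ## constant rows are named
  bad <- noise; bad[3, ] <- 5
  expect_error(pick_soft_threshold(bad), "g3")
})

test_that("tree cut recovers planted blocks and greys out small clusters", {
  v <- module_expr(n_mod = 2, block = 15, n_noise = 0, seed = 7)
  tom <- tom_similarity(adjacency_matrix(v, 6))
  labels <- detect_modules(1 - tom, min_module_size = 5)
  expect_equal(length(setdiff(unique(labels), "grey")), 2)
  expect_equal(adjusted_rand(labels, truth_labels(names(labels))), 1)
  ## pure noise with a large min size: mostly grey
  set.seed(8)
  noise <- matrix(rnorm(100 * 20), 100, 20,
                  dimnames = list(paste0("g", 1:100), paste0("s", 1:20)))
  ln <- detect_modules(1 - tom_similarity(adjacency_matrix(noise, 6)),
                       min_module_size = 50)
  expect_gt(mean(ln == "grey"), 0.9)
})

test_that("eigengene is the unit-variance first PC with fixed sign", {
  v <- module_expr(n_mod = 1, block = 20, n_noise = 0, seed = 9)
  genes <- rownames(v)
  me <- module_eigengene(v, genes)
  expect_equal(sd(me), 1)
  xs <- t(scale(t(v)))
  expect_gte(cor(me, colMeans(xs)), 0)
  ## identical genes: eigengene equals the standardized common profile
  common <- matrix(rep(rnorm(10), each = 3), 3, 10,
                   dimnames = list(c("a", "b", "c"), paste0("s", 1:10)))
  me2 <- module_eigengene(common, c("a", "b", "c"))
  prof <- scale(common[1, ])[, 1]
  expect_equal(unname(me2), unname(prof / sd(prof)), tolerance = 1e-8)
  ## first-PC optimality: explains at least as much variance as random
  ## unit projections of the standardized module
  set.seed(10)
  scores_var <- var(t(xs) %*% svd(t(xs))$v[, 1])
  for (i in 1:20) {
    w <- rnorm(nrow(xs)); w <- w / sqrt(sum(w^2))
    expect_gte(scores_var + 1e-8, var(t(xs) %*% w))
  }
})

test_that("same-factor split modules merge; orthogonal modules do not", {
  ## one latent factor, labels artificially split in two
  v <- module_expr(n_mod = 1, block = 30, n_noise = 0, seed = 11)
  labels <- stats::setNames(rep(c("M1", "M2"), each = 15), rownames(v))
  merged <- merge_close_modules(v, labels, dissim_threshold = 0.3)
  expect_equal(length(setdiff(unique(merged$labels), "grey")), 1)
  expect_length(merged$merged_from, 1)
  ## orthogonal factors stay separate
  v2 <- module_expr(n_mod = 2, block = 15, n_noise = 0, seed = 12)
  labels2 <- stats::setNames(truth_labels(rownames(v2)), rownames(v2))
  merged2 <- merge_close_modules(v2, labels2, dissim_threshold = 0.3)
  expect_equal(length(setdiff(unique(merged2$labels), "grey")), 2)
  expect_length(merged2$merged_from, 0)
  ## zero threshold: no merges ever
  merged3 <- merge_close_modules(v, labels, dissim_threshold = 0)
  expect_length(merged3$merged_from, 0)
})

test_that("module-trait correlation finds trait-coupled modules only", {
  sim <- generate_dataset(sim_config(
    n_mrna = 90, n_lncrna = 10, n_mirna = 5, n_modules = 2,
    module_size = 20, frac_de = 0, de_shift = 2, noise_sd = 0.3,
    n_triples = 0, n_rewired = 0, seed = 13))
  ds <- sim$dataset
  ## plant a DE shift on module M1's genes so it couples to the group label
  m1 <- names(sim$truth$module_map)[sim$truth$module_map == "M1"]
  v <- ds$values
  v[m1, samples_by_group(ds, "case")] <-
    v[m1, samples_by_group(ds, "case")] + 2
  trait <- as.numeric(ds$group == "case")
  labels <- stats::setNames(
    ifelse(rownames(v) %in% names(sim$truth$module_map),
           sim$truth$module_map[rownames(v)], "grey"), rownames(v))
  mt <- module_trait_correlation(v, labels, trait)
  expect_gt(abs(mt$r[mt$module == "M1"]), 0.8)
  expect_lt(mt$p[mt$module == "M1"], 0.01)
  ## trait equal to an eigengene correlates perfectly
  me <- module_eigengene(v, m1)
  mt2 <- module_trait_correlation(v, labels, me)
  expect_equal(abs(mt2$r[mt2$module == "M1"]), 1, tolerance = 1e-8)
  expect_error(module_trait_correlation(v, labels, rep(1, ncol(v))),
               "constant")
})

test_that("full module pipeline is deterministic", {
  v <- module_expr(seed = 14)
  run <- function() {
    st <- pick_soft_threshold(v)
    tom <- tom_similarity(adjacency_matrix(v, st$power))
    labels <- detect_modules(1 - tom)
    merge_close_modules(v, labels)
  }
  expect_identical(run(), run())
})
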