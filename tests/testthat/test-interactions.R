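test_that("the interaction matrix is the sign-flipped link-matrix product", {
  # single sample: beta_D = [[1,0]] (1 target, L=2), beta_C = [[2,0],[0,3]]
  chain <- fake_chain(array(c(1, 0), c(1, 2, 1)),
                      array(c(2, 0, 0, 3), c(2, 2, 1)))
  res <- interaction_matrix(chain)
  expect_equal(unname(res$interaction), matrix(c(-2, 0), 1, 2))
  expect_equal(res$n_samples_averaged, 1)
})

test_that("averaging over samples equals an explicit per-sample loop", {
  set.seed(5)
  S <- 7
  bD <- array(rnorm(3 * 2 * S), c(3, 2, S))
  bC <- array(rnorm(4 * 2 * S), c(4, 2, S))
  res <- interaction_matrix(fake_chain(bD, bC))
  ref <- matrix(0, 3, 4)
  for (s in 1:S) ref <- ref + bD[, , s] %*% t(bC[, , s])
  expect_equal(unname(res$interaction), -ref / S, tolerance = 1e-12)
})

test_that("a chain without link matrices cannot yield interactions", {
  set.seed(1)
  Y <- matrix(rnorm(30), 5, 6,
              dimnames = list(paste0("d", 1:5), paste0("c", 1:6)))
  chain <- macau_fit(response_matrix(Y),
                     config = sampler_config(n_latent = 2, burn_in = 10,
                                             n_collect = 10, seed = 1))
  expect_error(interaction_matrix(chain), "lacks a link matrix")
})

test_that("planted sensitivity effects recover with the right sign", {
  sim <- small_sim()
  res <- interaction_matrix(small_chain())
  truth <- sim$truth$interaction
  expect_gt(cor(as.vector(res$interaction), as.vector(truth)), 0.9)
  # strongest planted entries keep their sign
  strong <- abs(truth) > quantile(abs(truth), 0.75)
  expect_true(all(sign(res$interaction[strong]) == sign(truth[strong])))
})

test_that("eq4 reconstruction agrees with cold-start prediction and the data", {
  sim <- small_sim()
  chain <- small_chain()
  rec <- eq4_reconstruction(chain, sim$drug_side, sim$cell_side)
  cold <- predict_cold(chain, sim$drug_side, sim$cell_side)
  expect_equal(rec, cold, tolerance = 1e-8)
  obs <- !is.na(sim$response)
  expect_gt(cor(rec[obs], unclass(sim$response)[obs]), 0.95)
})

test_that("empirical p-values count null exceedances exactly as defined", {
  W <- matrix(c(2, -2), 1, 2)
  null_vals <- array(c(1, 3, 0, -1,        # nulls for entry 1 (obs +2)
                       1, 3, 0, -1),       # nulls for entry 2 (obs -2)
                     c(1, 2, 4))
  null_vals[1, 1, ] <- c(1, 3, 0, -1)
  null_vals[1, 2, ] <- c(1, 3, 0, -1)
  p <- tpinteract:::.empirical_pvalues(W, null_vals, "signed")
  expect_equal(p[1, 1], 1 / 4)   # one null >= +2
  expect_equal(p[1, 2], 0)       # no null <= -2
  p2 <- tpinteract:::.empirical_pvalues(W, null_vals, "two_sided")
  expect_equal(p2[1, 1], 1 / 4)  # |null| >= 2 once
  expect_equal(p2[1, 2], 1 / 4)
  ps <- tpinteract:::.empirical_pvalues(W, null_vals, "signed",
                                        smoothed = TRUE)
  expect_equal(ps[1, 1], 2 / 5)
})

test_that("injecting the observed statistic into the null reproduces it", {
  set.seed(9)
  W <- matrix(rnorm(6), 2, 3)
  null_vals <- array(rep(W, 5), c(2, 3, 5))   # every null equals observed
  p <- tpinteract:::.empirical_pvalues(W, null_vals, "signed")
  expect_true(all(p == 1))                     # >= / <= are inclusive
})

test_that("BH-Yekutieli matches hand-computed and brute-force references", {
  expect_equal(bh_yekutieli(0.04), 0.04)                 # m = 1, c(1) = 1
  expect_equal(bh_yekutieli(c(0.01, 1.0)), c(0.03, 1.0)) # m = 2, c(2) = 1.5
  expect_error(bh_yekutieli(c(0.5, 1.2)), "0, 1")
  expect_error(bh_yekutieli(c(0.5, -0.1)), "0, 1")

  set.seed(31)
  for (rep in 1:100) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)   # mix of uniform and skewed vectors
    q <- bh_yekutieli(p)
    expect_equal(q, by_bruteforce(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q >= 0 & q <= 1))
    # monotone: ordering of q follows ordering of p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("identical uniform p-values map to a flat q-vector", {
  p0 <- rep(0.02, 7)
  q <- bh_yekutieli(p0)
  expect_equal(q, by_bruteforce(p0))
  expect_equal(length(unique(q)), 1)
})

test_that("a small end-to-end permutation run is reproducible and coherent", {
  sim <- synth_generate(synth_config(n_drugs = 15, n_cells = 30,
                                     n_targets = 4, n_pathways = 3,
                                     L_true = 2, seed = 21))
  cfg <- sampler_config(n_latent = 4, burn_in = 30, n_collect = 40, seed = 13)
  pcfg <- sampler_config(n_latent = 4, burn_in = 20, n_collect = 30, seed = 13)
  run <- function() suppressWarnings(permutation_significance(
    sim$response, sim$drug_side, sim$cell_side, cfg,
    n_perm = 8, base_seed = 100, perm_config = pcfg))
  r1 <- run(); r2 <- run()
  expect_identical(r1$pvalues, r2$pvalues)
  expect_identical(r1$null_values, r2$null_values)
  expect_true(all(r1$qvalues >= r1$pvalues))
  expect_true(all(r1$qvalues >= 0 & r1$qvalues <= 1))
  expect_equal(dim(r1$null_values), c(4, 3, 8))
  # few permutations -> coarse granularity warning
  expect_warning(permutation_significance(
    sim$response, sim$drug_side, sim$cell_side, cfg,
    n_perm = 8, base_seed = 100, perm_config = pcfg), "granularity")
})

test_that("within-cell permutation preserves each cell line's score multiset", {
  sim <- small_sim()
  set.seed(77)
  perm <- tpinteract:::.permute_cell_side(sim$cell_side, "within_cell")
  Z0 <- unclass(sim$cell_side); Z1 <- unclass(perm)
  for (i in seq_len(nrow(Z0)))
    expect_setequal(unname(Z1[i, ]), unname(Z0[i, ]))
  set.seed(78)
  perm2 <- tpinteract:::.permute_cell_side(sim$cell_side, "across_cells")
  Z2 <- unclass(perm2)
  for (j in seq_len(ncol(Z0)))
    expect_setequal(unname(Z2[, j]), unname(Z0[, j]))
})

test_that("threshold_significant filters by q and sorts by absolute weight", {
  res <- structure(list(
    interaction = matrix(c(3, -5, 0.1, 2), 2, 2,
                         dimnames = list(c("t1", "t2"), c("p1", "p2"))),
    target_ids = c("t1", "t2"), pathway_ids = c("p1", "p2"),
    pvalues = matrix(c(0.01, 0.001, 0.9, 0.04), 2, 2),
    qvalues = matrix(c(0.1, 0.05, 1, 0.19), 2, 2),
    n_samples_averaged = 1L, n_permutations = 10L),
    class = "interaction_result")
  hits <- threshold_significant(res, q_max = 0.20)
  expect_equal(hits$target, c("t2", "t1", "t2"))  # |w| = 5, 3, 2
  expect_equal(hits$weight, c(-5, 3, 2))
  expect_equal(nrow(threshold_significant(res, q_max = 1)), 4)
  res$qvalues[] <- 1
  expect_equal(nrow(threshold_significant(res, q_max = 0.2)), 0)
  res$qvalues <- NULL
  expect_error(threshold_significant(res), "no q-values")
})

test_that("interaction results serialize to coherent CSV files", {
  res <- interaction_matrix(small_chain())
  prefix <- tempfile()
  paths <- write_interaction_result(res, prefix)
  expect_true(all(file.exists(paths)))
  W <- read_matrix(paths[1], "gene_expression")
  expect_equal(unclass(W)[, ], res$interaction, tolerance = 0)
  long <- read.csv(paths[2])
  expect_equal(nrow(long), length(res$interaction))
  expect_equal(
    long$weight[long$target == res$target_ids[2] &
                long$pathway == res$pathway_ids[3]],
    res$interaction[2, 3])
})
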