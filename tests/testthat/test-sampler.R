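test_that("a noiseless rank-1 matrix is reconstructed almost exactly", {
  set.seed(42)
  u <- rnorm(6); v <- rnorm(8)
  Y <- outer(u, v)
  dimnames(Y) <- list(paste0("d", 1:6), paste0("c", 1:8))
  chain <- macau_fit(response_matrix(Y),
                     config = sampler_config(n_latent = 2, burn_in = 200,
                                             n_collect = 200, seed = 7))
  pairs <- as.matrix(expand.grid(1:6, 1:8))
  pred <- predict_in_matrix(chain, pairs)
  expect_gt(cor(Y[pairs], pred), 0.99)
})

test_that("a constant response is absorbed by the global mean", {
  for (cc in c(5, -2)) {
    Y <- matrix(cc, 5, 6,
                dimnames = list(paste0("d", 1:5), paste0("c", 1:6)))
    chain <- macau_fit(response_matrix(Y),
                       config = sampler_config(n_latent = 3, burn_in = 100,
                                               n_collect = 100, seed = 2))
    pairs <- as.matrix(expand.grid(1:5, 1:6))
    pred <- predict_in_matrix(chain, pairs)
    expect_true(all(abs(pred - cc) < 0.05 * abs(cc) + 0.05))
  }
})

test_that("the same seed reproduces the chain bit for bit", {
  sim <- small_sim()
  cfg <- sampler_config(n_latent = 4, burn_in = 30, n_collect = 40, seed = 19)
  ch1 <- macau_fit(sim$response, sim$drug_side, sim$cell_side, cfg)
  ch2 <- macau_fit(sim$response, sim$drug_side, sim$cell_side, cfg)
  expect_identical(ch1$D, ch2$D)
  expect_identical(ch1$beta_C, ch2$beta_C)
  expect_identical(ch1$alpha, ch2$alpha)
})

test_that("entities with zero observations are rejected by name", {
  Y <- matrix(c(1, NA, 2, NA), 2, 2,
              dimnames = list(c("ok", "empty"), c("c1", "c2")))
  Y["empty", ] <- NA
  expect_error(macau_fit(response_matrix(Y)), "zero observed.*empty")
})

test_that("misaligned side information is rejected", {
  sim <- small_sim()
  shuffled <- side_info_matrix(
    unclass(sim$drug_side)[rev(rownames(sim$drug_side)), , drop = FALSE],
    "drug_target")
  expect_error(macau_fit(sim$response, shuffled, sim$cell_side),
               "not aligned")
})

test_that("predict_in_matrix averages per-sample bilinear products", {
  chain <- small_chain()
  pairs <- cbind(c(1, 5, 20), c(2, 40, 100))
  # explicit loop over samples as the reference
  S <- dim(chain$D)[3]
  ref <- rowMeans(vapply(seq_len(S), function(s)
    chain$global_mean +
      colSums(chain$D[, pairs[, 1], s] * chain$C[, pairs[, 2], s]),
    numeric(nrow(pairs))))
  expect_equal(predict_in_matrix(chain, pairs), ref, tolerance = 1e-12)

  # single-sample chain: prediction equals that sample exactly
  one <- chain
  one$D <- chain$D[, , 1, drop = FALSE]
  one$C <- chain$C[, , 1, drop = FALSE]
  expect_equal(predict_in_matrix(one, pairs),
               chain$global_mean +
                 colSums(chain$D[, pairs[, 1], 1] * chain$C[, pairs[, 2], 1]),
               tolerance = 1e-12)

  expect_error(predict_in_matrix(chain, cbind(999, 1)), "out of range")
})

test_that("held-out entries of the rank-1 fixture fall within 3 posterior sds", {
  set.seed(24)
  u <- rnorm(6); v <- rnorm(8)
  Y <- outer(u, v)
  dimnames(Y) <- list(paste0("d", 1:6), paste0("c", 1:8))
  held <- cbind(c(2, 4), c(3, 7))
  Ytr <- Y; Ytr[held] <- NA
  chain <- macau_fit(response_matrix(Ytr),
                     config = sampler_config(n_latent = 2, burn_in = 300,
                                             n_collect = 300, seed = 8))
  S <- dim(chain$D)[3]
  draws <- vapply(seq_len(S), function(s)
    chain$global_mean +
      colSums(chain$D[, held[, 1], s] * chain$C[, held[, 2], s]),
    numeric(nrow(held)))
  post_mean <- rowMeans(draws)
  post_sd <- apply(draws, 1, sd)
  expect_true(all(abs(post_mean - Y[held]) < 3 * post_sd + 1e-6))
})

test_that("cold-start predictions depend on side information only through the stored training transform", {
  sim <- small_sim()
  chain <- small_chain()
  # no leakage: stored scaling equals the training side's moments
  expect_equal(chain$cell_scaling$center, colMeans(unclass(sim$cell_side)))
  expect_equal(chain$cell_scaling$scale,
               apply(unclass(sim$cell_side), 2, sd))
  # a clone of a training drug's target vector predicts like that drug:
  # with no latent residual variance planted, the cold-start latent
  # (mu + beta' x) tracks the sampled latent of the training twin
  x <- unclass(sim$drug_side)[3, , drop = FALSE]
  rownames(x) <- "clone"
  clone_side <- side_info_matrix(x, "drug_target")
  pred_clone <- drop(predict_cold(chain, new_drug_side = clone_side))
  pred_train <- predict_in_matrix(
    chain, cbind(3, seq_along(chain$cell_ids)))
  expect_gt(cor(pred_clone, pred_train), 0.99)
  expect_lt(mean(abs(pred_clone - pred_train)) / sd(pred_train), 0.1)
})

test_that("an all-zero target vector reduces cold-start latents to the latent mean", {
  chain <- small_chain()   # binary drug side is unscaled by default
  zero <- side_info_matrix(
    matrix(0, 1, length(chain$target_ids),
           dimnames = list("none", chain$target_ids)), "drug_target")
  pred <- predict_cold(chain, new_drug_side = zero)
  S <- dim(chain$D)[3]
  ref <- rowMeans(vapply(seq_len(S), function(s)
    chain$global_mean + drop(crossprod(chain$mu_D[, s], chain$C[, , s])),
    numeric(length(chain$cell_ids))))
  expect_equal(unname(drop(pred)), unname(ref), tolerance = 1e-10)
})

test_that("predict_cold requires at least one new axis and matching features", {
  chain <- small_chain()
  expect_error(predict_cold(chain), "at least one axis")
  bad <- side_info_matrix(
    matrix(0:1, 2, 2, dimnames = list(c("n1", "n2"), c("wrong_a", "wrong_b"))),
    "drug_target")
  expect_error(predict_cold(chain, new_drug_side = bad), "lacks.*features")
})

test_that("chain serialization round-trips and writes a manifest", {
  chain <- small_chain()
  base <- tempfile()
  paths <- write_chain(chain, base)
  expect_true(all(file.exists(paths)))
  back <- read_chain(base)
  expect_identical(back$D, chain$D)
  manifest <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(manifest$n_latent, chain$n_latent)
  expect_equal(manifest$seed, chain$config$seed)
})

test_that("constant side features are dropped with a warning under standardization", {
  sim <- small_sim()
  Z <- unclass(sim$cell_side)
  Z[, 1] <- 2  # constant pathway score
  flat <- side_info_matrix(Z, "pathway_score")
  expect_warning(
    chain <- macau_fit(sim$response, NULL, flat,
                       sampler_config(n_latent = 3, burn_in = 20,
                                      n_collect = 20, seed = 4)),
    "constant side feature")
  expect_false(colnames(Z)[1] %in% chain$pathway_ids)
})
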