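# Shared fixtures.  Heavyweight fits are cached in an environment so
# several test files can reuse the same chain.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# a small planted screen + fitted chain, strong signal, no latent residuals
small_sim <- function() memo("small_sim", synth_generate(synth_config(
  n_drugs = 50, n_cells = 120, n_targets = 10, n_pathways = 6,
  L_true = 3, obs_noise_sd = 0.5, missing_fraction = 0.3, seed = 3)))

small_chain <- function() memo("small_chain", macau_fit(
  small_sim()$response, small_sim()$drug_side, small_sim()$cell_side,
  sampler_config(n_latent = 10, burn_in = 150, n_collect = 200, seed = 11)))

# hand-built posterior chain with known link matrices (no fitting)
fake_chain <- function(beta_D, beta_C, mu_D = NULL, mu_C = NULL,
                       global_mean = 0) {
  stopifnot(length(dim(beta_D)) == 3, length(dim(beta_C)) == 3)
  L <- dim(beta_D)[2]; S <- dim(beta_D)[3]
  if (is.null(mu_D)) mu_D <- matrix(0, L, S)
  if (is.null(mu_C)) mu_C <- matrix(0, L, S)
  structure(list(
    D = array(0, c(L, 1, S)), C = array(0, c(L, 1, S)),
    beta_D = beta_D, beta_C = beta_C, mu_D = mu_D, mu_C = mu_C,
    Lambda_D = array(rep(diag(L), S), c(L, L, S)),
    Lambda_C = array(rep(diag(L), S), c(L, L, S)),
    alpha = rep(1, S), global_mean = global_mean, n_latent = L,
    drug_ids = "d1", cell_ids = "c1",
    target_ids = paste0("t", seq_len(dim(beta_D)[1])),
    pathway_ids = paste0("p", seq_len(dim(beta_C)[1])),
    drug_scaling = list(mode = "none",
                        center = setNames(rep(0, dim(beta_D)[1]),
                                          paste0("t", seq_len(dim(beta_D)[1]))),
                        scale = setNames(rep(1, dim(beta_D)[1]),
                                         paste0("t", seq_len(dim(beta_D)[1]))),
                        feature_ids = paste0("t", seq_len(dim(beta_D)[1])),
                        kind = "drug_target"),
    cell_scaling = list(mode = "none",
                        center = setNames(rep(0, dim(beta_C)[1]),
                                          paste0("p", seq_len(dim(beta_C)[1]))),
                        scale = setNames(rep(1, dim(beta_C)[1]),
                                         paste0("p", seq_len(dim(beta_C)[1]))),
                        feature_ids = paste0("p", seq_len(dim(beta_C)[1])),
                        kind = "pathway_score"),
    config = sampler_config(n_latent = L, burn_in = 0, n_collect = S)),
    class = "posterior_chain")
}

# random per-tissue interaction matrices for report-selector tests
random_tissue_set <- function(n_tissues, n_targets, n_pathways, seed) {
  set.seed(seed)
  targets <- paste0("t", seq_len(n_targets))
  pathways <- paste0("p", seq_len(n_pathways))
  out <- lapply(seq_len(n_tissues), function(i)
    matrix(rnorm(n_targets * n_pathways), n_targets, n_pathways,
           dimnames = list(targets, pathways)))
  names(out) <- paste0("tissue", seq_len(n_tissues))
  out
}

# independent brute-force BH-Yekutieli step-up (oracle for bh_yekutieli)
by_bruteforce <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * cm * p[o[j]] / j, 0)
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
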