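# Gibbs sampler surface: configuration, fitting, and the posterior chain
# container.  The numerical core lives in src/gibbs.cpp; this file handles
# validation, centring, side-feature scaling and chain bookkeeping.

#' Sampler configuration
#'
#' Defaults follow the reference analysis: 400 burn-in iterations then 600
#' collected posterior samples; `n_latent = 30` is the usual choice when
#' drug side information is present, 10 when only cell-line features are
#' used (the fitting helpers pick these defaults when `n_latent = NULL`).
#'
#' @param n_latent number of latent dimensions L (`NULL` = decide at fit
#'   time from which side-information matrices are present).
#' @param burn_in discarded initial Gibbs iterations.
#' @param n_collect posterior samples kept after burn-in.
#' @param seed integer seed; every fit is bit-reproducible given it.
#' @param noise_mode `"adaptive"` samples the observation precision alpha
#'   under a Gamma prior; `"fixed_precision"` keeps it at `alpha`.
#' @param alpha observation precision: initial value (adaptive) or the
#'   fixed value.
#' @param alpha_prior,link_precision_prior Gamma (shape, rate) priors for
#'   the observation precision and the link-matrix precision scale.
#' @param side_scaling per-feature transform of side information:
#'   `"auto"` standardizes real-valued sides and leaves binary 0/1 sides
#'   untouched; or force `"none"`, `"center"`, `"standardize"`.
#' @param b0 Normal-Wishart scale on the latent means.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(n_latent = NULL, burn_in = 400, n_collect = 600,
                           seed = 1,
                           noise_mode = c("adaptive", "fixed_precision"),
                           alpha = 1,
                           alpha_prior = c(shape = 2, rate = 2),
                           link_precision_prior = c(shape = 2, rate = 2),
                           side_scaling = c("auto", "none", "center",
                                            "standardize"),
                           b0 = 2) {
  noise_mode <- match.arg(noise_mode)
  side_scaling <- match.arg(side_scaling)
  stopifnot(is.null(n_latent) || n_latent >= 1, burn_in >= 0, n_collect >= 1,
            alpha > 0, all(alpha_prior > 0), all(link_precision_prior > 0))
  structure(list(n_latent = n_latent, burn_in = as.integer(burn_in),
                 n_collect = as.integer(n_collect), seed = as.integer(seed),
                 noise_mode = noise_mode, alpha = alpha,
                 alpha_prior = alpha_prior,
                 link_precision_prior = link_precision_prior,
                 side_scaling = side_scaling, b0 = b0),
            class = "sampler_config")
}

.default_L <- function(config, has_drug_side) {
  if (!is.null(config$n_latent)) return(as.integer(config$n_latent))
  if (has_drug_side) 30L else 10L
}

# Fit per-feature scaling on a side matrix (entities x features); returns
# the scaled features x entities matrix plus the parameters needed to
# transform new entities identically.  Constant columns under standardize
# are dropped with a warning (division by zero otherwise).
.fit_side_scaling <- function(side, mode) {
  if (is.null(side)) return(NULL)
  vals <- unclass(side)
  kind <- attr(side, "kind")
  if (mode == "auto")
    mode <- if (identical(kind, "drug_target")) "none" else "standardize"
  center <- rep(0, ncol(vals))
  scale <- rep(1, ncol(vals))
  keep <- rep(TRUE, ncol(vals))
  if (mode %in% c("center", "standardize"))
    center <- colMeans(vals)
  if (mode == "standardize") {
    scale <- apply(vals, 2, sd)
    keep <- scale > 0
    if (!all(keep)) {
      warning("dropping constant side feature(s): ",
              paste(colnames(vals)[!keep], collapse = ", "), call. = FALSE)
      scale[!keep] <- 1
    }
  }
  names(center) <- names(scale) <- colnames(vals)
  list(mode = mode, center = center[keep], scale = scale[keep],
       feature_ids = colnames(vals)[keep], kind = kind)
}

# Apply stored scaling to an entities x features matrix; returns the
# features x entities matrix the sampler consumes.  Errors if features
# fitted on are absent from `side`.
.apply_side_scaling <- function(side, scaling) {
  if (is.null(scaling)) return(NULL)
  vals <- unclass(side)
  miss <- setdiff(scaling$feature_ids, colnames(vals))
  if (length(miss) > 0)
    stop("side information lacks trained features: ",
         paste(miss, collapse = ", "), call. = FALSE)
  vals <- vals[, scaling$feature_ids, drop = FALSE]
  vals <- sweep(vals, 2, scaling$center, "-")
  vals <- sweep(vals, 2, scaling$scale, "/")
  t(vals)
}

#' Fit the Bayesian matrix factorization model by Gibbs sampling
#'
#' Observed entries follow `y_ij ~ N(m + d_i' c_j, 1/alpha)` where `m` is
#' the observed global mean; each drug latent is
#' `d_i ~ N(mu_D + beta_D' x_i, Lambda_D^-1)` when target profiles `x` are
#' supplied (symmetrically for cell lines with pathway scores `z`), under a
#' Normal-Wishart hyperprior per axis and a Gamma-precision matrix-normal
#' prior on each link matrix.  Every post-burn-in Gibbs sample of the
#' latents, link matrices and hyperparameters is retained.
#'
#' @param response [response_matrix()]; every drug and cell line must have
#'   at least one observed entry.
#' @param drug_side,cell_side optional [side_info_matrix()] with entities
#'   matching (and aligned to) the response rows/columns.
#' @param config [sampler_config()].
#' @return a `posterior_chain`: arrays of collected samples (`D`, `C`,
#'   `beta_D`, `beta_C`, `mu_*`, `Lambda_*`, `alpha`), the global mean,
#'   training identifiers and the fitted side-scaling parameters.
#' @export
macau_fit <- function(response, drug_side = NULL, cell_side = NULL,
                      config = sampler_config()) {
  stopifnot(inherits(config, "sampler_config"))
  Y <- unclass(response)
  if (!is.null(drug_side) &&
      !identical(rownames(drug_side), rownames(Y)))
    stop("drug side information is not aligned to the response rows; run align_inputs()", call. = FALSE)
  if (!is.null(cell_side) &&
      !identical(rownames(cell_side), colnames(Y)))
    stop("cell side information is not aligned to the response columns; run align_inputs()", call. = FALSE)
  row_obs <- rowSums(!is.na(Y))
  col_obs <- colSums(!is.na(Y))
  if (any(row_obs == 0))
    stop("drug(s) with zero observed entries: ",
         paste(rownames(Y)[row_obs == 0], collapse = ", "), call. = FALSE)
  if (any(col_obs == 0))
    stop("cell line(s) with zero observed entries: ",
         paste(colnames(Y)[col_obs == 0], collapse = ", "), call. = FALSE)

  L <- .default_L(config, !is.null(drug_side))
  m <- mean(Y, na.rm = TRUE)
  Yc <- Y - m

  drug_scaling <- .fit_side_scaling(drug_side, config$side_scaling)
  cell_scaling <- .fit_side_scaling(cell_side, config$side_scaling)
  Xd <- .apply_side_scaling(drug_side, drug_scaling)
  Xc <- .apply_side_scaling(cell_side, cell_scaling)
  if (is.null(Xd)) Xd <- matrix(0, 0, nrow(Y))
  if (is.null(Xc)) Xc <- matrix(0, 0, ncol(Y))

  set.seed(config$seed)
  raw <- .gibbs_core(Yc, Xd, Xc, L, config$burn_in, config$n_collect,
                     config$noise_mode == "adaptive", config$alpha,
                     config$alpha_prior[["shape"]],
                     config$alpha_prior[["rate"]],
                     config$link_precision_prior[["shape"]],
                     config$link_precision_prior[["rate"]],
                     config$b0)

  structure(list(
    D = raw$D, C = raw$C,
    beta_D = if (nrow(Xd) > 0) raw$beta_D,
    beta_C = if (nrow(Xc) > 0) raw$beta_C,
    mu_D = raw$mu_D, mu_C = raw$mu_C,
    Lambda_D = raw$Lambda_D, Lambda_C = raw$Lambda_C,
    alpha = as.numeric(raw$alpha),
    global_mean = m, n_latent = L,
    drug_ids = rownames(Y), cell_ids = colnames(Y),
    target_ids = if (!is.null(drug_scaling)) drug_scaling$feature_ids,
    pathway_ids = if (!is.null(cell_scaling)) cell_scaling$feature_ids,
    drug_scaling = drug_scaling, cell_scaling = cell_scaling,
    config = config), class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "posterior_chain: %d samples, L = %d, %d drugs x %d cell lines\n",
    dim(x$D)[3], x$n_latent, length(x$drug_ids), length(x$cell_ids)))
  cat(sprintf("  drug side: %s | cell side: %s | seed %d\n",
              if (is.null(x$beta_D)) "absent" else
                sprintf("%d features", length(x$target_ids)),
              if (is.null(x$beta_C)) "absent" else
                sprintf("%d features", length(x$pathway_ids)),
              x$config$seed))
  invisible(x)
}

#' Posterior-mean predictions for training drug/cell pairs
#'
#' For each `(drug, cell)` index pair, averages
#' `global_mean + D_i . C_j` over the collected samples.
#'
#' @param chain [macau_fit()] result.
#' @param pairs two-column matrix (or data frame) of drug and cell indices
#'   into the training dimensions.
#' @return numeric vector of predictions, one per pair.
#' @export
predict_in_matrix <- function(chain, pairs) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  nd <- length(chain$drug_ids); nc <- length(chain$cell_ids)
  if (any(pairs[, 1] < 1 | pairs[, 1] > nd))
    stop("drug index out of range", call. = FALSE)
  if (any(pairs[, 2] < 1 | pairs[, 2] > nc))
    stop("cell index out of range", call. = FALSE)
  S <- dim(chain$D)[3]
  acc <- numeric(nrow(pairs))
  for (s in seq_len(S)) {
    Ds <- chain$D[, , s, drop = TRUE]
    Cs <- chain$C[, , s, drop = TRUE]
    if (is.null(dim(Ds))) { Ds <- matrix(Ds, nrow = chain$n_latent)
                            Cs <- matrix(Cs, nrow = chain$n_latent) }
    acc <- acc + colSums(Ds[, pairs[, 1], drop = FALSE] *
                         Cs[, pairs[, 2], drop = FALSE])
  }
  chain$global_mean + acc / S
}

# Per-sample cold-start latents for new entities: predictive mean
# mu + beta' x_new (no residual noise draw), with the training scaling.
.cold_latents <- function(chain, side, axis = c("drug", "cell")) {
  axis <- match.arg(axis)
  beta <- if (axis == "drug") chain$beta_D else chain$beta_C
  mus <- if (axis == "drug") chain$mu_D else chain$mu_C
  scaling <- if (axis == "drug") chain$drug_scaling else chain$cell_scaling
  if (is.null(beta))
    stop("chain was fitted without ", axis, " side information; cannot cold-start that axis", call. = FALSE)
  X <- .apply_side_scaling(side, scaling)          # F x N_new
  S <- dim(beta)[3]
  out <- array(0, dim = c(chain$n_latent, ncol(X), S))
  for (s in seq_len(S))
    out[, , s] <- mus[, s] + crossprod(matrix(beta[, , s],
                                              nrow = dim(beta)[1]), X)
  dimnames(out) <- list(NULL, rownames(side), NULL)
  out
}

#' Cold-start predictions from side information alone
#'
#' Predicts responses for new drugs and/or new cell lines never seen in
#' training.  A new entity's latent is its predictive mean
#' `mu + beta' x_new` per posterior sample (side features transformed with
#' the stored training scaling); a `NULL` side keeps the training entities'
#' sampled latents on that axis.  Predictions average over the chain.
#'
#' @param chain [macau_fit()] result.
#' @param new_drug_side,new_cell_side [side_info_matrix()] for the new
#'   entities, with (at least) the training feature set, or `NULL` to keep
#'   the training axis.
#' @return predicted response matrix (drugs x cells) with dimnames.
#' @export
predict_cold <- function(chain, new_drug_side = NULL, new_cell_side = NULL) {
  if (is.null(new_drug_side) && is.null(new_cell_side))
    stop("at least one axis must be new; use predict_in_matrix() otherwise",
         call. = FALSE)
  S <- dim(chain$D)[3]
  Dlat <- if (is.null(new_drug_side)) chain$D else
    .cold_latents(chain, new_drug_side, "drug")
  Clat <- if (is.null(new_cell_side)) chain$C else
    .cold_latents(chain, new_cell_side, "cell")
  nd <- dim(Dlat)[2]; nc <- dim(Clat)[2]
  acc <- matrix(0, nd, nc)
  for (s in seq_len(S))
    acc <- acc + crossprod(matrix(Dlat[, , s], ncol = nd),
                           matrix(Clat[, , s], ncol = nc))
  out <- chain$global_mean + acc / S
  rownames(out) <- if (is.null(new_drug_side)) chain$drug_ids else
    rownames(new_drug_side)
  colnames(out) <- if (is.null(new_cell_side)) chain$cell_ids else
    rownames(new_cell_side)
  out
}

#' Serialize a posterior chain to disk
#'
#' Writes a binary archive of the sample arrays next to a JSON manifest
#' (dimensions, configuration, seed, scaling parameters).
#'
#' @param chain [macau_fit()] result.
#' @param path base path; `<path>.rds` and `<path>.json` are written.
#' @return invisibly, the two paths.
#' @export
write_chain <- function(chain, path) {
  rds <- paste0(path, ".rds"); manifest <- paste0(path, ".json")
  saveRDS(chain, rds)
  jsonlite::write_json(list(
    n_latent = chain$n_latent, n_collect = dim(chain$D)[3],
    n_drugs = length(chain$drug_ids), n_cells = length(chain$cell_ids),
    seed = chain$config$seed, burn_in = chain$config$burn_in,
    noise_mode = chain$config$noise_mode,
    drug_scaling = chain$drug_scaling, cell_scaling = chain$cell_scaling),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(rds, manifest))
}

#' @rdname write_chain
#' @export
read_chain <- function(path) readRDS(paste0(path, ".rds"))
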