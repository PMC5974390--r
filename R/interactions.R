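# Target x pathway interaction inference: average the product of the two
# posterior link matrices over the chain (sign-flipped so positive =
# sensitivity), and assess per-entry significance against a permutation
# null with Benjamini-Hochberg-Yekutieli correction.

#' Extract the target x pathway interaction matrix from a chain
#'
#' `interaction = -(1/S) * sum_s beta_D^(s) %*% t(beta_C^(s))` over the S
#' collected samples.  The sign flip makes a positive entry mean that
#' activation of the pathway associates with sensitivity (lower IC50) to
#' drugs hitting the target.
#'
#' @param chain [macau_fit()] result fitted with side information on both
#'   axes.
#' @return an `interaction_result`: `interaction` (targets x pathways),
#'   labels, `n_samples_averaged`; p/q-value slots empty.
#' @export
interaction_matrix <- function(chain) {
  if (is.null(chain$beta_D) || is.null(chain$beta_C))
    stop("chain lacks a link matrix; fit with side information on both axes",
         call. = FALSE)
  S <- dim(chain$beta_D)[3]
  Fd <- dim(chain$beta_D)[1]; Fc <- dim(chain$beta_C)[1]
  acc <- matrix(0, Fd, Fc)
  for (s in seq_len(S))
    acc <- acc + tcrossprod(matrix(chain$beta_D[, , s], nrow = Fd),
                            matrix(chain$beta_C[, , s], nrow = Fc))
  inter <- -acc / S
  dimnames(inter) <- list(chain$target_ids, chain$pathway_ids)
  structure(list(interaction = inter,
                 target_ids = chain$target_ids,
                 pathway_ids = chain$pathway_ids,
                 n_samples_averaged = S,
                 pvalues = NULL, qvalues = NULL, n_permutations = 0L),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction_result: %d targets x %d pathways (%d samples averaged)\n",
              nrow(x$interaction), ncol(x$interaction), x$n_samples_averaged))
  if (!is.null(x$qvalues))
    cat(sprintf("  permutation null: %d permutations; %d entries with q <= 0.2\n",
                x$n_permutations, sum(x$qvalues <= 0.2)))
  invisible(x)
}

#' Reconstruct the response from side information and link matrices
#'
#' Per posterior sample, every predicted response is the linear combination
#' of all target x pathway interactions weighted by the drug's target
#' profile and the cell line's pathway scores (plus the latent-mean offset
#' cross terms), averaged over the chain.  This treats all entities as new:
#' it must agree with [predict_cold()] on both axes to numerical tolerance.
#'
#' @param chain [macau_fit()] result with side information on both axes.
#' @param drug_side,cell_side [side_info_matrix()] for the entities to
#'   reconstruct.
#' @return predicted response matrix (drugs x cells).
#' @export
eq4_reconstruction <- function(chain, drug_side, cell_side) {
  Xd <- .apply_side_scaling(drug_side, chain$drug_scaling)   # F_D x n
  Xc <- .apply_side_scaling(cell_side, chain$cell_scaling)   # F_C x m
  S <- dim(chain$beta_D)[3]
  Fd <- dim(chain$beta_D)[1]; Fc <- dim(chain$beta_C)[1]
  acc <- matrix(0, ncol(Xd), ncol(Xc))
  for (s in seq_len(S)) {
    bd <- matrix(chain$beta_D[, , s], nrow = Fd)
    bc <- matrix(chain$beta_C[, , s], nrow = Fc)
    dlat <- chain$mu_D[, s] + crossprod(bd, Xd)              # L x n
    clat <- chain$mu_C[, s] + crossprod(bc, Xc)              # L x m
    acc <- acc + crossprod(dlat, clat)
  }
  out <- chain$global_mean + acc / S
  dimnames(out) <- list(rownames(drug_side), rownames(cell_side))
  out
}

#' Benjamini-Hochberg-Yekutieli q-values
#'
#' Step-up false-discovery-rate correction valid under arbitrary
#' dependence: `q_(i) = min_{j >= i} ( m * c(m) * p_(j) / j )` clipped to
#' [0,1], with `c(m) = sum_{k=1..m} 1/k`.
#'
#' @param pvalues numeric vector of p-values in [0,1].
#' @return q-values in input order.
#' @export
bh_yekutieli <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BY")
}

# Empirical p-values of observed entries W against null draws
# (targets x pathways x n_perm).  "signed": one-sided keyed on the sign of
# the observed entry, p = count/n_perm as in the reference analysis;
# "two_sided": p = #{|null| >= |obs|}/n_perm.
.empirical_pvalues <- function(W, null_vals, alternative = "signed",
                               smoothed = FALSE) {
  n_perm <- dim(null_vals)[3]
  cnt <- matrix(0, nrow(W), ncol(W))
  if (alternative == "signed") {
    pos <- W >= 0
    for (t in seq_len(n_perm)) {
      nt <- matrix(null_vals[, , t], nrow(W), ncol(W))
      cnt <- cnt + ifelse(pos, nt >= W, nt <= W)
    }
  } else {
    for (t in seq_len(n_perm))
      cnt <- cnt + (abs(matrix(null_vals[, , t], nrow(W), ncol(W))) >= abs(W))
  }
  p <- if (smoothed) (cnt + 1) / (n_perm + 1) else cnt / n_perm
  dimnames(p) <- dimnames(W)
  p
}

# Permute each cell line's pathway-score vector independently (mode
# "within_cell"): destroys the target-pathway linkage while preserving
# every cell line's score multiset.  Mode "across_cells" instead permutes
# cell-line labels independently per pathway column.
.permute_cell_side <- function(cell_side, mode = c("within_cell",
                                                   "across_cells")) {
  mode <- match.arg(mode)
  vals <- unclass(cell_side)
  perm <- vals
  if (mode == "within_cell") {
    for (i in seq_len(nrow(vals)))
      perm[i, ] <- vals[i, sample.int(ncol(vals))]
  } else {
    for (j in seq_len(ncol(vals)))
      perm[, j] <- vals[sample.int(nrow(vals)), j]
  }
  side_info_matrix(perm, attr(cell_side, "kind"))
}

#' Permutation significance of the interaction matrix
#'
#' Builds an empirical null per interaction entry by refitting the full
#' model on permuted cell-line side information (each cell line's pathway
#' scores shuffled independently; drug targets are never permuted, so that
#' shared-target structure is preserved).  For a positive observed entry,
#' `p = #\{null >= observed\} / n_perm`; for a negative one,
#' `p = #\{null <= observed\} / n_perm` (`alternative = "signed"`, the
#' default).  This sign-conditioned estimator is anti-conservative by
#' construction (its null distribution is uniform on [0, 0.5], so about
#' twice the nominal fraction falls below any small threshold);
#' `alternative = "two_sided"` (`p = #\{|null| >= |observed|\} / n_perm`)
#' is the calibrated variant.  `smoothed = TRUE` uses the
#' `(count + 1) / (n_perm + 1)` estimator instead of the raw count ratio.
#' q-values are Benjamini-Hochberg-Yekutieli over all entries.
#'
#' @param response,drug_side,cell_side aligned inputs as for [macau_fit()].
#' @param config [sampler_config()] for the observed fit.
#' @param n_perm number of permutations (reference analysis: 1000;
#'   desk-scale default here 100).
#' @param base_seed permutation `t` uses seed `base_seed + t`.
#' @param perm_config reduced-budget [sampler_config()] for the permuted
#'   refits (default: burn-in 100, collect 150, same L and priors).
#' @param alternative `"signed"` (one-sided keyed on the observed sign) or
#'   `"two_sided"`.
#' @param perm_mode see details above.
#' @param smoothed use the `(count+1)/(n_perm+1)` p estimator.
#' @return an `interaction_result` with `pvalues`, `qvalues`,
#'   `n_permutations`, and the null draws in `null_values`
#'   (targets x pathways x n_perm).
#' @export
permutation_significance <- function(response, drug_side, cell_side,
                                     config = sampler_config(),
                                     n_perm = 100, base_seed = config$seed,
                                     perm_config = NULL,
                                     alternative = c("signed", "two_sided"),
                                     perm_mode = c("within_cell",
                                                   "across_cells"),
                                     smoothed = FALSE) {
  alternative <- match.arg(alternative)
  perm_mode <- match.arg(perm_mode)
  stopifnot(n_perm >= 1)
  if (1 / n_perm > 0.05)
    warning(sprintf(
      "with %d permutations the p-value granularity (%.2f) is coarser than 0.05",
      n_perm, 1 / n_perm), call. = FALSE)
  if (is.null(perm_config)) {
    perm_config <- config
    perm_config$burn_in <- 100L
    perm_config$n_collect <- 150L
  }
  obs_chain <- macau_fit(response, drug_side, cell_side, config)
  obs <- interaction_matrix(obs_chain)
  W <- obs$interaction
  null_vals <- array(NA_real_, dim = c(nrow(W), ncol(W), n_perm),
                     dimnames = c(dimnames(W), list(NULL)))
  for (t in seq_len(n_perm)) {
    pc <- perm_config
    pc$seed <- as.integer(base_seed + t)
    set.seed(pc$seed)
    perm_side <- .permute_cell_side(cell_side, perm_mode)
    chain_t <- macau_fit(response, drug_side, perm_side, pc)
    null_vals[, , t] <- interaction_matrix(chain_t)$interaction
  }
  p <- .empirical_pvalues(W, null_vals, alternative, smoothed)
  q <- matrix(bh_yekutieli(as.vector(p)), nrow(W), ncol(W),
              dimnames = dimnames(W))
  obs$pvalues <- p
  obs$qvalues <- q
  obs$n_permutations <- as.integer(n_perm)
  obs$null_values <- null_vals
  obs$alternative <- alternative
  obs
}

#' Significant target-pathway interactions
#'
#' Entries with `q <= q_max` (reference threshold: 20%), sorted by
#' absolute interaction weight, descending.
#'
#' @param result [permutation_significance()] result (q-values required).
#' @param q_max q-value threshold (default 0.20).
#' @return data frame `(target, pathway, weight, p, q)`.
#' @export
threshold_significant <- function(result, q_max = 0.20) {
  if (is.null(result$qvalues))
    stop("interaction result has no q-values; run permutation_significance()",
         call. = FALSE)
  keep <- which(result$qvalues <= q_max, arr.ind = TRUE)
  out <- data.frame(
    target = result$target_ids[keep[, 1]],
    pathway = result$pathway_ids[keep[, 2]],
    weight = result$interaction[keep],
    p = result$pvalues[keep],
    q = result$qvalues[keep],
    stringsAsFactors = FALSE)
  out[order(-abs(out$weight)), , drop = FALSE]
}

#' Write an interaction result as CSV files
#'
#' Emits `<prefix>_weights.csv`, and when present `<prefix>_pvalues.csv`,
#' `<prefix>_qvalues.csv`, plus a long-format
#' `<prefix>_long.csv` (target, pathway, weight, p, q).
#'
#' @param result `interaction_result`.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
write_interaction_result <- function(result, prefix) {
  paths <- paste0(prefix, "_weights.csv")
  write_matrix(result$interaction, paths)
  if (!is.null(result$pvalues)) {
    write_matrix(result$pvalues, p1 <- paste0(prefix, "_pvalues.csv"))
    write_matrix(result$qvalues, p2 <- paste0(prefix, "_qvalues.csv"))
    paths <- c(paths, p1, p2)
  }
  long <- expand.grid(target = result$target_ids,
                      pathway = result$pathway_ids,
                      stringsAsFactors = FALSE)
  long$weight <- as.vector(result$interaction)
  if (!is.null(result$pvalues)) {
    long$p <- as.vector(result$pvalues)
    long$q <- as.vector(result$qvalues)
  }
  pl <- paste0(prefix, "_long.csv")
  write.csv(long, pl, row.names = FALSE, quote = FALSE)
  invisible(c(paths, pl))
}
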