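# Cross-validation harnesses for the four prediction regimes:
#   1 new cell lines  2 new drugs  3 matrix imputation  4 double cold start
# plus the setting-4 quality gate used before any interaction analysis.

#' Pearson correlation of observed vs predicted values
#'
#' @param observed,predicted paired numeric vectors; pairs with a missing
#'   member are dropped; at least 3 complete pairs and nonzero variance on
#'   both sides are required.
#' @return correlation coefficient, or `NA` with a warning when undefined
#'   (zero variance).
#' @export
pearson <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 3) stop("need at least 3 paired finite values",
                          call. = FALSE)
  if (sd(o) == 0 || sd(p) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(o, p)
}

#' Deterministic k-fold assignment
#'
#' @param n number of items.
#' @param k folds.
#' @param seed RNG seed.
#' @return integer vector of fold labels (1..k) forming a partition.
#' @export
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

.cv_result <- function(setting, fold_r, folds, config) {
  fold_r <- fold_r[is.finite(fold_r)]
  structure(list(setting = setting, fold_r = fold_r,
                 mean_r = mean(fold_r), sd_r = sd(fold_r),
                 folds = folds, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("setting %d: mean r = %.3f (sd %.3f) over %d folds\n",
              x$setting, x$mean_r, x$sd_r, length(x$fold_r)))
  invisible(x)
}

# shared skeleton for settings 1 and 2: cold-start CV over one axis
.axis_cv <- function(response, drug_side, cell_side, config, k, repeats,
                     seed, axis) {
  Y <- unclass(response)
  n <- if (axis == "cell") ncol(Y) else nrow(Y)
  fold_r <- c(); fold_defs <- list()
  for (r in seq_len(repeats)) {
    folds <- make_folds(n, k, seed + r - 1)
    fold_defs[[r]] <- folds
    for (f in seq_len(k)) {
      test <- which(folds == f)
      if (axis == "cell") {
        Ytr <- Y[, -test, drop = FALSE]
        keep_drug <- rowSums(!is.na(Ytr)) > 0
        Ytr <- Ytr[keep_drug, , drop = FALSE]
        chain <- macau_fit(
          response_matrix(Ytr),
          if (!is.null(drug_side))
            side_info_matrix(unclass(drug_side)[keep_drug, , drop = FALSE],
                             attr(drug_side, "kind")),
          side_info_matrix(unclass(cell_side)[-test, , drop = FALSE],
                           attr(cell_side, "kind")),
          config)
        pred <- predict_cold(chain, new_cell_side =
          side_info_matrix(unclass(cell_side)[test, , drop = FALSE],
                           attr(cell_side, "kind")))
        obs <- Y[keep_drug, test, drop = FALSE]
      } else {
        Ytr <- Y[-test, , drop = FALSE]
        keep_cell <- colSums(!is.na(Ytr)) > 0
        Ytr <- Ytr[, keep_cell, drop = FALSE]
        chain <- macau_fit(
          response_matrix(Ytr),
          side_info_matrix(unclass(drug_side)[-test, , drop = FALSE],
                           attr(drug_side, "kind")),
          if (!is.null(cell_side))
            side_info_matrix(unclass(cell_side)[keep_cell, , drop = FALSE],
                             attr(cell_side, "kind")),
          config)
        pred <- predict_cold(chain, new_drug_side =
          side_info_matrix(unclass(drug_side)[test, , drop = FALSE],
                           attr(drug_side, "kind")))
        obs <- Y[test, keep_cell, drop = FALSE]
      }
      ok <- sum(is.finite(obs))
      if (ok < 3) { warning("fold with too few observed test entries skipped",
                            call. = FALSE); next }
      fold_r <- c(fold_r, pearson(as.vector(obs), as.vector(pred)))
    }
  }
  .cv_result(if (axis == "cell") 1L else 2L, fold_r, fold_defs, config)
}

#' Setting 1: predict new cell lines for existing drugs
#'
#' Cells are split into k folds (repeated); the model is fitted on the
#' training cells with cell-line side information (default L = 10 when no
#' drug features are used) and held-out cells are predicted cold from
#' their pathway scores.  Pearson r pools all observed test entries per
#' fold.
#'
#' @param response [response_matrix()].
#' @param cell_side [side_info_matrix()] of pathway scores (required).
#' @param config [sampler_config()]; `n_latent = NULL` picks the
#'   axis-appropriate default.
#' @param drug_side optional drug side information also given to the fit.
#' @param k,repeats folds and repeats (reference analysis: 10 and 10).
#' @param seed fold seed; repeat r uses `seed + r - 1`.
#' @return a `cv_result`.
#' @export
setting1_new_cells <- function(response, cell_side, config = sampler_config(),
                               drug_side = NULL, k = 10, repeats = 10,
                               seed = 1) {
  .axis_cv(response, drug_side, cell_side, config, k, repeats, seed, "cell")
}

#' Setting 2: predict new drugs on existing cell lines
#'
#' Symmetric to [setting1_new_cells()] over drugs, using binary target
#' profiles as drug side information (default L = 30).
#'
#' @param response [response_matrix()].
#' @param drug_side [side_info_matrix()] of kind `drug_target` (required).
#' @param cell_side optional cell side information also given to the fit.
#' @inheritParams setting1_new_cells
#' @return a `cv_result`.
#' @export
setting2_new_drugs <- function(response, drug_side, cell_side = NULL,
                               config = sampler_config(), k = 10,
                               repeats = 10, seed = 1) {
  .axis_cv(response, drug_side, cell_side, config, k, repeats, seed, "drug")
}

#' Setting 3: imputation of randomly held-out entries
#'
#' Masks a random `test_fraction` of the observed entries (resampling the
#' mask if a drug or cell line would lose all its observations), fits on
#' the rest, and predicts the held-out entries in-matrix.
#'
#' @param response [response_matrix()].
#' @param drug_side,cell_side optional side information.
#' @param config [sampler_config()].
#' @param test_fraction fraction of observed entries held out (default
#'   0.1).
#' @param repeats number of random masks.
#' @param seed mask seed; repeat r uses `seed + r - 1`.
#' @param max_retries mask resampling attempts before erroring.
#' @return a `cv_result`.
#' @export
setting3_imputation <- function(response, drug_side = NULL, cell_side = NULL,
                                config = sampler_config(),
                                test_fraction = 0.1, repeats = 1, seed = 1,
                                max_retries = 50) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  Y <- unclass(response)
  obs <- which(!is.na(Y))
  fold_r <- c(); masks <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1)
    test <- NULL
    for (try in seq_len(max_retries)) {
      cand <- sample(obs, round(test_fraction * length(obs)))
      Ytr <- Y; Ytr[cand] <- NA
      if (all(rowSums(!is.na(Ytr)) > 0) && all(colSums(!is.na(Ytr)) > 0)) {
        test <- cand; break
      }
    }
    if (is.null(test))
      stop("could not find a mask keeping every drug and cell observed",
           call. = FALSE)
    masks[[r]] <- test
    Ytr <- Y; Ytr[test] <- NA
    chain <- macau_fit(response_matrix(Ytr), drug_side, cell_side, config)
    idx <- arrayInd(test, dim(Y))
    pred <- predict_in_matrix(chain, idx)
    fold_r <- c(fold_r, pearson(Y[test], pred))
  }
  .cv_result(3L, fold_r, masks, config)
}

#' Setting 4: double cold start (new drugs on new cell lines)
#'
#' Independent k-folds over drugs and over cells.  With
#' `pairing = "full"`, every (drug-fold i, cell-fold j) block is a test
#' set (k^2 fits); `pairing = "diagonal"` pairs fold i with fold i (k
#' fits).  Each block's training data contain only entries whose drug AND
#' cell are outside the block; held-out blocks are predicted cold on both
#' axes.
#'
#' @param response [response_matrix()].
#' @param drug_side,cell_side side information, both required.
#' @param config [sampler_config()] (reference analysis: L = 30).
#' @param k folds per axis.
#' @param seed fold seed (drug folds use `seed`, cell folds `seed + 1000`).
#' @param pairing `"full"` or `"diagonal"`.
#' @return a `cv_result`.
#' @export
setting4_double_cv <- function(response, drug_side, cell_side,
                               config = sampler_config(), k = 10, seed = 1,
                               pairing = c("full", "diagonal")) {
  pairing <- match.arg(pairing)
  Y <- unclass(response)
  dfolds <- make_folds(nrow(Y), k, seed)
  cfolds <- make_folds(ncol(Y), k, seed + 1000)
  blocks <- if (pairing == "full")
    expand.grid(i = seq_len(k), j = seq_len(k)) else
    data.frame(i = seq_len(k), j = seq_len(k))
  fold_r <- c()
  for (b in seq_len(nrow(blocks))) {
    dtest <- which(dfolds == blocks$i[b])
    ctest <- which(cfolds == blocks$j[b])
    Ytr <- Y[-dtest, -ctest, drop = FALSE]
    keep_drug <- rowSums(!is.na(Ytr)) > 0
    keep_cell <- colSums(!is.na(Ytr)) > 0
    Ytr <- Ytr[keep_drug, keep_cell, drop = FALSE]
    chain <- macau_fit(
      response_matrix(Ytr),
      side_info_matrix(unclass(drug_side)[-dtest, , drop = FALSE][keep_drug, ,
                       drop = FALSE], attr(drug_side, "kind")),
      side_info_matrix(unclass(cell_side)[-ctest, , drop = FALSE][keep_cell, ,
                       drop = FALSE], attr(cell_side, "kind")),
      config)
    pred <- predict_cold(chain,
      new_drug_side = side_info_matrix(
        unclass(drug_side)[dtest, , drop = FALSE], attr(drug_side, "kind")),
      new_cell_side = side_info_matrix(
        unclass(cell_side)[ctest, , drop = FALSE], attr(cell_side, "kind")))
    obs <- Y[dtest, ctest, drop = FALSE]
    if (sum(is.finite(obs)) < 3) {
      warning("empty or near-empty test block skipped", call. = FALSE)
      next
    }
    fold_r <- c(fold_r, pearson(as.vector(obs), as.vector(pred)))
  }
  out <- .cv_result(4L, fold_r,
                    list(drug_folds = dfolds, cell_folds = cfolds), config)
  out$pairing <- pairing
  out
}

#' Quality gate on a setting-4 cross-validation
#'
#' A tissue's interaction analysis is considered validated when the
#' double-cold-start mean Pearson r reaches the threshold (reference
#' value 0.3).
#'
#' @param cv `cv_result` from [setting4_double_cv()].
#' @param threshold minimum mean r (default 0.3).
#' @return list `(pass, mean_r, threshold, message)`.
#' @export
quality_gate <- function(cv, threshold = 0.3) {
  stopifnot(inherits(cv, "cv_result"))
  if (cv$setting != 4L)
    warning("quality gate is defined on setting-4 results", call. = FALSE)
  pass <- is.finite(cv$mean_r) && cv$mean_r >= threshold
  list(pass = pass, mean_r = cv$mean_r, threshold = threshold,
       message = sprintf("mean r = %.3f %s threshold %.2f: %s",
                         cv$mean_r, if (pass) ">=" else "<", threshold,
                         if (pass) "validated" else "unvalidated"))
}
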