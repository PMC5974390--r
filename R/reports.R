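# Tissue-level and cross-tissue selection of interaction matrices: the
# heatmap filters (top-5% absolute value, top-k variance/mean) and the
# antagonistic-pair table.

.as_interaction_matrix <- function(x) {
  if (inherits(x, "interaction_result")) x$interaction else as.matrix(x)
}

#' Reduce one tissue's interaction matrix for display
#'
#' Two-step filter: (1) keep targets having at least one entry whose
#' absolute value lies in the top `top_frac` quantile of all absolute
#' entries of the matrix; (2) among those, keep the `keep_targets` targets
#' with the highest variance across pathways.  Row and column order are
#' otherwise preserved.
#'
#' @param result `interaction_result` or targets x pathways matrix.
#' @param top_frac top fraction by absolute value (default 0.05).
#' @param keep_targets maximum targets kept (default 25); all survivors are
#'   returned if fewer pass step 1.
#' @return reduced targets x pathways matrix (exact submatrix).
#' @export
tissue_heatmap_selection <- function(result, top_frac = 0.05,
                                     keep_targets = 25) {
  stopifnot(top_frac > 0, top_frac <= 1, keep_targets >= 1)
  W <- .as_interaction_matrix(result)
  cut <- quantile(abs(W), 1 - top_frac, names = FALSE)
  hit <- which(apply(abs(W) >= cut, 1, any))
  if (length(hit) > keep_targets) {
    rv <- apply(W[hit, , drop = FALSE], 1, var)
    hit <- hit[rank(-rv, ties.method = "first") <= keep_targets]
  }
  W[hit, , drop = FALSE]
}

#' Stack per-tissue interaction matrices into a tissues x pairs matrix
#'
#' Vectorizes each tissue's targets x pathways matrix in target-major
#' order (all pathways of target 1, then target 2, ...); pair columns are
#' labelled `"target|pathway"`.
#'
#' @param set named list of `interaction_result` (or matrices), one per
#'   tissue, sharing target and pathway labels.
#' @return tissues x (targets * pathways) matrix.
#' @export
cross_tissue_matrix <- function(set) {
  stopifnot(length(set) >= 2)
  mats <- lapply(set, .as_interaction_matrix)
  ref <- dimnames(mats[[1]])
  for (m in mats)
    if (!identical(dimnames(m), ref))
      stop("tissue interaction matrices have mismatched labels",
           call. = FALSE)
  pair_names <- as.vector(t(outer(ref[[1]], ref[[2]], paste, sep = "|")))
  out <- do.call(rbind, lapply(mats, function(m) as.vector(t(m))))
  dimnames(out) <- list(names(set), pair_names)
  out
}

#' Undo [cross_tissue_matrix()] for one tissue row
#'
#' @param cross tissues x pairs matrix from [cross_tissue_matrix()].
#' @param tissue row to reshape.
#' @param target_ids,pathway_ids the original labels.
#' @return targets x pathways matrix.
#' @export
uncross_tissue <- function(cross, tissue, target_ids, pathway_ids) {
  matrix(cross[tissue, ], nrow = length(target_ids),
         ncol = length(pathway_ids), byrow = TRUE,
         dimnames = list(target_ids, pathway_ids))
}

.top_pair_filter <- function(cross, top_frac) {
  cut <- quantile(abs(cross), 1 - top_frac, names = FALSE)
  which(apply(abs(cross) >= cut, 2, any))
}

#' Cross-tissue pairs with consistently high interactions
#'
#' Keeps pairs with at least one tissue in the top `top_frac` absolute
#' value, then the `keep_pairs` pairs with the highest mean across tissues
#' (`mode = "mean"`, the figure-legend reading) or the lowest variance
#' across tissues (`mode = "low_variance"`, the main-text reading).
#'
#' @param set named list of per-tissue interaction results (>= 2 tissues).
#' @param top_frac top fraction by absolute value (default 0.05).
#' @param keep_pairs pairs kept (default 30).
#' @param mode `"mean"` or `"low_variance"`.
#' @return reduced tissues x pairs matrix.
#' @export
select_highest <- function(set, top_frac = 0.05, keep_pairs = 30,
                           mode = c("mean", "low_variance")) {
  mode <- match.arg(mode)
  cross <- cross_tissue_matrix(set)
  keep <- .top_pair_filter(cross, top_frac)
  sub <- cross[, keep, drop = FALSE]
  crit <- switch(mode,
    mean = -colMeans(sub),
    low_variance = apply(sub, 2, var))
  if (length(keep) > keep_pairs)
    sub <- sub[, rank(crit, ties.method = "first") <= keep_pairs,
               drop = FALSE]
  sub
}

#' Cross-tissue pairs with the most divergent interactions
#'
#' As [select_highest()], but ranks the surviving pairs by variance across
#' tissues, descending.
#'
#' @inheritParams select_highest
#' @return reduced tissues x pairs matrix.
#' @export
select_divergent <- function(set, top_frac = 0.05, keep_pairs = 30) {
  cross <- cross_tissue_matrix(set)
  keep <- .top_pair_filter(cross, top_frac)
  sub <- cross[, keep, drop = FALSE]
  if (length(keep) > keep_pairs) {
    cv <- apply(sub, 2, var)
    sub <- sub[, rank(-cv, ties.method = "first") <= keep_pairs,
               drop = FALSE]
  }
  sub
}

#' Target-pathway pairs with antagonistic effects across tissues
#'
#' Per pair, finds the tissues with the maximal and minimal interaction
#' weight; keeps pairs whose extremes have opposite signs (true
#' antagonism) and ranks them by `balance = | |w_max| - |w_min| |`,
#' ascending -- a balance near zero means an equally strong sensitivity
#' effect in one tissue and resistance effect in another.
#'
#' @param set named list of per-tissue interaction results (>= 2 tissues).
#' @param keep_pairs rows returned (default 30).
#' @return data frame `(pair, tissue_max, w_max, tissue_min, w_min,
#'   balance)` sorted ascending by balance.
#' @export
antagonistic_pairs <- function(set, keep_pairs = 30) {
  cross <- cross_tissue_matrix(set)
  imax <- apply(cross, 2, which.max)
  imin <- apply(cross, 2, which.min)
  w_max <- cross[cbind(imax, seq_len(ncol(cross)))]
  w_min <- cross[cbind(imin, seq_len(ncol(cross)))]
  out <- data.frame(
    pair = colnames(cross),
    tissue_max = rownames(cross)[imax],
    w_max = w_max,
    tissue_min = rownames(cross)[imin],
    w_min = w_min,
    balance = abs(abs(w_max) - abs(w_min)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$w_max > 0 & out$w_min < 0, , drop = FALSE]
  out <- out[order(out$balance, out$pair), , drop = FALSE]
  head(out, keep_pairs)
}

#' Heatmap of an interaction (sub)matrix
#'
#' Convenience wrapper around `pheatmap` with a diverging palette; a plain
#' pass-through of the values (no scaling).
#'
#' @param W matrix, e.g. from [tissue_heatmap_selection()].
#' @param file optional PNG/SVG path; plots to the active device otherwise.
#' @param ... passed to `pheatmap::pheatmap`.
#' @return invisibly, the pheatmap object.
#' @export
plot_interaction_heatmap <- function(W, file = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("the pheatmap package is required for plotting", call. = FALSE)
  lim <- max(abs(W))
  ph <- pheatmap::pheatmap(
    W, filename = file,
    breaks = seq(-lim, lim, length.out = 101),
    color = grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(100),
    ...)
  invisible(ph)
}
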