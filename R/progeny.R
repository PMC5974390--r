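# Perturbation-footprint pathway scoring: fit a genes x pathways weight
# matrix from perturbation z-scores (multiple linear model per gene, keep
# the 100 genes with smallest p-values per pathway), then score expression
# data by plain matrix multiplication.

#' Default pathway set
#'
#' The 11 signaling pathways covered by the perturbation compendium.
#' @export
progeny_pathways <- c("EGFR", "NFkB", "TGFb", "MAPK", "p53", "TNFa",
                      "PI3K", "VEGF", "Hypoxia", "Trail", "JAK.STAT")

#' Bundle perturbation z-scores with their pathway design
#'
#' @param zscores genes x experiments numeric matrix (rownames = gene ids,
#'   unique).
#' @param design experiments x pathways matrix with entries in
#'   `{-1, 0, +1}`: pathway inhibited / untouched / activated.  Every
#'   experiment must perturb at least one pathway.
#' @return a `perturbation_set` list.
#' @export
perturbation_set <- function(zscores, design) {
  zscores <- as.matrix(zscores); design <- as.matrix(design)
  if (ncol(zscores) != nrow(design))
    stop("zscores columns and design rows must match (one per experiment)",
         call. = FALSE)
  .check_unique(rownames(zscores), "gene")
  if (!all(design %in% c(-1, 0, 1)))
    stop("design entries must be -1, 0 or +1", call. = FALSE)
  if (any(rowSums(design != 0) == 0))
    stop("every experiment must perturb at least one pathway", call. = FALSE)
  structure(list(zscores = zscores, design = design),
            class = "perturbation_set")
}

#' Per-gene z-scores of a perturbation experiment
#'
#' `z = (mean(perturbed) - mean(control)) / sd(control)` per gene, the
#' control standard deviation floored at `eps`.
#'
#' @param perturbed genes x replicates matrix (or vector) of perturbed
#'   expression.
#' @param controls genes x replicates matrix of control expression; at
#'   least 2 replicates (a dispersion estimate is needed).
#' @param eps floor for the control standard deviation.
#' @return numeric vector of z-scores, named by gene.
#' @export
perturbation_zscores <- function(perturbed, controls, eps = 1e-8) {
  perturbed <- as.matrix(perturbed); controls <- as.matrix(controls)
  if (ncol(controls) < 2)
    stop("need at least 2 control replicates", call. = FALSE)
  if (!identical(rownames(perturbed), rownames(controls)) ||
      nrow(perturbed) != nrow(controls))
    stop("perturbed and control gene sets differ", call. = FALSE)
  s <- pmax(apply(controls, 1, sd), eps)
  (rowMeans(perturbed) - rowMeans(controls)) / s
}

#' Fit pathway weights from perturbation z-scores
#'
#' Per gene, ordinary least squares of its z-scores on the pathway design
#' columns plus an intercept; per pathway, two-sided t-test p-values on the
#' coefficients.  Each pathway keeps the coefficients of its
#' `genes_per_pathway` genes with smallest p-values (ties broken by
#' ascending gene identifier), all other weights set to zero.
#'
#' @param data [perturbation_set()].
#' @param genes_per_pathway nonzero weights retained per pathway
#'   (default 100).
#' @return a `progeny_model`: `weights` (genes x pathways, sparse by
#'   zeroing), `pvalues` (kept for audit), `genes_per_pathway`.
#' @export
fit_progeny <- function(data, genes_per_pathway = 100) {
  stopifnot(inherits(data, "perturbation_set"), genes_per_pathway >= 1)
  X <- cbind(`(Intercept)` = 1, data$design)
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop("need more experiments than pathways + 1", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear pathway column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  Yt <- t(data$zscores)                       # experiments x genes
  coefs <- qr.coef(qrX, Yt)                   # p x genes
  resid <- Yt - X %*% coefs
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))    # pivoting: rank full, order kept
  XtXinv_diag <- XtXinv_diag[order(qrX$pivot)]
  se <- sqrt(outer(XtXinv_diag, sigma2))      # p x genes
  tstat <- coefs / se
  pvals <- 2 * pt(abs(tstat), df, lower.tail = FALSE)

  pathways <- colnames(data$design)
  genes <- rownames(data$zscores)
  W <- matrix(0, length(genes), length(pathways),
              dimnames = list(genes, pathways))
  P <- matrix(NA_real_, length(genes), length(pathways),
              dimnames = list(genes, pathways))
  k <- min(genes_per_pathway, length(genes))
  for (pw in pathways) {
    pv <- pvals[pw, ]
    P[, pw] <- pv
    sel <- order(pv, genes)[seq_len(k)]       # tie-break: ascending gene id
    W[sel, pw] <- coefs[pw, sel]
  }
  structure(list(weights = W, pvalues = P, pathways = pathways,
                 genes_per_pathway = as.integer(genes_per_pathway)),
            class = "progeny_model")
}

#' Score expression data against a fitted pathway model
#'
#' `scores = expression %*% weights` restricted to the genes shared by the
#' expression matrix and the model -- exact matrix multiplication, no
#' further normalization.  Model genes missing from the expression data are
#' treated as absent (a warning reports the coverage fraction).
#'
#' @param expression samples x genes matrix (e.g. a [side_info_matrix()]
#'   of kind `gene_expression`) with gene colnames.
#' @param model [fit_progeny()] result, or a weights matrix.
#' @param center subtract the per-gene mean across samples first
#'   (off by default; useful across datasets).
#' @return samples x pathways score matrix.
#' @export
progeny_score <- function(expression, model, center = FALSE) {
  W <- if (inherits(model, "progeny_model")) model$weights else as.matrix(model)
  E <- unclass(as.matrix(expression))
  shared <- intersect(colnames(E), rownames(W))
  if (length(shared) == 0)
    stop("no genes shared between expression data and model", call. = FALSE)
  coverage <- length(shared) / nrow(W)
  if (coverage < 1)
    warning(sprintf("expression covers %.1f%% of model genes",
                    100 * coverage), call. = FALSE)
  E <- E[, shared, drop = FALSE]
  if (center) E <- sweep(E, 2, colMeans(E))
  E %*% W[shared, , drop = FALSE]
}

#' Write / read a pathway weight model as CSV (genes x pathways)
#'
#' @param model [fit_progeny()] result.
#' @param path CSV destination.
#' @export
write_progeny_model <- function(model, path) {
  write_matrix(model$weights, path)
}

#' @rdname write_progeny_model
#' @export
read_progeny_model <- function(path) {
  W <- unclass(read_matrix(path, "gene_expression"))
  attr(W, "kind") <- NULL
  structure(list(weights = W, pvalues = NULL, pathways = colnames(W),
                 genes_per_pathway = max(colSums(W != 0))),
            class = "progeny_model")
}
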