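# Synthetic drug screens with planted target-pathway interaction
# structure.  The generator draws from the same generative equations the
# sampler assumes, so fitted interaction matrices can be compared to a
# known planted truth without any external download.

#' Synthetic screen configuration
#'
#' Defaults are the reference study conditions used throughout the test
#' suite: 100 drugs x 300 cell lines, 20 protein targets (1-3 per drug),
#' 11 pathways, rank-5 planted structure, observation noise sd 0.5, 30%
#' missing entries.
#'
#' @param n_drugs,n_cells,n_targets,n_pathways dimensions.
#' @param L_true planted latent rank.
#' @param targets_per_drug integer range (min, max) of targets per drug.
#' @param latent_residual_sd sd of entity-level latent noise around
#'   `beta' x` (0 = latents fully determined by side information).
#' @param obs_noise_sd sd of observation noise on the response.
#' @param missing_fraction fraction of entries masked missing at random.
#' @param n_tissues number of tissue labels assigned to cell lines.
#' @param tissue_effect_sd sd of additive per-tissue mean shifts on the
#'   pathway scores (0 = no tissue structure).
#' @param beta_sd sd of the planted link-matrix entries.
#' @param seed RNG seed; same seed gives bit-identical output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_drugs = 100, n_cells = 300, n_targets = 20,
                         n_pathways = 11, L_true = 5,
                         targets_per_drug = c(1, 3),
                         latent_residual_sd = 0, obs_noise_sd = 0.5,
                         missing_fraction = 0.3, n_tissues = 1,
                         tissue_effect_sd = 0, beta_sd = 1, seed = 1) {
  stopifnot(n_drugs >= 1, n_cells >= 1, n_targets >= 1, n_pathways >= 1,
            L_true >= 1, length(targets_per_drug) == 2,
            targets_per_drug[1] >= 1,
            targets_per_drug[2] <= n_targets,
            latent_residual_sd >= 0, obs_noise_sd >= 0,
            missing_fraction >= 0, missing_fraction < 1, n_tissues >= 1,
            tissue_effect_sd >= 0)
  structure(as.list(environment()), class = "synth_config")
}

.synth_names <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

# Draw the shared scaffolding: target incidence, tissue assignment,
# pathway scores.  Used by both the planted and the null generator.
.synth_sides <- function(cfg) {
  drugs <- .synth_names("drug", cfg$n_drugs)
  cells <- .synth_names("cell", cfg$n_cells)
  targets <- .synth_names("target", cfg$n_targets)
  pathways <- if (cfg$n_pathways == length(progeny_pathways))
    progeny_pathways else .synth_names("pathway", cfg$n_pathways)

  X <- matrix(0, cfg$n_drugs, cfg$n_targets, dimnames = list(drugs, targets))
  tmin <- cfg$targets_per_drug[1]; tmax <- cfg$targets_per_drug[2]
  for (i in seq_len(cfg$n_drugs)) {
    nt <- if (tmin == tmax) tmin else sample(tmin:tmax, 1)
    X[i, sample(cfg$n_targets, nt)] <- 1
  }
  tissues <- .synth_names("tissue", cfg$n_tissues)
  assignment <- sample(rep(tissues, length.out = cfg$n_cells))
  shift <- matrix(rnorm(cfg$n_tissues * cfg$n_pathways,
                        sd = cfg$tissue_effect_sd),
                  cfg$n_tissues, cfg$n_pathways,
                  dimnames = list(tissues, pathways))
  Z <- matrix(rnorm(cfg$n_cells * cfg$n_pathways), cfg$n_cells,
              cfg$n_pathways, dimnames = list(cells, pathways)) +
       shift[assignment, , drop = FALSE]
  rownames(Z) <- cells
  list(X = X, Z = Z, ann = tissue_annotation(cells, assignment))
}

.synth_mask <- function(Y, fraction, max_retries = 50) {
  if (fraction == 0) return(Y)
  for (try in seq_len(max_retries)) {
    M <- Y
    M[runif(length(Y)) < fraction] <- NA
    if (all(rowSums(!is.na(M)) > 0) && all(colSums(!is.na(M)) > 0))
      return(M)
  }
  stop("masking left a drug or cell line fully missing after ",
       max_retries, " retries", call. = FALSE)
}

#' Generate a synthetic screen with planted interaction structure
#'
#' Draws binary target profiles (uniform 1-3 targets per drug), standard
#' normal pathway scores (plus optional tissue mean shifts), normal link
#' matrices `beta_D` (targets x L) and `beta_C` (pathways x L), latents
#' `D = beta_D' x (+ residual)` and `C = beta_C' z (+ residual)`, and the
#' response `Y = D'C + noise`, masked missing at random.  The planted
#' interaction matrix is reported sign-flipped (`-beta_D beta_C'`) to
#' match the pipeline's convention.
#'
#' @param cfg [synth_config()].
#' @return list `(response, drug_side, cell_side, annotation, truth)`;
#'   `truth` holds `beta_D`, `beta_C`, `interaction`, the latents, the
#'   noiseless response and the tissue assignment.
#' @export
synth_generate <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  sides <- .synth_sides(cfg)
  beta_D <- matrix(rnorm(cfg$n_targets * cfg$L_true, sd = cfg$beta_sd),
                   cfg$n_targets, cfg$L_true,
                   dimnames = list(colnames(sides$X), NULL))
  beta_C <- matrix(rnorm(cfg$n_pathways * cfg$L_true, sd = cfg$beta_sd),
                   cfg$n_pathways, cfg$L_true,
                   dimnames = list(colnames(sides$Z), NULL))
  D <- t(sides$X %*% beta_D) +
    matrix(rnorm(cfg$L_true * cfg$n_drugs, sd = cfg$latent_residual_sd),
           cfg$L_true, cfg$n_drugs)
  C <- t(sides$Z %*% beta_C) +
    matrix(rnorm(cfg$L_true * cfg$n_cells, sd = cfg$latent_residual_sd),
           cfg$L_true, cfg$n_cells)
  clean <- crossprod(D, C)
  dimnames(clean) <- list(rownames(sides$X), rownames(sides$Z))
  Y <- clean + matrix(rnorm(length(clean), sd = cfg$obs_noise_sd),
                      nrow(clean), ncol(clean))
  Y <- .synth_mask(Y, cfg$missing_fraction)
  list(response = response_matrix(Y),
       drug_side = side_info_matrix(sides$X, "drug_target"),
       cell_side = side_info_matrix(sides$Z, "pathway_score"),
       annotation = sides$ann,
       truth = list(beta_D = beta_D, beta_C = beta_C,
                    interaction = -tcrossprod(beta_D, beta_C),
                    D = D, C = C, noiseless = clean,
                    tissue = sides$ann, config = cfg))
}

#' Generate a null screen: pathway scores carry no signal
#'
#' Same shapes and marginals as [synth_generate()], but the response is
#' built from latents drawn independently of the cell-line side
#' information, so any apparent target-pathway interaction is spurious.
#' Used to calibrate the permutation test.
#'
#' @param cfg [synth_config()].
#' @return as [synth_generate()]; `truth$interaction` is `NA` (not
#'   applicable) and `truth$null` is `TRUE`.
#' @export
synth_generate_null <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  sides <- .synth_sides(cfg)
  beta_D <- matrix(rnorm(cfg$n_targets * cfg$L_true, sd = cfg$beta_sd),
                   cfg$n_targets, cfg$L_true,
                   dimnames = list(colnames(sides$X), NULL))
  D <- t(sides$X %*% beta_D) +
    matrix(rnorm(cfg$L_true * cfg$n_drugs, sd = cfg$latent_residual_sd),
           cfg$L_true, cfg$n_drugs)
  # cell latents independent of the pathway scores: match their scale
  csd <- sqrt(cfg$n_pathways) * cfg$beta_sd
  C <- matrix(rnorm(cfg$L_true * cfg$n_cells, sd = csd),
              cfg$L_true, cfg$n_cells)
  clean <- crossprod(D, C)
  dimnames(clean) <- list(rownames(sides$X), rownames(sides$Z))
  Y <- clean + matrix(rnorm(length(clean), sd = cfg$obs_noise_sd),
                      nrow(clean), ncol(clean))
  Y <- .synth_mask(Y, cfg$missing_fraction)
  list(response = response_matrix(Y),
       drug_side = side_info_matrix(sides$X, "drug_target"),
       cell_side = side_info_matrix(sides$Z, "pathway_score"),
       annotation = sides$ann,
       truth = list(beta_D = beta_D, beta_C = NULL, interaction = NA,
                    D = D, C = C, noiseless = clean,
                    tissue = sides$ann, config = cfg, null = TRUE))
}

#' Generate synthetic perturbation experiments for pathway-model fitting
#'
#' Each experiment perturbs exactly one pathway (activation +1 or
#' inhibition -1, equiprobable); each pathway owns a disjoint block of
#' `informative_per_pathway` genes whose planted weights are
#' `N(0, effect_sd)`; z-scores are
#' `planted_weights %*% t(design) + N(0, noise_sd)`.
#'
#' @param n_genes,n_experiments dimensions.
#' @param n_pathways pathways (default the 11 standard labels).
#' @param informative_per_pathway planted informative genes per pathway.
#' @param effect_sd sd of planted weights (0 = pure-noise null).
#' @param noise_sd sd of added noise on the z-scores.
#' @param seed RNG seed.
#' @return list `(data, planted_weights, informative)` where `data` is a
#'   [perturbation_set()] and `informative` maps each pathway to its
#'   planted gene ids.
#' @export
synth_perturbations <- function(n_genes = 2000, n_experiments = 500,
                                n_pathways = 11,
                                informative_per_pathway = 150,
                                effect_sd = 1, noise_sd = 0.1, seed = 1) {
  stopifnot(n_experiments > n_pathways + 1,
            informative_per_pathway * n_pathways <= n_genes)
  set.seed(seed)
  genes <- .synth_names("gene", n_genes)
  pathways <- if (n_pathways == length(progeny_pathways))
    progeny_pathways else .synth_names("pathway", n_pathways)
  design <- matrix(0, n_experiments, n_pathways,
                   dimnames = list(.synth_names("exp", n_experiments),
                                   pathways))
  design[cbind(seq_len(n_experiments),
               sample(n_pathways, n_experiments, replace = TRUE))] <-
    sample(c(-1, 1), n_experiments, replace = TRUE)
  W <- matrix(0, n_genes, n_pathways, dimnames = list(genes, pathways))
  informative <- list()
  for (p in seq_len(n_pathways)) {
    block <- genes[seq((p - 1) * informative_per_pathway + 1,
                       p * informative_per_pathway)]
    W[block, p] <- rnorm(informative_per_pathway, sd = effect_sd)
    informative[[pathways[p]]] <- block
  }
  Z <- W %*% t(design) +
    matrix(rnorm(n_genes * n_experiments, sd = noise_sd), n_genes)
  dimnames(Z) <- list(genes, rownames(design))
  list(data = perturbation_set(Z, design), planted_weights = W,
       informative = informative)
}

#' Write a generated screen to disk in the package's CSV formats
#'
#' @param sim [synth_generate()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
synth_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    response = file.path(dir, "response.csv"),
    drug_side = file.path(dir, "drug_targets.csv"),
    cell_side = file.path(dir, "pathway_scores.csv"),
    annotation = file.path(dir, "tissues.csv"),
    interaction = file.path(dir, "planted_interaction.csv"))
  write_matrix(sim$response, paths["response"])
  write_matrix(sim$drug_side, paths["drug_side"])
  write_matrix(sim$cell_side, paths["cell_side"])
  write.csv(sim$annotation, paths["annotation"], row.names = FALSE,
            quote = FALSE)
  if (is.matrix(sim$truth$interaction))
    write_matrix(sim$truth$interaction, paths["interaction"])
  invisible(paths)
}
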