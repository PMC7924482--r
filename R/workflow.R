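# End-to-end workflows composing the modules: train-and-evaluate on a
# genome with held-out chromosomes, and cross-species application of a
# trained model.

#' Train on a genome and evaluate lambda on held-out chromosomes
#'
#' Builds a limited unbalanced dataset (ratio Q, class weight CW = Q) from
#' all non-holdout chromosomes, trains the network, scans each held-out
#' chromosome at 1-bp stride and computes the lambda score over its GSS.
#' The benchmark defaults (15-epoch cap, patience 4, batch 64) suit the
#' desk-scale synthetic genomes, which separate within a handful of
#' epochs; pass a different `config` for harder data.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gss GSS data.frame.
#' @param Q Negative:positive ratio.
#' @param holdout_chroms Chromosomes excluded from training and used for
#'   genome-wide evaluation.
#' @param seed Integer seed driving sampling, initialisation and training.
#' @param config A [training_config()].
#' @param r Lambda central-window width (default 400).
#' @return A list: `dataset`, `model`, `tracks`, `lambda`
#'   (a `lambda_result`), `test_metrics` (confusion summary on the held
#'   -aside test split at threshold 0.5).
#' @export
train_and_evaluate <- function(genome, gss, Q, holdout_chroms, seed = 1L,
                               config = training_config(max_epochs = 15L,
                                                        patience = 4L,
                                                        batch_size = 64L,
                                                        seed = seed),
                               r = 400L) {
  dataset <- build_dataset(genome, gss, Q = Q,
                           holdout_chroms = holdout_chroms, seed = seed)
  model <- build_model(seed = seed)
  model <- train_model(model, dataset, config)
  tracks <- scan_genome(model, genome, chroms = holdout_chroms)
  lam <- evaluate_lambda(tracks, gss, r = r,
                         tags = list(Q = Q, seed = seed,
                                     chroms = paste(holdout_chroms,
                                                    collapse = ",")))
  te <- get_split(dataset, "test")
  cm <- confusion_metrics(te$y, predict(model, te$X),
                          threshold = config$threshold)
  list(dataset = dataset, model = model, tracks = tracks, lambda = lam,
       test_metrics = cm)
}

#' Apply a trained model across species
#'
#' Scans a different genome with an already-trained model and computes
#' lambda over that genome's own GSS annotations — the cross-species
#' annotation-transfer workflow.
#'
#' @param model A trained `gss_model`.
#' @param genome Target genome (named character vector).
#' @param gss Target genome's GSS data.frame.
#' @param chroms Chromosomes to scan (default: all).
#' @param r Lambda central-window width (default 400).
#' @param tags Extra provenance tags.
#' @return A list: `tracks`, `lambda`.
#' @export
cross_species_lambda <- function(model, genome, gss, chroms = NULL,
                                 r = 400L, tags = list()) {
  tracks <- scan_genome(model, genome, chroms = chroms)
  lam <- evaluate_lambda(tracks, gss, r = r,
                         tags = c(list(cross_species = TRUE), tags))
  list(tracks = tracks, lambda = lam)
}

#' CpG-content baseline lambda
#'
#' Computes the sliding-window CpG-count track on the given chromosomes
#' and runs it through the same Z-score / metagene / lambda pipeline as
#' model predictions.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gss GSS data.frame.
#' @param chroms Chromosomes to evaluate (default: all).
#' @param r Lambda central-window width (default 400).
#' @return A `lambda_result`.
#' @export
cpg_baseline_lambda <- function(genome, gss, chroms = NULL, r = 400L) {
  if (is.null(chroms)) chroms <- names(genome)
  tracks <- lapply(chroms, function(ch)
    cpg_baseline_track(genome[[ch]], chrom = ch))
  evaluate_lambda(tracks, gss, r = r,
                  tags = list(predictor = "cpg_baseline",
                              chroms = paste(chroms, collapse = ",")))
}
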