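#' Pipeline configuration
#'
#' Gathers every knob of the four-stage pipeline: per-modality min-max
#' normalization, snapshot PCA with variance-threshold component selection,
#' one sparse-response DBN per modality, and the ELM classifier on the
#' concatenated features.
#'
#' @param pca_threshold cumulative explained-variance target in (0, 1\].
#' @param pca_max_k cap on retained components per modality.
#' @param hidden_size DBN hidden layer size; `NULL` (default) uses each
#'   modality's retained PCA dimension.
#' @param n_hidden_layers stacked RBMs per DBN (default 3).
#' @param rbm an [sr_train_config()] for layerwise pretraining.
#' @param finetune `"supervised"` (softmax-head backpropagation on training
#'   labels) or `"off"`.
#' @param finetune_lr,finetune_epochs fine-tuning step size and epochs.
#' @param elm_L ELM hidden nodes; `NULL` uses 10x the concatenated feature
#'   dimension, capped at 1000.
#' @param variant `"full"`, `"no_sparsity"` (sparsity weight forced to 0) or
#'   `"pca_elm"` (no DBN stage).
#' @param seed master seed; every stage draws a named substream from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pca_threshold = 0.90, pca_max_k = 20L,
                            hidden_size = NULL, n_hidden_layers = 3L,
                            rbm = sr_train_config(), finetune = "supervised",
                            finetune_lr = 0.1, finetune_epochs = 50L,
                            elm_L = NULL, variant = "full", seed = 1L) {
  if (!variant %in% c("full", "no_sparsity", "pca_elm"))
    abort_validation("unknown variant")
  if (!finetune %in% c("supervised", "off"))
    abort_validation("finetune must be 'supervised' or 'off'")
  if (!(pca_threshold > 0 && pca_threshold <= 1))
    abort_validation("pca_threshold must be in (0, 1]")
  structure(list(pca_threshold = pca_threshold,
                 pca_max_k = as.integer(pca_max_k),
                 hidden_size = hidden_size,
                 n_hidden_layers = as.integer(n_hidden_layers), rbm = rbm,
                 finetune = finetune, finetune_lr = finetune_lr,
                 finetune_epochs = as.integer(finetune_epochs),
                 elm_L = elm_L, variant = variant, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Fit the full pipeline on a training dataset
#'
#' Stages, fitted in order and only on the rows of `train`: per-modality
#' min-max normalization; per-modality snapshot PCA with the smallest
#' component count reaching `pca_threshold` (capped at `pca_max_k`);
#' per-modality rescaling of scores to \[0, 1\]; one sparse-response DBN per
#' modality (pretrained, optionally fine-tuned against the training labels);
#' concatenation of the top-layer features across modalities; and the ELM
#' solved by pseudoinverse. The `pca_elm` variant skips the DBN stage and
#' feeds PCA scores straight to the ELM; `no_sparsity` sets the sparsity
#' weight to zero.
#'
#' @param train a [labeled_dataset()].
#' @param config a [pipeline_config()].
#' @return An object of class `pipeline_bundle` holding every fitted stage
#'   and the exact configuration.
#' @export
fit_pipeline <- function(train, config) {
  if (!inherits(train, "labeled_dataset"))
    abort_validation("train must be a labeled_dataset")
  if (!inherits(config, "pipeline_config"))
    abort_validation("config must be a pipeline_config")
  if (config$variant == "pca_elm" && !is.null(config$hidden_size))
    warning("variant 'pca_elm' has no DBN stage; DBN settings are ignored")
  mods <- names(train$modalities)
  norms <- list(); pcas <- list(); score_norms <- list(); dbns <- list()
  feats <- list()
  n <- length(train$labels)
  for (m in mods) {
    X <- train$modalities[[m]]
    norms[[m]] <- minmax_fit(X)
    X01 <- minmax_apply(norms[[m]], X)
    k_all <- min(n - 1, ncol(X01))
    pca_full <- fit_fast_pca(X01, k_all)
    k <- min(select_k_for_variance(pca_full$explained_variance_ratio,
                                   config$pca_threshold),
             config$pca_max_k)
    pcas[[m]] <- slice_pca(pca_full, k)
    scores <- pca_transform(pcas[[m]], X01)
    if (config$variant == "pca_elm") {
      feats[[m]] <- scores
      next
    }
    ## RBM visible units are [0,1] activations: rescale scores before the DBN
    score_norms[[m]] <- minmax_fit(scores)
    S01 <- minmax_apply(score_norms[[m]], scores)
    hidden <- config$hidden_size %||% k
    dbn <- build_dbn(k, hidden, config$n_hidden_layers,
                     config$rbm$weight_init_sd,
                     derive_seed(config$seed, paste0("dbn_init_", m)))
    rbm_cfg <- config$rbm
    rbm_cfg$seed <- derive_seed(config$seed, paste0("dbn_train_", m))
    if (config$variant == "no_sparsity") rbm_cfg$lam <- 0
    dbn <- pretrain(dbn, S01, rbm_cfg)
    if (config$finetune == "supervised")
      dbn <- finetune(dbn, S01, train$labels, lr = config$finetune_lr,
                      epochs = config$finetune_epochs,
                      seed = derive_seed(config$seed, paste0("ft_", m)))
    dbns[[m]] <- dbn
    feats[[m]] <- extract_features(dbn, S01)
  }
  Fmat <- do.call(cbind, feats)
  L <- config$elm_L %||% min(10L * ncol(Fmat), 1000L)
  elm <- init_elm(ncol(Fmat), L, derive_seed(config$seed, "elm"))
  elm <- fit_elm(elm, Fmat, train$labels, class_names = train$class_names)
  structure(list(format_version = 1L, config = config, modalities = mods,
                 norms = norms, pcas = pcas, score_norms = score_norms,
                 dbns = dbns, elm = elm, class_names = train$class_names),
            class = "pipeline_bundle")
}

slice_pca <- function(model, k) {
  structure(list(mean = model$mean,
                 components = model$components[seq_len(k), , drop = FALSE],
                 explained_variance = model$explained_variance[seq_len(k)],
                 explained_variance_ratio =
                   model$explained_variance_ratio[seq_len(k)]),
            class = "pca_model")
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("<pipeline_bundle> variant '%s', %d modalities, classes: %s\n",
              x$config$variant, length(x$modalities),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Apply a fitted pipeline to new data
#'
#' Pure transformation: applies the stored normalization, PCA projection,
#' DBN forward pass and ELM without refitting anything.
#'
#' @param bundle a fitted `pipeline_bundle`.
#' @param newdata a [labeled_dataset()] or a named list of matrices with the
#'   same modalities the bundle was fitted on.
#' @return List with `codes` (integer class codes), `class` (names) and
#'   `scores` (per-class score matrix, columns named).
#' @export
predict_pipeline <- function(bundle, newdata) {
  mats <- if (inherits(newdata, "labeled_dataset")) newdata$modalities
          else newdata
  if (!identical(sort(names(mats)), sort(bundle$modalities)))
    abort_validation("modalities of newdata do not match the fitted bundle")
  feats <- list()
  for (m in bundle$modalities) {
    X01 <- minmax_apply(bundle$norms[[m]], as.matrix(mats[[m]]))
    scores <- pca_transform(bundle$pcas[[m]], X01)
    feats[[m]] <- if (bundle$config$variant == "pca_elm") scores
    else extract_features(bundle$dbns[[m]],
                          minmax_apply(bundle$score_norms[[m]], scores))
  }
  predict(bundle$elm, do.call(cbind, feats))
}

#' Save a fitted pipeline bundle
#'
#' Serialises every stage, configuration and seed losslessly, with a format
#' version stamp checked on load.
#'
#' @param bundle a `pipeline_bundle`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  if (!inherits(bundle, "pipeline_bundle"))
    abort_validation("bundle must be a pipeline_bundle")
  saveRDS(list(format = "srdbnelm_bundle", version = 1L, bundle = bundle),
          path)
  invisible(path)
}

#' Load a pipeline bundle written by [save_bundle()]
#'
#' @param path file path.
#' @return The `pipeline_bundle`.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: '%s'", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e)
                    abort_io(sprintf("corrupt or unreadable bundle '%s': %s",
                                     path, conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, "srdbnelm_bundle"))
    abort_io(sprintf("'%s' is not a pipeline bundle", path))
  if (!identical(obj$version, 1L))
    abort_io(sprintf("bundle format version %s not supported",
                     format(obj$version)))
  obj$bundle
}
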