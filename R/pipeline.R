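#' Pipeline configuration
#'
#' One configuration object controls featurizer dimensions, training
#' hyperparameters and seeds for the whole step-wise pipeline. The
#' defaults are the original study settings (995-wide descriptor panel,
#' 50-atom graphs, 1905-bit fingerprints, 97-token sequences, 93-long
#' fingerprint-index vectors; Adam 1e-4/100 epochs/batch 32 for base
#' models and 1e-3/300 epochs/batch 32 for the meta model; decision
#' threshold 0.5).
#'
#' @param fractions Step-wise split fractions (base-train, base-valid,
#'   meta-train, meta-valid).
#' @param split_seed Seed for the split shuffle.
#' @param model_seed Base seed for network initialization/training; model
#'   `i` trains with `model_seed + i`.
#' @param desc_width Descriptor panel width.
#' @param max_atoms Graph featurizer atom cap.
#' @param max_len SMILES token-sequence length.
#' @param fp_index_len Fingerprint-index vector length.
#' @param ecfp_bits Embedded fingerprint length.
#' @param base_cfg,meta_cfg [train_config()] objects for the two stages.
#' @param threshold Decision threshold.
#' @param members `NULL` to search all 31 combinations, or a fixed
#'   character subset of `BASE_FEATURE_NAMES` to skip the search.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fractions = c(0.7, 0.1, 0.1, 0.1),
                            split_seed = 42L, model_seed = 1L,
                            desc_width = 995L, max_atoms = 50L,
                            max_len = 97L, fp_index_len = 93L,
                            ecfp_bits = 1024L,
                            base_cfg = train_config(1e-4, 100L),
                            meta_cfg = train_config(1e-3, 300L),
                            threshold = 0.5, members = NULL) {
  structure(list(fractions = fractions, split_seed = as.integer(split_seed),
                 model_seed = as.integer(model_seed),
                 desc_width = as.integer(desc_width),
                 max_atoms = as.integer(max_atoms),
                 max_len = as.integer(max_len),
                 fp_index_len = as.integer(fp_index_len),
                 ecfp_bits = as.integer(ecfp_bits),
                 base_cfg = base_cfg, meta_cfg = meta_cfg,
                 threshold = threshold, members = members),
            class = "pipeline_config")
}

#' Fit featurizer state on the base-training set
#'
#' Learns everything the featurizers need from training data only: the
#' per-descriptor min/max normalizer and the SMILES token vocabulary.
#'
#' @param dataset The base-training [labeled_dataset()].
#' @param config A [pipeline_config()].
#' @return Object of class `featurizer_state` with `normalizer`, `vocab`
#'   and the configured dimensions.
#' @export
fit_featurizer_state <- function(dataset, config = pipeline_config()) {
  smiles <- dataset$records$smiles
  graphs <- lapply(smiles, function(s) with_ring_info(parse_smiles(s)))
  raw <- compute_raw_descriptors(smiles, width = config$desc_width,
                                 graphs = graphs)
  structure(list(normalizer = fit_descriptor_normalizer(raw),
                 vocab = build_token_vocabulary(smiles),
                 config = config),
            class = "featurizer_state")
}

#' Compute all five base-feature views for a dataset
#'
#' Produces the five feature containers (DESC descriptors, MGF graphs,
#' MFP combined fingerprints, SeV token sequences, FPeV fingerprint
#' indices) for every featurizable molecule. Molecules exceeding the atom
#' or token caps are dropped — not truncated — with per-reason counts in
#' the result (`dropped`); all views cover exactly the kept molecules so
#' the base models stay aligned.
#'
#' @param dataset A [labeled_dataset()].
#' @param state A [fit_featurizer_state()] object.
#' @return List with `features` (named list of containers in
#'   `BASE_FEATURE_NAMES` order), `labels`, `smiles` (kept molecules),
#'   `kept` (indices into the dataset) and `dropped` (named counts).
#' @export
featurize_dataset <- function(dataset, state) {
  stopifnot(inherits(state, "featurizer_state"))
  cfg <- state$config
  smiles <- dataset$records$smiles
  labels <- dataset$records$label
  graphs <- lapply(smiles, function(s) with_ring_info(parse_smiles(s)))
  n_atoms <- vapply(graphs, `[[`, integer(1), "n")
  n_tokens <- vapply(smiles, function(s) length(smiles_tokenize(s)), integer(1))
  oversize <- n_atoms > cfg$max_atoms
  overlength <- n_tokens > cfg$max_len
  kept <- which(!oversize & !overlength)
  dropped <- c(oversize = sum(oversize),
               overlength = sum(overlength & !oversize))
  if (length(kept) == 0L) stop("no featurizable molecules left", call. = FALSE)
  smiles <- smiles[kept]; graphs <- graphs[kept]; labels <- labels[kept]

  raw <- compute_raw_descriptors(smiles, width = cfg$desc_width, graphs = graphs)
  desc <- dense_features(apply_descriptor_normalizer(state$normalizer, raw))

  mgf <- graph_features_set(lapply(graphs, featurize_graph,
                                   max_atoms = cfg$max_atoms))

  mfp <- dense_features(t(vapply(graphs, compute_combined_fingerprints,
                                 integer(1905L))))

  sev_ids <- t(vapply(smiles, function(s)
    encode_smiles_tokens(s, state$vocab, max_len = cfg$max_len),
    integer(cfg$max_len), USE.NAMES = FALSE))
  sev <- sequence_features(sev_ids, vocab_size = length(state$vocab))

  fpev_ids <- t(vapply(graphs, function(g)
    compute_fp_index_vector(g, n_bits = cfg$ecfp_bits,
                            max_len = cfg$fp_index_len),
    integer(cfg$fp_index_len)))
  fpev <- sequence_features(fpev_ids, vocab_size = cfg$ecfp_bits)

  list(features = list(DESC = desc, MGF = mgf, MFP = mfp,
                       SeV = sev, FPeV = fpev),
       labels = labels, smiles = smiles, kept = kept, dropped = dropped)
}

.base_spec_for <- function(name, state) {
  cfg <- state$config
  switch(name,
    DESC = base_model_spec("FCNND", input_dim = cfg$desc_width),
    MGF = base_model_spec("GCNN"),
    MFP = base_model_spec("FCNNF"),
    SeV = base_model_spec("C1D_SMILES", vocab_size = length(state$vocab),
                          input_dim = cfg$max_len),
    FPeV = base_model_spec("C1D_FP", vocab_size = cfg$ecfp_bits,
                           input_dim = cfg$fp_index_len))
}

#' Run the full step-wise training pipeline
#'
#' Executes the three stages end to end on one dataset: four-way split,
#' featurizer-state fitting on the base-training part, training of the
#' five base models (validated on the base-validation part with best-epoch
#' selection), meta-feature assembly from base-model probabilities on the
#' meta partitions, the 31-combination search with one meta model per
#' combination (trained on meta-train, scored on meta-valid), and
#' selection of the winning combination. Base models never see meta-train
#' or meta-valid labels — the step-wise isolation that keeps the stacking
#' stage honest — and the returned manifest records the SMILES sets per
#' role so the isolation is auditable ([audit_data_flow()]).
#'
#' @param dataset A reconciled [labeled_dataset()] (it is reconciled again
#'   defensively).
#' @param config A [pipeline_config()].
#' @return Object of class `run_manifest`: split sizes, drop accounting,
#'   per-base-model validation reports, the 31-row combination grid
#'   (`combinations`), the selected combination (`selected`), trained
#'   models, featurizer state and configuration.
#' @export
run_stepwise_training <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "pipeline_config"))
  dataset <- reconcile_labels(dataset)
  split <- stepwise_split(dataset, config$fractions, config$split_seed)
  state <- fit_featurizer_state(split$base_train, config)
  parts <- lapply(split[c("base_train", "base_valid",
                          "meta_train", "meta_valid")],
                  featurize_dataset, state = state)
  fit <- .fit_stack(parts, state, config)
  manifest <- c(fit, list(
    split_sizes = vapply(parts, function(p) length(p$labels), integer(1)),
    dropped = lapply(parts, `[[`, "dropped"),
    role_smiles = lapply(parts, `[[`, "smiles"),
    state = state, config = config,
    dataset_name = dataset$name))
  class(manifest) <- "run_manifest"
  manifest
}

# Shared by single-split and CV paths: train base models on base_train,
# search combinations on the meta partitions.
.fit_stack <- function(parts, state, config) {
  base_models <- list()
  base_valid_report <- list()
  probs <- list(meta_train = list(), meta_valid = list())
  for (i in seq_along(BASE_FEATURE_NAMES)) {
    nm <- BASE_FEATURE_NAMES[i]
    spec <- .base_spec_for(nm, state)
    cfg <- config$base_cfg
    cfg$seed <- config$model_seed + i
    model <- train_base_model(build_base_model(spec, seed = cfg$seed),
                              parts$base_train$features[[nm]],
                              parts$base_train$labels,
                              parts$base_valid$features[[nm]],
                              parts$base_valid$labels, cfg)
    base_models[[nm]] <- model
    base_valid_report[[nm]] <- model$validation
    probs$meta_train[[nm]] <-
      predict_probabilities(model, parts$meta_train$features[[nm]])
    probs$meta_valid[[nm]] <-
      predict_probabilities(model, parts$meta_valid$features[[nm]])
  }

  combos <- enumerate_feature_combinations()
  if (!is.null(config$members)) {
    keep <- vapply(combos$members, function(m)
      setequal(m, config$members) || length(m) == 1L, logical(1))
    combos <- combos[keep, , drop = FALSE]
  }
  grid <- list(); meta_models <- list()
  for (r in seq_len(nrow(combos))) {
    members <- combos$members[[r]]
    mt <- assemble_meta_features(probs$meta_train, members)
    mv <- assemble_meta_features(probs$meta_valid, members)
    mcfg <- config$meta_cfg
    mcfg$seed <- config$model_seed + 100L + r
    mm <- train_meta_model(mt, parts$meta_train$labels, cfg = mcfg,
                           valid_meta = mv,
                           valid_labels = parts$meta_valid$labels)
    p <- predict_probabilities(mm, mv)
    rep <- metric_report(parts$meta_valid$labels, p, config$threshold)
    grid[[r]] <- data.frame(id = combos$id[r], size = combos$size[r],
                            MCC = rep[["MCC"]], NPV = rep[["NPV"]],
                            ACC = rep[["ACC"]], PPV = rep[["PPV"]],
                            SPE = rep[["SPE"]], SEN = rep[["SEN"]],
                            BACC = rep[["BACC"]], AUC = rep[["AUC"]])
    grid[[r]]$members <- list(members)
    meta_models[[combos$id[r]]] <- mm
  }
  grid <- do.call(rbind, grid)
  selected <- select_best_combination(grid)
  list(base_models = base_models,
       base_valid_report = do.call(rbind, base_valid_report),
       combinations = grid,
       selected = selected,
       meta_model = meta_models[[selected$id]],
       meta_models = meta_models)
}

#' @method print run_manifest
#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", x$dataset_name, "\n  split sizes:",
      paste(names(x$split_sizes), x$split_sizes, collapse = ", "),
      "\n  selected combination:", x$selected$id, "(",
      paste(x$selected$members[[1]], collapse = "+"), ")\n")
  invisible(x)
}

#' Audit step-wise data-flow isolation
#'
#' Verifies from the manifest that no molecule appears in more than one of
#' the four roles — in particular that nothing the base models trained on
#' leaks into the meta partitions.
#'
#' @param manifest A [run_stepwise_training()] manifest.
#' @return `TRUE` invisibly; errors on a leak.
#' @export
audit_data_flow <- function(manifest) {
  rs <- manifest$role_smiles
  nms <- names(rs)
  for (a in seq_along(nms)) {
    for (b in seq_along(nms)) {
      if (a >= b) next
      overlap <- intersect(rs[[a]], rs[[b]])
      if (length(overlap) > 0)
        stop("data-flow leak: ", length(overlap), " molecule(s) shared by ",
             nms[a], " and ", nms[b], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Evaluate a trained pipeline on an external test set
#'
#' Standardizes and featurizes the test molecules with the pipeline's
#' fitted state (unfeaturizable molecules are excluded with counts), runs
#' the five base models and the selected meta model, and reports the full
#' metric row at the configured decision threshold.
#'
#' @param manifest A [run_stepwise_training()] manifest.
#' @param test_dataset A [labeled_dataset()].
#' @return List with `metrics` (named vector SEN/SPE/NPV/PPV/ACC/MCC/
#'   BACC/AUC), `probabilities`, `labels`, `dropped` counts.
#' @export
evaluate_on_test_set <- function(manifest, test_dataset) {
  stopifnot(inherits(manifest, "run_manifest"))
  ft <- featurize_dataset(test_dataset, manifest$state)
  members <- manifest$selected$members[[1]]
  probs <- stats::setNames(lapply(members, function(nm)
    predict_probabilities(manifest$base_models[[nm]], ft$features[[nm]])),
    members)
  meta <- assemble_meta_features(probs, members)
  p <- predict_probabilities(manifest$meta_model, meta)
  list(metrics = metric_report(ft$labels, p, manifest$config$threshold),
       probabilities = p, labels = ft$labels, dropped = ft$dropped)
}

#' Consecutive-splitting cross-validated step-wise training
#'
#' Runs the full step-wise pipeline once per fold of a
#' [consecutive_cv_folds()] plan and aggregates the per-fold combination
#' grids into mean and standard-deviation summaries (the
#' cross-validated combination table).
#'
#' @param dataset A reconciled [labeled_dataset()].
#' @param k Fold count (default 10).
#' @param config A [pipeline_config()].
#' @param folds Optional integer subset of folds to run (default all).
#' @return List with `per_fold` (list of per-fold results), `summary`
#'   (mean over folds per combination) and `summary_sd`.
#' @export
run_stepwise_cv <- function(dataset, k = 10L, config = pipeline_config(),
                            folds = NULL) {
  dataset <- reconcile_labels(dataset)
  plan <- consecutive_cv_folds(dataset, k, seed = config$split_seed)
  folds <- folds %||% seq_len(k)
  per_fold <- list()
  for (f in folds) {
    parts <- lapply(stats::setNames(nm = c("base_train", "base_valid",
                                           "meta_train", "meta_valid")),
                    function(role) fold_subset(dataset, plan, f, role))
    state <- fit_featurizer_state(parts$base_train, config)
    fparts <- lapply(parts, featurize_dataset, state = state)
    fit <- .fit_stack(fparts, state, config)
    per_fold[[as.character(f)]] <- fit
  }
  grids <- lapply(per_fold, `[[`, "combinations")
  metric_cols <- c("MCC", "NPV", "ACC", "PPV", "SPE", "SEN", "BACC", "AUC")
  ids <- grids[[1]]$id
  mean_grid <- grids[[1]][, c("id", "size")]
  sd_grid <- grids[[1]][, c("id", "size")]
  for (mc in metric_cols) {
    vals <- vapply(grids, function(g) g[[mc]][match(ids, g$id)],
                   numeric(length(ids)))
    vals <- matrix(vals, nrow = length(ids))
    mean_grid[[mc]] <- rowMeans(vals, na.rm = TRUE)
    sd_grid[[mc]] <- apply(vals, 1, stats::sd, na.rm = TRUE)
  }
  list(per_fold = per_fold, summary = mean_grid, summary_sd = sd_grid,
       plan = plan)
}
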