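#' Base-model architecture specification
#'
#' The five base architectures of the individual prediction stage, one per
#' molecular view:
#' \describe{
#'   \item{FCNND}{fully connected network on the 995-wide descriptor panel;
#'     four hidden layers of decreasing width (default 512-256-128-64),
#'     ReLU, kernel+bias L2 regularization 0.01, dropout 0.5 on the middle
#'     hidden layers, sigmoid output.}
#'   \item{GCNN}{two graph-convolution layers of 64 channels (ReLU, kernel
#'     L2 0.01, symmetric renormalized propagation with internal
#'     self-loops), gated global attention pooling with 1024 channels, one
#'     dense layer of 1024 units, sigmoid output.}
#'   \item{FCNNF}{as FCNND but on the 1905-bit combined fingerprint block
#'     with much smaller hidden widths (default 200-100-50-25).}
#'   \item{C1D_SMILES}{trainable embedding `(vocab+1) x 200` over the
#'     97-long token-id sequence, three 1-D convolutions (192 filters,
#'     kernels 10/5/3, ReLU), global max pooling, dense 128-64, sigmoid
#'     output.}
#'   \item{C1D_FP}{same convolutional architecture over the 93-long
#'     fingerprint-index vector (ids in 0..1024, 0 = pad).}
#' }
#' Hidden widths are reconstructions (the original figures are not fully
#' specified in text) and are configurable.
#'
#' @param kind One of `"FCNND"`, `"GCNN"`, `"FCNNF"`, `"C1D_SMILES"`,
#'   `"C1D_FP"`.
#' @param hidden Hidden layer widths (dense architectures) or dense-head
#'   widths (C1D).
#' @param l2 Kernel/bias regularization weight (default 0.01).
#' @param dropout Dropout rate on middle hidden layers (default 0.5).
#' @param embedding_dim Embedding width for C1D (default 200).
#' @param conv_filters,conv_kernels 1-D convolution stack (defaults 192 and
#'   10/5/3).
#' @param vocab_size Token-vocabulary size (C1D_SMILES) or fingerprint
#'   length (C1D_FP, default 1024).
#' @param input_dim Input width; defaults to the paper configuration of the
#'   chosen kind (995, 65-channel graph, 1905, 97, 93).
#' @return Object of class `base_model_spec`.
#' @export
base_model_spec <- function(kind = c("FCNND", "GCNN", "FCNNF",
                                     "C1D_SMILES", "C1D_FP"),
                            hidden = NULL, l2 = 0.01, dropout = 0.5,
                            embedding_dim = 200L, conv_filters = 192L,
                            conv_kernels = c(10L, 5L, 3L),
                            vocab_size = NULL, input_dim = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    FCNND = list(hidden = c(512L, 256L, 128L, 64L), input_dim = 995L),
    FCNNF = list(hidden = c(200L, 100L, 50L, 25L), input_dim = 1905L),
    GCNN = list(hidden = c(64L, 64L), input_dim = 65L),
    C1D_SMILES = list(hidden = c(128L, 64L), input_dim = 97L),
    C1D_FP = list(hidden = c(128L, 64L), input_dim = 93L))
  hidden <- hidden %||% defaults$hidden
  input_dim <- input_dim %||% defaults$input_dim
  if (kind == "C1D_FP" && is.null(vocab_size)) vocab_size <- 1024L
  stopifnot(all(hidden > 0), input_dim > 0)
  structure(list(kind = kind, hidden = as.integer(hidden), l2 = l2,
                 dropout = dropout, embedding_dim = as.integer(embedding_dim),
                 conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 vocab_size = if (!is.null(vocab_size)) as.integer(vocab_size),
                 input_dim = as.integer(input_dim),
                 pool_channels = 1024L),
            class = "base_model_spec")
}

.layers_for_spec <- function(spec) {
  k <- spec$kind
  if (k %in% c("FCNND", "FCNNF")) {
    nh <- length(spec$hidden)
    middle <- if (nh >= 3) 2:(nh - 1) else integer(0)
    layers <- lapply(seq_len(nh), function(i) {
      nn_dense(spec$hidden[i], "relu", l2 = spec$l2, l2_bias = spec$l2,
               dropout = if (i %in% middle) spec$dropout else 0)
    })
    c(layers, list(nn_dense(1L, "linear", l2 = spec$l2, l2_bias = spec$l2)))
  } else if (k == "GCNN") {
    list(nn_graph_conv(spec$hidden[1], l2 = spec$l2),
         nn_graph_conv(spec$hidden[2], l2 = spec$l2),
         nn_gated_pool(spec$pool_channels),
         nn_dense(spec$pool_channels, "relu"),
         nn_dense(1L, "linear"))
  } else {
    if (is.null(spec$vocab_size))
      stop("C1D specs need vocab_size before building", call. = FALSE)
    layers <- list(nn_embedding(spec$vocab_size, spec$embedding_dim))
    for (kk in spec$conv_kernels)
      layers <- c(layers, list(nn_conv1d(spec$conv_filters, kk)))
    layers <- c(layers, list(nn_global_max_pool()))
    for (h in spec$hidden) layers <- c(layers, list(nn_dense(h, "relu")))
    c(layers, list(nn_dense(1L, "linear")))
  }
}

#' Build an untrained base model
#'
#' Instantiates the network of a [base_model_spec()] with Glorot-uniform
#' initial weights (seeded).
#'
#' @param spec A [base_model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `base_model`: list with `spec`, `net`,
#'   `trained = FALSE`.
#' @export
build_base_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "base_model_spec"))
  set.seed(as.integer(seed))
  input_dim <- switch(spec$kind,
    GCNN = 65L,
    C1D_SMILES = , C1D_FP = spec$input_dim,   # sequence length; embedding sets width
    spec$input_dim)
  net <- .nn_build(.layers_for_spec(spec), input_dim)
  structure(list(spec = spec, net = net, trained = FALSE, history = NULL,
                 validation = NULL),
            class = "base_model")
}

#' @method print base_model
#' @export
print.base_model <- function(x, ...) {
  np <- n_parameters(x)
  cat("base_model", x$spec$kind, if (x$trained) "(trained)" else "(untrained)",
      "-", np, "parameters\n")
  invisible(x)
}

#' Total trainable parameter count of a model
#'
#' @param model A `base_model` or `meta_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$net$layers, function(ly) {
    sum(vapply(.param_names(ly), function(p) length(ly[[p]]), numeric(1)))
  }, numeric(1)))
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (paper setting 1e-4 for base
#'   models, 1e-3 for the meta model).
#' @param epochs Training epochs (paper: 100 base / 300 meta).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param keep_best Keep the epoch checkpoint with the best validation AUC
#'   (default `TRUE`); otherwise final-epoch weights are kept.
#' @param verbose Print per-epoch progress.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100L,
                         batch_size = 32L, seed = 1L, keep_best = TRUE,
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 keep_best = keep_best, verbose = verbose),
            class = "train_config")
}

# ---- feature containers -------------------------------------------------

#' Feature containers for model training
#'
#' Wrap featurized data in the batchable container the training loop
#' consumes. `dense_features` holds a numeric matrix (descriptors,
#' fingerprint bits or meta features); `sequence_features` holds an integer
#' id matrix (token ids or fingerprint indices; 0 = pad);
#' `graph_features_set` holds the padded node/adjacency pairs of
#' [featurize_graph()] with the renormalized propagation matrix
#' precomputed.
#'
#' @param X Numeric matrix (molecules x features).
#' @return A feature container (class `feature_container`).
#' @export
dense_features <- function(X) {
  X <- as.matrix(X)
  structure(list(kind = "dense", X = X, n = nrow(X), dim = ncol(X)),
            class = "feature_container")
}

#' @rdname dense_features
#' @param ids Integer matrix (molecules x sequence length); 0 is the pad id.
#' @param vocab_size Number of non-pad ids.
#' @export
sequence_features <- function(ids, vocab_size) {
  ids <- as.matrix(ids)
  storage.mode(ids) <- "integer"
  structure(list(kind = "seq", ids = ids, vocab_size = as.integer(vocab_size),
                 n = nrow(ids), dim = ncol(ids)),
            class = "feature_container")
}

#' @rdname dense_features
#' @param graphs List of [featurize_graph()] outputs.
#' @export
graph_features_set <- function(graphs) {
  n <- length(graphs)
  stopifnot(n > 0)
  N <- nrow(graphs[[1]]$nodes)
  H <- do.call(rbind, lapply(graphs, `[[`, "nodes"))
  mask <- unlist(lapply(graphs, function(g)
    c(rep(1, g$n_atoms), rep(0, N - g$n_atoms))))
  ahat <- lapply(graphs, function(g) {
    A <- g$adjacency
    if (g$n_atoms > 0) {
      idx <- seq_len(g$n_atoms)
      A[cbind(idx, idx)] <- 1            # self-loops on real atoms
      d <- rowSums(A[idx, , drop = FALSE])
      dinv <- 1 / sqrt(pmax(d, 1))
      A[idx, ] <- A[idx, , drop = FALSE] * dinv
      A[, idx] <- sweep(A[, idx, drop = FALSE], 2, dinv, "*")
    }
    methods::as(A, "CsparseMatrix")
  })
  structure(list(kind = "graph", H = H, ahat = ahat, mask = mask,
                 N = N, n = n, dim = ncol(H)),
            class = "feature_container")
}

#' @method print feature_container
#' @export
print.feature_container <- function(x, ...) {
  cat("feature_container(", x$kind, "): ", x$n, " molecules, width ",
      x$dim, "\n", sep = "")
  invisible(x)
}

.container_batch <- function(fc, idx) {
  if (fc$kind == "dense") {
    fc$X[idx, , drop = FALSE]
  } else if (fc$kind == "seq") {
    list(ids = fc$ids[idx, , drop = FALSE])
  } else {
    N <- fc$N
    rows <- as.vector(vapply(idx, function(i) ((i - 1L) * N + 1L):(i * N),
                             integer(N)))
    m <- length(idx)
    list(H = fc$H[rows, , drop = FALSE],
         Ahat = Matrix::bdiag(fc$ahat[idx]),
         mask = fc$mask[rows],
         group = rep(seq_len(m), each = N),
         B = m, N = N)
  }
}

.check_features <- function(spec, fc) {
  if (!inherits(fc, "feature_container"))
    stop("features must be a feature_container", call. = FALSE)
  ok <- switch(spec$kind,
    FCNND = , FCNNF = fc$kind == "dense" && fc$dim == spec$input_dim,
    GCNN = fc$kind == "graph" && fc$dim == 65L,
    C1D_SMILES = , C1D_FP = fc$kind == "seq" && fc$dim == spec$input_dim)
  if (!ok)
    stop("feature shape/kind mismatch for ", spec$kind, ": got ", fc$kind,
         " width ", fc$dim, ", expected ",
         switch(spec$kind, GCNN = "graph width 65",
                paste0(if (spec$kind %in% c("FCNND", "FCNNF")) "dense" else "seq",
                       " width ", spec$input_dim)),
         call. = FALSE)
  invisible(TRUE)
}

# ---- training -----------------------------------------------------------

.train_network <- function(layers, input_dim, features, labels,
                           valid_features, valid_labels, cfg) {
  set.seed(cfg$seed)
  net <- .nn_build(layers, input_dim)
  state <- .adam_init(net)
  n <- features$n
  has_val <- !is.null(valid_features) && !is.null(valid_labels)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     valid_loss = numeric(0), valid_auc = numeric(0))
  best <- list(auc = -Inf, net = net)
  t_global <- 0L
  if (cfg$epochs > 0) {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (s in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        x <- .container_batch(features, idx)
        fw <- .nn_forward(net, x, training = TRUE)
        lo <- .bce_with_logits(fw$out, labels[idx])
        losses <- c(losses, lo$loss + .l2_penalty(net))
        grads <- .nn_backward(net, fw$caches, lo$dz)
        t_global <- t_global + 1L
        upd <- .adam_step(net, grads, state, cfg$learning_rate, t_global)
        net <- upd$net; state <- upd$state
      }
      vloss <- NA_real_; vauc <- NA_real_
      if (has_val) {
        vlogit <- .predict_logits(net, valid_features)
        vloss <- .bce_with_logits(vlogit, valid_labels)$loss
        vauc <- suppressWarnings(auc_roc(valid_labels, vlogit))
        if (cfg$keep_best && !is.na(vauc) && vauc > best$auc)
          best <- list(auc = vauc, net = net)
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                     valid_loss = vloss, valid_auc = vauc))
      if (cfg$verbose)
        message(sprintf("epoch %d: loss %.4f valid_auc %.3f", ep,
                        mean(losses), vauc))
    }
  }
  if (has_val && cfg$keep_best && is.finite(best$auc)) net <- best$net
  list(net = net, history = hist)
}

.predict_logits <- function(net, features, chunk = 256L) {
  n <- features$n
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    x <- .container_batch(features, idx)
    out[idx] <- as.vector(.nn_forward(net, x, training = FALSE)$out)
  }
  out
}

#' Train a base model
#'
#' Seeded minibatch training with Adam on binary cross-entropy, keeping
#' the epoch checkpoint with the best validation AUC (model selection on
#' the base-validation set). Feature shapes are validated before any
#' training starts. With `cfg$epochs = 0` the model keeps its (seeded)
#' initial weights.
#'
#' @param model A [build_base_model()] object (or a [base_model_spec()]).
#' @param features,labels Training [dense_features()]/[sequence_features()]
#'   /[graph_features_set()] container and binary 0/1 labels.
#' @param valid_features,valid_labels Validation container and labels (may
#'   be `NULL`).
#' @param cfg A [train_config()].
#' @return The trained `base_model` with `history` (per-epoch losses and
#'   validation AUC) and `validation` (the [metric_report()] on the
#'   validation set).
#' @export
train_base_model <- function(model, features, labels,
                             valid_features = NULL, valid_labels = NULL,
                             cfg = train_config()) {
  if (inherits(model, "base_model_spec")) model <- build_base_model(model)
  stopifnot(inherits(model, "base_model"), inherits(cfg, "train_config"))
  spec <- model$spec
  .check_features(spec, features)
  if (!is.null(valid_features)) .check_features(spec, valid_features)
  if (features$n != length(labels))
    stop("labels length does not match feature rows", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  input_dim <- if (spec$kind == "GCNN") 65L else spec$input_dim
  res <- .train_network(.layers_for_spec(spec), input_dim, features, labels,
                        valid_features, valid_labels, cfg)
  model$net <- res$net
  model$history <- res$history
  model$trained <- cfg$epochs > 0
  if (!is.null(valid_features)) {
    p <- predict_probabilities(model, valid_features)
    model$validation <- metric_report(valid_labels, p)
  }
  model
}

#' Predict blocker probabilities
#'
#' @param model A trained (or initialized) `base_model` or `meta_model`.
#' @param features A matching feature container (or numeric matrix for
#'   meta/dense models).
#' @return Numeric vector of probabilities in `[0, 1]`, one per molecule.
#' @export
predict_probabilities <- function(model, features) {
  if (is.matrix(features)) features <- dense_features(features)
  if (inherits(model, "base_model")) .check_features(model$spec, features)
  stats::plogis(.predict_logits(model$net, features))
}
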