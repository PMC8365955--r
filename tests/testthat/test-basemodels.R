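test_that("FCNND parameter count matches hand arithmetic", {
  m <- build_base_model(base_model_spec("FCNND"), seed = 1)
  # (995*512+512)+(512*256+256)+(256*128+128)+(128*64+64)+(64*1+1)
  expect_equal(n_parameters(m), 682497)
  mf <- build_base_model(base_model_spec("FCNNF"), seed = 1)
  expect_equal(n_parameters(mf),
               (1905 * 200 + 200) + (200 * 100 + 100) + (100 * 50 + 50) +
                 (50 * 25 + 25) + (25 + 1))
})

test_that("GCNN and C1D architectures follow their specifications", {
  g <- build_base_model(base_model_spec("GCNN"), seed = 1)
  expect_equal(ncol(g$net$layers[[1]]$W), 64L)       # first layer channels
  expect_equal(ncol(g$net$layers[[3]]$Wg), 1024L)    # attention channels
  expect_equal(dim(g$net$layers[[4]]$W), c(1024L, 1024L))
  c1 <- build_base_model(base_model_spec("C1D_SMILES", vocab_size = 64),
                         seed = 1)
  expect_equal(dim(c1$net$layers[[1]]$E), c(65L, 200L))  # vocab + pad rows
  expect_equal(dim(c1$net$layers[[2]]$W), c(10 * 200L, 192L))
  expect_equal(dim(c1$net$layers[[3]]$W), c(5 * 192L, 192L))
  expect_equal(dim(c1$net$layers[[4]]$W), c(3 * 192L, 192L))
  c2 <- build_base_model(base_model_spec("C1D_FP"), seed = 1)
  expect_equal(dim(c2$net$layers[[1]]$E), c(1025L, 200L))
  expect_error(base_model_spec("FCNNX"))
})

test_that("shape mismatches error before training starts", {
  X <- matrix(runif(20 * 10), 20)
  expect_error(train_base_model(base_model_spec("FCNND"), dense_features(X),
                                rbinom(20, 1, 0.5)), "mismatch")
  expect_error(train_base_model(base_model_spec("FCNNF"),
                                sequence_features(matrix(1L, 5, 1905), 10),
                                rbinom(5, 1, 0.5)), "mismatch")
  Xd <- matrix(runif(20 * 995), 20)
  expect_error(train_base_model(base_model_spec("FCNND"), dense_features(Xd),
                                rbinom(19, 1, 0.5)), "labels length")
  expect_error(train_base_model(base_model_spec("FCNND"), dense_features(Xd),
                                rep(2, 20)), "binary")
})

test_that("untrained models sit at chance on balanced random data", {
  set.seed(3)
  X <- matrix(runif(300 * 995), 300)
  y <- rep(0:1, 150)
  m <- train_base_model(base_model_spec("FCNND"), dense_features(X), y,
                        dense_features(X), y,
                        train_config(epochs = 0, seed = 2))
  expect_false(m$trained)
  p <- predict_probabilities(m, dense_features(X))
  expect_equal(suppressWarnings(auc_roc(y, p)), 0.5, tolerance = 0.1)
})

test_that("probabilities are bounded, sized, and inference-deterministic", {
  set.seed(6)
  specs <- list(base_model_spec("FCNND"), base_model_spec("FCNNF"))
  containers <- list(dense_features(matrix(runif(15 * 995), 15)),
                     dense_features(matrix(rbinom(15 * 1905, 1, 0.1), 15)))
  for (i in 1:2) {
    m <- build_base_model(specs[[i]], seed = i)
    p <- predict_probabilities(m, containers[[i]])
    expect_length(p, 15L)
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(p, predict_probabilities(m, containers[[i]]))
  }
  ds <- synth_small()
  graphs <- lapply(ds$records$smiles[1:10], featurize_graph)
  gc <- graph_features_set(graphs)
  mg <- build_base_model(base_model_spec("GCNN"), seed = 4)
  pg <- predict_probabilities(mg, gc)
  expect_true(all(pg >= 0 & pg <= 1) && length(pg) == 10)
  vocab <- build_token_vocabulary(ds$records$smiles)
  ids <- t(vapply(ds$records$smiles[1:10], function(s)
    encode_smiles_tokens(s, vocab), integer(97)))
  ms <- build_base_model(base_model_spec("C1D_SMILES",
                                         vocab_size = length(vocab)), seed = 4)
  ps <- predict_probabilities(ms, sequence_features(ids, length(vocab)))
  expect_true(all(ps >= 0 & ps <= 1) && length(ps) == 10)
})

test_that("seeded training is repeatable and learns the planted rule", {
  ds <- synth_small()
  y <- ds$records$label
  X <- t(vapply(ds$records$smiles, compute_combined_fingerprints,
                integer(1905)))
  tr <- 1:110; va <- 111:160
  cfg <- train_config(1e-3, epochs = 4, seed = 9)
  m1 <- train_base_model(base_model_spec("FCNNF"), dense_features(X[tr, ]),
                         y[tr], dense_features(X[va, ]), y[va], cfg)
  m2 <- train_base_model(base_model_spec("FCNNF"), dense_features(X[tr, ]),
                         y[tr], dense_features(X[va, ]), y[va], cfg)
  expect_identical(m1$history, m2$history)           # identical loss curve
  expect_gt(m1$validation[["AUC"]], 0.9)
})

test_that("GCNN output is invariant to atom reordering", {
  ds <- synth_small()
  graphs <- lapply(ds$records$smiles[1:8], featurize_graph)
  m <- build_base_model(base_model_spec("GCNN"), seed = 12)
  p0 <- predict_probabilities(m, graph_features_set(graphs))
  set.seed(2)
  permuted <- lapply(graphs, function(g) {
    perm <- sample(g$n_atoms)                        # permute real atoms only
    full <- c(perm, setdiff(seq_len(nrow(g$nodes)), seq_len(g$n_atoms)))
    list(nodes = g$nodes[full, ], adjacency = g$adjacency[full, full],
         n_atoms = g$n_atoms)
  })
  p1 <- predict_probabilities(m, graph_features_set(permuted))
  expect_equal(p0, p1, tolerance = 1e-10)
})
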