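test_that("descriptor normalizer maps to [0,1] with clipping and constants", {
  M <- cbind(a = c(0, 10), b = c(3, 3))
  nz <- fit_descriptor_normalizer(M)
  expect_equal(unname(nz$min), c(0, 3))
  expect_true(nz$constant[["b"]])
  out <- apply_descriptor_normalizer(nz, c(a = 5, b = 3))
  expect_equal(unname(out), c(0.5, 0))
  expect_equal(unname(apply_descriptor_normalizer(nz, c(a = 20, b = 9))),
               c(1, 0))                              # clipped / constant
  expect_equal(unname(apply_descriptor_normalizer(nz, c(a = -3, b = 0))),
               c(0, 0))
  expect_error(fit_descriptor_normalizer(M[1, , drop = FALSE]), "2 rows")
})

test_that("descriptor panel has fixed width and hand-checkable counts", {
  raw <- compute_raw_descriptors(c("CC", "CCO", "c1ccccc1"))
  expect_equal(dim(raw), c(3L, 995L))
  expect_true(all(is.finite(raw)))
  expect_equal(unname(raw[1, "nHeavyAtom"]), 2)              # ethane
  expect_equal(unname(raw[1, "nH"]), 6)
  expect_equal(unname(raw[2, "count_O"]), 1)
  expect_equal(unname(raw[3, "nAromAtom"]), 6)
  expect_equal(unname(raw[3, "nRing"]), 1)
  expect_equal(unname(raw[3, "Wiener"]), 27)                 # benzene, by hand
  # determinism
  raw2 <- compute_raw_descriptors(c("CC", "CCO", "c1ccccc1"))
  expect_identical(raw, raw2)
})

test_that("normalized descriptors of the fitting set lie in [0,1]", {
  ds <- synth_small()
  smi <- ds$records$smiles[1:40]
  raw <- compute_raw_descriptors(smi)
  nz <- fit_descriptor_normalizer(raw)
  out <- apply_descriptor_normalizer(nz, raw)
  expect_true(all(out >= 0 & out <= 1))
  v <- compute_descriptor_vector(smi[1], nz)
  expect_length(v, 995L)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("graph featurizer emits 50x65 nodes and symmetric adjacency", {
  gf <- featurize_graph("c1ccccc1")
  expect_equal(dim(gf$nodes), c(50L, 65L))
  expect_equal(dim(gf$adjacency), c(50L, 50L))
  expect_equal(sum(rowSums(gf$nodes) > 0), 6L)
  expect_equal(sum(gf$adjacency), 12)                # 6 ring bonds, symmetric
  expect_identical(gf$adjacency, t(gf$adjacency))
  gm <- featurize_graph("C")
  expect_equal(sum(rowSums(gm$nodes) > 0), 1L)
  expect_equal(sum(gm$adjacency), 0)
  long <- paste(rep("C", 51), collapse = "")
  expect_error(featurize_graph(long), "exceeds 50")
})

test_that("graph adjacency and padding properties hold on a synthetic batch", {
  ds <- synth_small()
  for (s in ds$records$smiles[1:25]) {
    g <- parse_smiles(s)
    gf <- featurize_graph(g)
    expect_identical(gf$adjacency, t(gf$adjacency))
    if (g$n < 50) {
      pad <- (g$n + 1):50
      expect_true(all(gf$nodes[pad, ] == 0))
      expect_true(all(gf$adjacency[pad, ] == 0))
      expect_true(all(gf$adjacency[, pad] == 0))
    }
    expect_equal(sum(gf$adjacency), 2 * nrow(g$bonds))
  }
})

test_that("combined fingerprint is a 1905-long 0/1 block, SMILES-order invariant", {
  fp <- compute_combined_fingerprints("c1ccccc1CCN")
  expect_length(fp, 1905L)
  expect_true(all(fp %in% c(0L, 1L)))
  # two SMILES writings of the same molecule
  expect_identical(compute_combined_fingerprints("OCC"),
                   compute_combined_fingerprints("C(O)C"))
  expect_identical(compute_combined_fingerprints("c1ccccc1O"),
                   compute_combined_fingerprints("Oc1ccccc1"))
})

test_that("element-count keys of the substructure block behave hierarchically", {
  keys_ccl4 <- pubchem_like_keys("C(Cl)(Cl)(Cl)Cl")
  nm <- hergstack:::.pubchem_element_counts
  idx_cl1 <- which(nm$element == "Cl" & nm$threshold == 1)
  idx_cl4 <- which(nm$element == "Cl" & nm$threshold == 4)
  idx_cl8 <- which(nm$element == "Cl" & nm$threshold == 8)
  idx_c2 <- which(nm$element == "C" & nm$threshold == 2)
  expect_equal(keys_ccl4[idx_cl1], 1L)
  expect_equal(keys_ccl4[idx_cl4], 1L)
  expect_equal(keys_ccl4[idx_cl8], 0L)
  expect_equal(keys_ccl4[idx_c2], 0L)               # only one carbon
  expect_length(keys_ccl4, 881L)
})

test_that("token vocabulary is deterministic with a reserved pad", {
  v <- build_token_vocabulary(c("CCO", "CCN"))
  expect_equal(v$tokens, c("C", "N", "O"))
  expect_equal(v$pad_index, 0L)
  expect_length(v, 3L)                               # + pad = 4 symbols total
  v2 <- build_token_vocabulary(c("CCN", "CCO"))      # order-independent
  expect_identical(v$index, v2$index)
  vcl <- build_token_vocabulary("Clc1ccccc1")
  expect_true("Cl" %in% vcl$tokens)
  expect_true("c" %in% vcl$tokens)
  expect_true("1" %in% vcl$tokens)
  expect_false("l" %in% vcl$tokens)
})

test_that("token encoding pads to 97, round-trips, and guards length", {
  v <- build_token_vocabulary(c("CCO", "CCN", "c1ccccc1"))
  ids <- encode_smiles_tokens("CCO", v)
  expect_length(ids, 97L)
  expect_equal(sum(ids != 0), 3L)
  expect_equal(decode_token_ids(ids, v), "CCO")
  expect_error(encode_smiles_tokens(strrep("C", 98), v), "exceeding")
  expect_warning(idsu <- encode_smiles_tokens("CCS", v), "unknown")
  expect_equal(sum(idsu != 0), 2L)                   # S mapped to pad
  expect_error(encode_smiles_tokens("CCS", v, strict = TRUE), "unknown")
  # serialization round-trip
  path <- tempfile(fileext = ".json")
  write_token_vocabulary(v, path)
  v3 <- read_token_vocabulary(path)
  expect_identical(v$index, v3$index)
})

test_that("fingerprint index vector is sorted, padded and capped", {
  fpi <- compute_fp_index_vector("c1ccccc1CCN")
  expect_length(fpi, 93L)
  on <- fpi[fpi != 0]
  expect_true(all(diff(on) > 0))                     # strictly increasing
  expect_true(all(on >= 1 & on <= 1024))
  expect_true(all(fpi[(length(on) + 1):93] == 0))    # sentinel tail
  expect_warning(tr <- compute_fp_index_vector("c1ccccc1CCN", max_len = 5),
                 "truncating")
  expect_length(tr, 5L)
  # matches the on-bit oracle of the underlying fingerprint
  bits <- morgan_fingerprint("c1ccccc1CCN", 2, 1024)
  expect_equal(on, which(bits == 1L))
})

test_that("featurizers are deterministic pure functions", {
  s <- "CC(C)Cc1ccc(cc1)C(C)C(=O)O"
  expect_identical(compute_combined_fingerprints(s),
                   compute_combined_fingerprints(s))
  expect_identical(featurize_graph(s), featurize_graph(s))
  expect_identical(compute_fp_index_vector(s), compute_fp_index_vector(s))
})
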