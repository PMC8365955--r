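# 65-dim one-hot atom feature layout:
#   element one-hot over .element_symbols (43)
#   + degree one-hot 0..5 (6) + total-H one-hot 0..4 (5)
#   + implicit valence one-hot 0..5 (6) + aromatic flag (1)
#   + formal charge one-hot -2..+2 truncated to fit exactly 65 dims,
# i.e. the +2 charge slot is dropped (a +2 formal charge on a single atom
# does not occur in the standardized, neutralized datasets this featurizer
# serves).
.ATOM_FEATURE_DIM <- 65L

.atom_features <- function(g, a) {
  f <- numeric(66L)
  k <- match(g$element[a], .element_symbols)
  if (!is.na(k)) f[k] <- 1
  deg <- min(g$degree[a], 5L); f[43L + deg + 1L] <- 1
  hh <- min(g$hcount[a], 4L);  f[49L + hh + 1L] <- 1
  val <- min(g$degree[a] + g$hcount[a], 5L); f[54L + val + 1L] <- 1
  f[61L] <- as.numeric(g$aromatic[a])
  chg <- max(-2L, min(2L, g$charge[a])); f[61L + chg + 3L] <- 1
  f[seq_len(.ATOM_FEATURE_DIM)]
}

#' Molecular graph features for the graph-convolutional base model
#'
#' Converts a molecule into the fixed-shape pair used by the GCNN base
#' model: a `max_atoms x 65` node feature matrix (one-hot atom descriptors,
#' zero-padded rows beyond the true atom count) and a symmetric
#' `max_atoms x max_atoms` 0/1 adjacency matrix without self-loops.
#' The graph-convolution layer adds self-loops and applies the symmetric
#' degree renormalization internally, so the adjacency here is the raw
#' bond-incidence matrix.
#'
#' @param smiles A canonical SMILES string or a `mol_graph`.
#' @param max_atoms Maximum heavy-atom count (default 50). Molecules with
#'   more heavy atoms raise an oversize error naming the molecule; callers
#'   typically drop such molecules with a logged count.
#' @return List with `nodes` (`max_atoms x 65` matrix), `adjacency`
#'   (`max_atoms x max_atoms` matrix) and `n_atoms`.
#' @export
featurize_graph <- function(smiles, max_atoms = 50L) {
  g <- if (inherits(smiles, "mol_graph")) smiles else parse_smiles(smiles)
  if (g$n > max_atoms)
    stop("molecule exceeds ", max_atoms, " heavy atoms (", g$n, "): ",
         g$smiles, call. = FALSE)
  nodes <- matrix(0, nrow = max_atoms, ncol = .ATOM_FEATURE_DIM)
  for (a in seq_len(g$n)) nodes[a, ] <- .atom_features(g, a)
  adjacency <- matrix(0, nrow = max_atoms, ncol = max_atoms)
  if (nrow(g$bonds) > 0) {
    adjacency[cbind(g$bonds$i, g$bonds$j)] <- 1
    adjacency[cbind(g$bonds$j, g$bonds$i)] <- 1
  }
  list(nodes = nodes, adjacency = adjacency, n_atoms = g$n)
}
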