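# Deterministic integer hashing for fingerprint environments.
# Polynomial rolling hash mod a Mersenne prime; all intermediates stay
# below 2^53 so double arithmetic is exact.
.HASH_P <- 2147483647

.hash_combine <- function(h, xs) {
  for (x in xs) h <- (h * 31 + (x %% .HASH_P)) %% .HASH_P
  h
}

#' Morgan (extended-connectivity) fingerprint
#'
#' In-package Morgan/ECFP implementation on the parsed molecular graph.
#' Atom environments are grown iteratively: the round-0 identifier hashes
#' the atom's element, degree, hydrogen count, formal charge, aromaticity
#' and ring membership; each subsequent round hashes the previous
#' identifier together with the sorted (bond-order, neighbor-identifier)
#' pairs. All identifiers from rounds `0..radius` are folded onto `n_bits`
#' positions. Identifiers are stable across platforms and invariant to the
#' SMILES writing order of a molecule.
#'
#' Note the diameter/radius convention: "ECFP2" denotes diameter 2, i.e.
#' `radius = 1`; the radius-2 fingerprint corresponds to ECFP4.
#'
#' @param smiles A canonical SMILES string, or a `mol_graph` from
#'   [parse_smiles()].
#' @param radius Neighborhood radius (number of growth rounds).
#' @param n_bits Folded fingerprint length.
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  bits <- integer(n_bits)
  bits[unique(morgan_on_bits(smiles, radius, n_bits))] <- 1L
  bits
}

#' On-bit positions of a Morgan fingerprint
#'
#' @inheritParams morgan_fingerprint
#' @return Sorted unique integer vector of 1-based on-bit positions.
#' @export
morgan_on_bits <- function(smiles, radius = 2L, n_bits = 2048L) {
  g <- if (inherits(smiles, "mol_graph")) smiles else parse_smiles(smiles)
  ri <- .get_ring_info(g)
  elem_code <- vapply(g$element, function(e) {
    k <- match(e, .element_symbols)
    if (is.na(k)) 999 else k
  }, numeric(1), USE.NAMES = FALSE)
  ids <- vapply(seq_len(g$n), function(a) {
    .hash_combine(7, c(elem_code[a], g$degree[a], g$hcount[a],
                       g$charge[a] + 10, as.numeric(g$aromatic[a]),
                       as.numeric(ri$atom_ring[a])))
  }, numeric(1))
  all_ids <- ids
  if (g$n > 0 && radius > 0 && nrow(g$bonds) > 0) {
    nbr <- vector("list", g$n)
    for (k in seq_len(nrow(g$bonds))) {
      ocode <- if (g$bonds$aromatic[k]) 15 else g$bonds$order[k] * 10
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      nbr[[i]] <- rbind(nbr[[i]], c(ocode, j))
      nbr[[j]] <- rbind(nbr[[j]], c(ocode, i))
    }
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (a in seq_len(g$n)) {
        nb <- nbr[[a]]
        if (is.null(nb)) next
        pairs <- cbind(nb[, 1], ids[nb[, 2]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        new_ids[a] <- .hash_combine(r + 11, c(ids[a], t(pairs)))
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  sort(unique(as.integer(all_ids %% n_bits) + 1L))
}

# Element symbol table shared by fingerprints, atom features and descriptors.
.element_symbols <- c(
  "C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B",
  "Si", "Se", "As", "Te", "H", "Li", "Na", "K", "Mg", "Ca",
  "Fe", "Zn", "Cu", "Mn", "Co", "Ni", "Cr", "Mo", "V", "Al",
  "Sn", "Sb", "Bi", "Hg", "Pb", "Cd", "Ag", "Au", "Pt", "Pd",
  "Ge", "Ti", "Be"
)

# PubChem-style section 1: hierarchic element-count keys (element, threshold).
.pubchem_element_counts <- local({
  spec <- list(
    c("H", 4), c("H", 8), c("H", 16), c("H", 32),
    c("Li", 1), c("Li", 2),
    c("B", 1), c("B", 2), c("B", 4),
    c("C", 2), c("C", 4), c("C", 8), c("C", 16), c("C", 32),
    c("N", 1), c("N", 2), c("N", 4), c("N", 8),
    c("O", 1), c("O", 2), c("O", 4), c("O", 8), c("O", 16),
    c("F", 1), c("F", 2), c("F", 4),
    c("Na", 1), c("Na", 2),
    c("Si", 1), c("Si", 2),
    c("P", 1), c("P", 2), c("P", 4),
    c("S", 1), c("S", 2), c("S", 4), c("S", 8),
    c("Cl", 1), c("Cl", 2), c("Cl", 4), c("Cl", 8),
    c("K", 1), c("K", 2),
    c("Br", 1), c("Br", 2), c("Br", 4),
    c("I", 1), c("I", 2), c("I", 4),
    c("Be", 1), c("Mg", 1), c("Al", 1), c("Ca", 1), c("Sc", 1), c("Ti", 1),
    c("V", 1), c("Cr", 1), c("Mn", 1), c("Fe", 1), c("Co", 1), c("Ni", 1),
    c("Cu", 1), c("Zn", 1), c("Ga", 1), c("Ge", 1), c("As", 1), c("Se", 1),
    c("Kr", 1), c("Rb", 1), c("Sr", 1), c("Y", 1), c("Zr", 1), c("Nb", 1),
    c("Mo", 1), c("Ru", 1), c("Rh", 1), c("Pd", 1), c("Ag", 1), c("Cd", 1),
    c("In", 1), c("Sn", 1), c("Sb", 1), c("Te", 1), c("Xe", 1), c("Cs", 1),
    c("Ba", 1), c("Lu", 1), c("Hf", 1), c("Ta", 1), c("W", 1), c("Re", 1),
    c("Os", 1), c("Ir", 1), c("Pt", 1), c("Au", 1), c("Hg", 1), c("Tl", 1),
    c("Pb", 1), c("Bi", 1), c("La", 1), c("Ce", 1), c("Pr", 1), c("Nd", 1),
    c("Sm", 1), c("Eu", 1), c("Gd", 1), c("Tb", 1), c("Dy", 1), c("Ho", 1),
    c("Er", 1), c("Tm", 1), c("Yb", 1), c("Tc", 1), c("U", 1)
  )
  data.frame(element = vapply(spec, `[`, character(1), 1),
             threshold = as.integer(vapply(spec, `[`, character(1), 2)))
})

# Bonded element-pair keys (section-3 style).
.pubchem_atom_pairs <- c(
  "C-C", "C-N", "C-O", "C-S", "C-F", "C-Cl", "C-Br", "C-I", "C-P", "C-B",
  "C-Si", "N-N", "N-O", "N-S", "N-P", "N-F", "N-Cl", "N-Br", "O-O", "O-S",
  "O-P", "S-S", "S-P", "P-P", "O-Si", "B-N", "B-O", "C-Se", "N-Se", "O-Se",
  "S-Cl", "S-F", "P-F", "P-Cl", "Si-Si", "B-F", "C-As", "O-As", "C-Te",
  "B-B", "N-I", "O-F", "O-Cl", "O-Br", "O-I", "S-N", "S-Br", "S-I",
  "P-O", "P-S", "Se-Se", "As-As", "C-H", "N-H"
)

#' PubChem-style 881-bit substructure keys (stand-in)
#'
#' A documented, synthetic stand-in for the 881-bit PubChem/CACTVS
#' substructure keys: no implementation of the published key definition is
#' available in this stack, and downstream models only require a fixed
#' 881-long 0/1 block. Layout: bits 1-115 are hierarchic element-count keys
#' following the published section-1 table; bits 116-263 are ring-count
#' keys (smallest-ring sizes 3-10 crossed with count thresholds, plus
#' aromatic-, hetero-, and saturated-ring counts); bits 264-317 are bonded
#' element-pair keys; the remaining bits are hashed radius-2 circular
#' substructure keys folded into the residual width. The block is
#' deterministic and canonical-SMILES invariant, but is not bit-compatible
#' with CACTVS/PyBioMed output.
#'
#' @param smiles A canonical SMILES string or a `mol_graph`.
#' @return Integer 0/1 vector of length 881.
#' @export
pubchem_like_keys <- function(smiles) {
  g <- if (inherits(smiles, "mol_graph")) smiles else parse_smiles(smiles)
  ri <- .get_ring_info(g)
  bits <- integer(881L)

  # section 1: element counts (H from implicit/explicit hydrogen tally)
  counts <- table(g$element)
  nH <- sum(g$hcount) + sum(g$element == "H")
  tab <- .pubchem_element_counts
  for (k in seq_len(nrow(tab))) {
    el <- tab$element[k]
    cnt <- if (el == "H") nH else if (el %in% names(counts)) counts[[el]] else 0L
    if (cnt >= tab$threshold[k]) bits[k] <- 1L
  }
  off <- nrow(tab)  # 115

  # section 2: ring keys from smallest-ring sizes through each ring bond
  ring_sizes <- ri$ring_size[!is.na(ri$ring_size)]
  # distinct rings approximated by unique (size) multiset scaled by bonds/size
  size_counts <- vapply(3:10, function(s) {
    b <- sum(ring_sizes == s)
    as.integer(ceiling(b / s))
  }, integer(1))
  pos <- off
  for (s in seq_along(3:10)) {
    for (t in 1:5) {
      pos <- pos + 1L
      if (size_counts[s] >= t) bits[pos] <- 1L
    }
  }                                              # 40 bits
  arom_bonds <- g$bonds$aromatic & ri$bond_ring
  n_arom_rings <- as.integer(ceiling(sum(arom_bonds) / 6))
  n_rings <- ri$n_rings
  hetero_ring_atoms <- sum(ri$atom_ring & g$element != "C")
  sat_bonds <- ri$bond_ring & !g$bonds$aromatic & g$bonds$order == 1
  grid <- c(vapply(1:8, function(t) n_rings >= t, logical(1)),
            vapply(1:6, function(t) n_arom_rings >= t, logical(1)),
            vapply(1:6, function(t) hetero_ring_atoms >= t, logical(1)),
            vapply(1:6, function(t) sum(sat_bonds) >= t * 3, logical(1)))
  bits[pos + seq_along(grid)] <- as.integer(grid)
  pos <- off + 148L                              # section 2 padded to 148

  # section 3: bonded element pairs
  if (nrow(g$bonds) > 0) {
    pe <- apply(cbind(g$element[g$bonds$i], g$element[g$bonds$j]), 1,
                function(p) paste(sort(p), collapse = "-"))
    pairs_norm <- vapply(strsplit(.pubchem_atom_pairs, "-", fixed = TRUE),
                         function(p) paste(sort(p), collapse = "-"), character(1))
    hit <- pairs_norm %in% pe
    # C-H / N-H pairs from implicit hydrogens
    hit[pairs_norm == paste(sort(c("C", "H")), collapse = "-")] <-
      any(g$element == "C" & g$hcount > 0)
    hit[pairs_norm == paste(sort(c("H", "N")), collapse = "-")] <-
      any(g$element == "N" & g$hcount > 0)
    bits[pos + which(hit)] <- 1L
  }
  pos <- pos + length(.pubchem_atom_pairs)       # 317

  # remainder: hashed circular substructure block
  rem <- 881L - pos
  on <- morgan_on_bits(g, radius = 2L, n_bits = rem)
  bits[pos + on] <- 1L
  bits
}

#' Combined 1905-bit fingerprint block
#'
#' Concatenates the 1024-bit diameter-2 circular fingerprint (ECFP2,
#' `radius = 1`) with the 881 PubChem-style substructure keys, giving the
#' 1905-long 0/1 feature block consumed by the fingerprint base model.
#'
#' @param smiles A canonical SMILES string or a `mol_graph`.
#' @return Integer 0/1 vector of length 1905 (1024 ECFP2 bits, then 881 keys).
#' @export
compute_combined_fingerprints <- function(smiles) {
  g <- if (inherits(smiles, "mol_graph")) smiles else parse_smiles(smiles)
  c(morgan_fingerprint(g, radius = 1L, n_bits = 1024L),
    pubchem_like_keys(g))
}

#' Fingerprint-index embedding vector
#'
#' FP2VEC-style representation: the sorted 1-based positions of the on bits
#' of a 1024-bit radius-2 Morgan fingerprint, right-padded with the
#' sentinel 0 to a fixed length (default 93). Molecules with more on bits
#' than `max_len` are truncated to the first `max_len` indices with a
#' warning.
#'
#' @param smiles A canonical SMILES string or a `mol_graph`.
#' @param n_bits Fingerprint length (default 1024).
#' @param radius Morgan radius (default 2).
#' @param max_len Output length (default 93).
#' @return Integer vector of length `max_len`; non-sentinel entries are
#'   strictly increasing values in `1..n_bits`, sentinel is 0.
#' @export
compute_fp_index_vector <- function(smiles, n_bits = 1024L, radius = 2L,
                                    max_len = 93L) {
  on <- morgan_on_bits(smiles, radius = radius, n_bits = n_bits)
  if (length(on) > max_len) {
    warning("fingerprint has ", length(on), " on bits; truncating to ",
            max_len, call. = FALSE)
    on <- on[seq_len(max_len)]
  }
  c(on, rep(0L, max_len - length(on)))
}
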