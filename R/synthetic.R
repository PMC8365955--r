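# Scaffold grammar: units that concatenate into valid SMILES. Each unit's
# first and last atoms keep at least one free valence, so arbitrary unit
# sequences chain correctly (rings attach through their first and last
# written atoms). Chlorine is deliberately absent from the grammar: the
# planted motif is the only source of Cl, so its fingerprint environment is
# unique to positives.
.synth_units <- c(
  "C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C",
  "CO", "CCO", "CN", "CCN", "CS",
  "C=C", "CC=C", "C(=O)", "C(=O)N", "C(=O)O", "C(F)(F)",
  "c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
  "C1CCCCC1", "C1CCNCC1", "C1CCOC1"
)
.synth_unit_weights <- c(
  4, 4, 3, 2, 2, 1,
  2, 2, 2, 2, 1,
  1, 1, 2, 1, 1, 1,
  4, 2, 1, 1,
  2, 1, 1
)

#' Synthetic dataset specification
#'
#' Conditions for the seeded synthetic SMILES generator: dataset size,
#' positive fraction, label-flip noise rate, the planted substructure
#' motif (default: a basic tertiary amine attached to a para-substituted
#' chloroaromatic ring — a caricature of the lipophilic-amine pharmacophore
#' associated with hERG liability) and scaffold-grammar size parameters.
#'
#' @param n Dataset size (>= 2).
#' @param positive_fraction Fraction of molecules carrying the motif
#'   (default 0.5).
#' @param noise_rate Label-flip probability after motif labeling
#'   (default 0).
#' @param motif Planted substructure as a SMILES unit; its first atom is
#'   the attachment point.
#' @param min_units,max_units Scaffold length range in grammar units.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 2000L, positive_fraction = 0.5,
                           noise_rate = 0,
                           motif = "CN(C)Cc1ccc(Cl)cc1",
                           min_units = 2L, max_units = 5L, seed = 1L) {
  stopifnot(n >= 2, positive_fraction >= 0, positive_fraction <= 1,
            noise_rate >= 0, noise_rate <= 1, min_units >= 1,
            max_units >= min_units)
  structure(list(n = as.integer(n), positive_fraction = positive_fraction,
                 noise_rate = noise_rate, motif = motif,
                 min_units = as.integer(min_units),
                 max_units = as.integer(max_units), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Designated motif fingerprint bits: the radius-<=2 environments of the
# aromatic chlorine, i.e. the 1024-bit radius-2 Morgan bits of
# chlorobenzene that plain benzene lacks. These environments are identical
# in every motif occurrence (the chlorine's 2-neighborhood never touches
# the attachment point).
.motif_bits <- function(n_bits = 1024L, radius = 2L) {
  setdiff(morgan_on_bits("Clc1ccccc1", radius, n_bits),
          morgan_on_bits("c1ccccc1", radius, n_bits))
}

.assemble_scaffold <- function(n_units) {
  idx <- sample.int(length(.synth_units), n_units, replace = TRUE,
                    prob = .synth_unit_weights)
  .synth_units[idx]
}

#' Generate a labeled synthetic SMILES dataset
#'
#' Assembles each molecule from a seeded random scaffold grammar (chains,
#' branches, rings, heteroatom substitutions), inserts the planted motif
#' into positives, labels by motif presence, then flips labels with the
#' configured noise rate. All molecules have at most 50 heavy atoms and at
#' most 97 SMILES tokens, parse in every featurizer, and are canonicalized
#' through [standardize_molecule()]. The planted rule is verified at
#' generation time: a designated fingerprint bit (the chloroaromatic
#' environment of the motif) is on for every motif-bearing molecule, and
#' motif-free molecules whose hashed fingerprints collide with it are
#' regenerated, so at zero noise a single-bit rule on that bit separates
#' the classes perfectly.
#'
#' @param spec A [synthetic_spec()].
#' @param max_atoms,max_tokens Size caps (defaults 50 heavy atoms, 97
#'   tokens) applied before canonicalization.
#' @return A [labeled_dataset()] with attributes `motif_bit` (the
#'   designated 1-based fingerprint bit), `spec`, and `true_label`
#'   (pre-noise motif labels).
#' @export
generate_synthetic_dataset <- function(spec = synthetic_spec(),
                                       max_atoms = 50L, max_tokens = 97L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  mbits <- .motif_bits()
  designated <- min(mbits)
  n <- spec$n
  is_pos <- stats::rbinom(n, 1L, spec$positive_fraction)
  smiles <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:60) {
      k <- sample(spec$min_units:spec$max_units, 1L)
      units <- .assemble_scaffold(k)
      if (is_pos[i] == 1L) {
        slot <- sample.int(k + 1L, 1L)
        units <- append(units, spec$motif, after = slot - 1L)
      }
      smi <- paste(units, collapse = "")
      g <- tryCatch(parse_smiles(smi), error = function(e) NULL)
      if (is.null(g) || g$n > max_atoms) next
      if (length(smiles_tokenize(smi)) > max_tokens) next
      on_bits <- morgan_on_bits(g, radius = 2L, n_bits = 1024L)
      if (is_pos[i] == 1L && !(designated %in% on_bits)) next
      if (is_pos[i] == 0L && designated %in% on_bits) next
      smiles[i] <- smi
      ok <- TRUE
      break
    }
    if (!ok)
      stop("synthetic generation failed after bounded retries at molecule ",
           i, " (infeasible spec?)", call. = FALSE)
  }
  can <- standardize_molecule(smiles, neutralize = FALSE)
  if (anyNA(can))
    stop("internal error: generated SMILES failed canonicalization",
         call. = FALSE)
  label <- is_pos
  flip <- stats::rbinom(n, 1L, spec$noise_rate) == 1L
  label[flip] <- 1L - label[flip]
  ds <- labeled_dataset(can, label, source = "synthetic",
                        name = sprintf("synthetic_n%d_seed%d", n, spec$seed))
  attr(ds, "motif_bit") <- designated
  attr(ds, "motif_bits") <- mbits
  attr(ds, "true_label") <- is_pos
  attr(ds, "spec") <- spec
  ds
}
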