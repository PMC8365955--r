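#' SMILES tokenizer
#'
#' Splits a SMILES string into chemically meaningful tokens: bracket atoms
#' (`[...]`) are single tokens, the two-character organic-subset halogens
#' `Cl` and `Br` are single tokens, `%nn` two-digit ring closures are single
#' tokens, and every remaining character (organic-subset atoms, aromatic
#' lowercase atoms, bond symbols, branches, ring digits, dots) is its own
#' token.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens; `character(0)` for an empty string.
#' @examples
#' smiles_tokenize("Clc1ccccc1")
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || nchar(smiles) == 0L) return(character(0))
  m <- gregexpr("\\[[^][]*\\]|Br|Cl|%[0-9]{2}|.", smiles, perl = TRUE)[[1]]
  regmatches(smiles, list(m))[[1]]
}

# Default valences used for implicit-hydrogen assignment (OpenSMILES).
# Multi-valence elements list all allowed values in increasing order.
.default_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = c(1L, 3L, 5L, 7L), Br = c(1L, 3L, 5L, 7L),
  I = c(1L, 3L, 5L, 7L)
)

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

.parse_bracket_atom <- function(token) {
  body <- substr(token, 2L, nchar(token) - 1L)
  # isotope prefix
  body <- sub("^[0-9]+", "", body)
  m <- regexpr("^([A-Z][a-z]?|[a-z]{1,2}|\\*)", body, perl = TRUE)
  if (m == -1L) stop("unparseable bracket atom: ", token, call. = FALSE)
  sym <- regmatches(body, m)
  rest <- substr(body, nchar(sym) + 1L, nchar(body))
  aromatic <- sym == tolower(sym) && sym != "*"
  element <- if (aromatic) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
  rest <- gsub("@{1,2}", "", rest)                       # chirality ignored
  hcount <- 0L
  hm <- regexpr("H[0-9]*", rest)
  if (hm != -1L) {
    hs <- regmatches(rest, hm)
    hcount <- if (nchar(hs) == 1L) 1L else as.integer(substring(hs, 2))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  cm <- regexpr("[+-][0-9]*|\\+{2,}|-{2,}", rest)
  if (cm != -1L) {
    cs <- regmatches(rest, cm)
    sign <- if (substr(cs, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cs)
    n <- if (nchar(digits) > 0L) as.integer(digits) else
      sum(strsplit(cs, "")[[1]] %in% c("+", "-"))
    charge <- sign * n
  }
  list(element = element, aromatic = aromatic, hcount = hcount,
       charge = charge, explicit_h = TRUE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds an explicit molecular graph (heavy atoms only) from a SMILES
#' string: elements, aromatic flags, formal charges, implicit hydrogen
#' counts, and a bond table with orders. Stereo annotations (`@`, `/`, `\`)
#' and isotopes are accepted and ignored. Implicit hydrogens on
#' organic-subset atoms follow the standard lowest-fitting-valence rule,
#' with aromatic atoms contributing one additional unit of used valence for
#' the delocalized system.
#'
#' @param smiles A single SMILES string (typically canonical).
#' @return An object of class `mol_graph`: a list with `n` (atom count),
#'   `element`, `aromatic`, `charge`, `hcount`, `degree` (per-atom vectors),
#'   and `bonds`, a data.frame with columns `i`, `j`, `order`, `aromatic`.
#' @examples
#' g <- parse_smiles("c1ccccc1O")
#' g$n
#' @export
parse_smiles <- function(smiles) {
  tokens <- smiles_tokenize(smiles)
  if (length(tokens) == 0L) stop("empty SMILES string", call. = FALSE)
  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); hfixed <- integer(0); hexplicit <- logical(0)
  bi <- integer(0); bj <- integer(0); border <- numeric(0); barom <- logical(0)
  prev <- NA_integer_
  stack <- integer(0)
  pending_bond <- NA_character_
  ring <- list()   # closure label -> list(atom, bond)

  add_atom <- function(el, arom, chg, hc, hex) {
    element <<- c(element, el); aromatic <<- c(aromatic, arom)
    charge <<- c(charge, chg); hfixed <<- c(hfixed, hc)
    hexplicit <<- c(hexplicit, hex)
    length(element)
  }
  add_bond <- function(a, b, spec) {
    arom <- FALSE; order <- 1
    if (!is.na(spec)) {
      order <- switch(spec, "-" = 1, "=" = 2, "#" = 3, "$" = 4,
                      ":" = 1, "/" = 1, "\\" = 1)
      arom <- identical(spec, ":")
    } else if (aromatic[a] && aromatic[b]) {
      arom <- TRUE
    }
    bi <<- c(bi, a); bj <<- c(bj, b)
    border <<- c(border, order); barom <<- c(barom, arom)
  }

  for (tok in tokens) {
    if (tok %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pending_bond <- tok
    } else if (tok == "(") {
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles, call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
    } else if (grepl("^%[0-9]{2}$", tok) || grepl("^[0-9]$", tok)) {
      label <- sub("^%", "", tok)
      if (is.null(ring[[label]])) {
        ring[[label]] <- list(atom = prev, bond = pending_bond)
      } else {
        open <- ring[[label]]
        spec <- if (!is.na(pending_bond)) pending_bond else open$bond
        add_bond(open$atom, prev, spec)
        ring[[label]] <- NULL
      }
      pending_bond <- NA_character_
    } else if (grepl("^\\[", tok)) {
      at <- .parse_bracket_atom(tok)
      id <- add_atom(at$element, at$aromatic, at$charge, at$hcount, TRUE)
      if (!is.na(prev)) add_bond(prev, id, pending_bond)
      pending_bond <- NA_character_
      prev <- id
    } else if (tok %in% .organic_subset || tok %in% .aromatic_organic) {
      arom <- tok %in% .aromatic_organic
      el <- if (arom) toupper(tok) else tok
      id <- add_atom(el, arom, 0L, 0L, FALSE)
      if (!is.na(prev)) add_bond(prev, id, pending_bond)
      pending_bond <- NA_character_
      prev <- id
    } else {
      stop("unrecognized SMILES token '", tok, "' in: ", smiles, call. = FALSE)
    }
  }
  open_labels <- names(ring)[!vapply(ring, is.null, logical(1))]
  if (length(open_labels) > 0L)
    stop("unmatched ring bond(s) in SMILES: ", smiles, call. = FALSE)

  n <- length(element)
  bonds <- data.frame(i = bi, j = bj, order = border, aromatic = barom)
  degree <- tabulate(c(bi, bj), nbins = n)
  # implicit hydrogens for organic-subset atoms
  bondsum <- numeric(n)
  if (nrow(bonds) > 0) {
    ord <- ifelse(bonds$aromatic, 1, bonds$order)
    bondsum <- tabulate(c(bonds$i, bonds$j), nbins = n) * 0
    for (k in seq_len(nrow(bonds))) {
      bondsum[bonds$i[k]] <- bondsum[bonds$i[k]] + ord[k]
      bondsum[bonds$j[k]] <- bondsum[bonds$j[k]] + ord[k]
    }
  }
  hcount <- hfixed
  for (a in seq_len(n)) {
    if (hexplicit[a]) next
    vals <- .default_valences[[element[a]]]
    if (is.null(vals)) { hcount[a] <- 0L; next }
    used <- bondsum[a] + as.integer(aromatic[a])
    fit <- vals[vals >= used]
    hcount[a] <- if (length(fit) == 0L) 0L else as.integer(fit[1] - used)
  }
  structure(list(n = n, element = element, aromatic = aromatic,
                 charge = charge, hcount = hcount, degree = degree,
                 bonds = bonds, smiles = smiles),
            class = "mol_graph")
}

#' @method print mol_graph
#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph:", x$smiles, "\n  atoms:", x$n,
      " bonds:", nrow(x$bonds),
      " aromatic atoms:", sum(x$aromatic), "\n")
  invisible(x)
}

# igraph view of a mol_graph (heavy-atom skeleton)
.mol_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds) > 0) g$bonds[, c("i", "j")] else
      data.frame(i = integer(0), j = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n))
  )
}

# Ring info with per-object caching: featurization pipelines parse once
# and reuse the ring perception across fingerprint/descriptor/graph views.
.get_ring_info <- function(g) {
  ri <- attr(g, "ring_info")
  if (is.null(ri)) ri <- .ring_info(g)
  ri
}

#' Attach cached ring information to a parsed molecule
#'
#' @param g A `mol_graph`.
#' @return The same `mol_graph` with ring perception precomputed.
#' @keywords internal
#' @export
with_ring_info <- function(g) {
  if (is.null(attr(g, "ring_info"))) attr(g, "ring_info") <- .ring_info(g)
  g
}

# Ring membership per bond and per atom, plus smallest-ring sizes.
# A bond is a ring bond iff its endpoints stay connected after removing it;
# the smallest ring through it is the shortest alternative path + 1.
.ring_info <- function(g) {
  nb <- nrow(g$bonds)
  bond_ring <- logical(nb)
  ring_size <- rep(NA_integer_, nb)
  if (nb > 0) {
    ig <- .mol_igraph(g)
    for (k in seq_len(nb)) {
      e <- igraph::get_edge_ids(ig, c(g$bonds$i[k], g$bonds$j[k]))
      ig2 <- igraph::delete_edges(ig, e)
      d <- igraph::distances(ig2, v = g$bonds$i[k], to = g$bonds$j[k])[1, 1]
      if (is.finite(d)) { bond_ring[k] <- TRUE; ring_size[k] <- as.integer(d + 1) }
    }
  }
  atom_ring <- logical(g$n)
  if (any(bond_ring)) {
    rb <- g$bonds[bond_ring, ]
    atom_ring[unique(c(rb$i, rb$j))] <- TRUE
  }
  n_rings <- nb - (g$n - igraph::count_components(.mol_igraph(g)))  # cyclomatic
  list(bond_ring = bond_ring, ring_size = ring_size,
       atom_ring = atom_ring, n_rings = as.integer(n_rings))
}
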