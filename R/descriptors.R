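# Per-element atomic properties used by autocorrelation and Burden
# descriptors: mass, Pauling electronegativity, static polarizability
# (A^3), van der Waals radius (A). Unlisted elements fall back to carbon.
.atom_props <- local({
  tab <- rbind(
    C  = c(12.011, 2.55, 1.76, 1.70),
    N  = c(14.007, 3.04, 1.10, 1.55),
    O  = c(15.999, 3.44, 0.80, 1.52),
    S  = c(32.06,  2.58, 2.90, 1.80),
    F  = c(18.998, 3.98, 0.56, 1.47),
    Cl = c(35.45,  3.16, 2.18, 1.75),
    Br = c(79.904, 2.96, 3.05, 1.85),
    I  = c(126.90, 2.66, 5.35, 1.98),
    P  = c(30.974, 2.19, 3.63, 1.80),
    B  = c(10.81,  2.04, 3.03, 1.92),
    Si = c(28.085, 1.90, 5.38, 2.10),
    Se = c(78.971, 2.55, 3.77, 1.90),
    H  = c(1.008,  2.20, 0.67, 1.20)
  )
  colnames(tab) <- c("mass", "en", "polar", "vdw")
  tab
})

.atom_prop <- function(elements, prop) {
  v <- .atom_props[match(elements, rownames(.atom_props)), prop]
  v[is.na(v)] <- .atom_props["C", prop]
  v
}

.autocorr_types <- c("ATS", "AATS", "ATSC", "Moran", "Geary")
.autocorr_props <- c("mass", "en", "polar", "vdw", "degree", "hcount")
.autocorr_maxlag <- 7L

#' Names of the raw descriptor panel
#'
#' The descriptor featurizer emits a fixed-width vector (default width 995,
#' the width the descriptor base model consumes). The implemented panel —
#' Open Babel physicochemical properties, constitutional counts,
#' topological indices, 2D autocorrelations over six atomic properties and
#' Burden-matrix eigenvalue descriptors — occupies the leading slots; the
#' remaining slots are named `pad_*` and are identically zero (they
#' normalize to 0 and carry no information). 3D conformer-dependent
#' descriptors are not computed.
#'
#' @param width Total vector width (default 995).
#' @return Character vector of length `width`.
#' @export
descriptor_names <- function(width = 995L) {
  ob <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  const <- c("nAtom", "nHeavyAtom", "nBonds", "nBondsS", "nBondsD",
             "nBondsT", "nBondsA", "nAromAtom", "nRing", "nRotB",
             "nHetero", "nHalogen", "nH", "totalCharge", "totalAbsCharge",
             "nPosAtom", "nNegAtom",
             paste0("nDeg", 0:5),
             paste0("count_", .element_symbols))
  topo <- c("Wiener", "MeanDist", "TopoDiameter", "TopoRadius", "Zagreb1",
            "Zagreb2", "Randic", "Chi0", "BalabanJ", "Kappa1", "Kappa2",
            "Kappa3", "EccMean", "nTriangle")
  ac <- unlist(lapply(.autocorr_props, function(p)
    unlist(lapply(.autocorr_types, function(t)
      paste0(t, "_", p, "_d", 0:.autocorr_maxlag)))))
  burden <- as.vector(outer(c("hi1", "hi2", "lo1", "lo2"),
                            c("mass", "en", "polar"),
                            function(a, b) paste0("BCUT_", b, "_", a)))
  nm <- c(ob, const, topo, ac, burden)
  if (length(nm) > width)
    stop("descriptor width ", width, " smaller than implemented panel (",
         length(nm), ")", call. = FALSE)
  c(nm, sprintf("pad_%03d", seq_len(width - length(nm))))
}

# Graph-derived block of the descriptor panel (everything except propOB).
.graph_descriptors <- function(g) {
  ri <- .get_ring_info(g)
  ig <- .mol_igraph(g)
  D <- igraph::distances(ig)
  finiteD <- D[is.finite(D) & D > 0]
  deg <- g$degree
  nb <- nrow(g$bonds)

  halogens <- c("F", "Cl", "Br", "I")
  rot <- 0L
  if (nb > 0) {
    for (k in seq_len(nb)) {
      if (!ri$bond_ring[k] && !g$bonds$aromatic[k] && g$bonds$order[k] == 1 &&
          deg[g$bonds$i[k]] > 1L && deg[g$bonds$j[k]] > 1L)
        rot <- rot + 1L
    }
  }
  const <- c(
    nAtom = g$n + sum(g$hcount), nHeavyAtom = g$n, nBonds = nb,
    nBondsS = if (nb) sum(g$bonds$order == 1 & !g$bonds$aromatic) else 0,
    nBondsD = if (nb) sum(g$bonds$order == 2 & !g$bonds$aromatic) else 0,
    nBondsT = if (nb) sum(g$bonds$order == 3) else 0,
    nBondsA = if (nb) sum(g$bonds$aromatic) else 0,
    nAromAtom = sum(g$aromatic), nRing = ri$n_rings, nRotB = rot,
    nHetero = sum(!g$element %in% c("C", "H")),
    nHalogen = sum(g$element %in% halogens),
    nH = sum(g$hcount) + sum(g$element == "H"),
    totalCharge = sum(g$charge), totalAbsCharge = sum(abs(g$charge)),
    nPosAtom = sum(g$charge > 0), nNegAtom = sum(g$charge < 0)
  )
  degcnt <- vapply(0:5, function(d) sum(deg == d), numeric(1))
  names(degcnt) <- paste0("nDeg", 0:5)
  elcnt <- vapply(.element_symbols, function(e) sum(g$element == e), numeric(1))
  names(elcnt) <- paste0("count_", .element_symbols)

  # topological indices
  wiener <- sum(finiteD) / 2
  zag1 <- sum(deg^2)
  zag2 <- if (nb) sum(deg[g$bonds$i] * deg[g$bonds$j]) else 0
  randic <- if (nb) sum(1 / sqrt(pmax(1, deg[g$bonds$i] * deg[g$bonds$j]))) else 0
  chi0 <- sum(1 / sqrt(pmax(1, deg)))
  ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
  A <- g$n
  tri <- 0
  if (nb > 0 && A > 2) {
    adj <- matrix(0, A, A)
    adj[cbind(g$bonds$i, g$bonds$j)] <- 1
    adj[cbind(g$bonds$j, g$bonds$i)] <- 1
    tri <- sum(diag(adj %*% adj %*% adj)) / 6
  }
  p2 <- sum(deg * (deg - 1) / 2)
  p3 <- if (nb) sum((deg[g$bonds$i] - 1) * (deg[g$bonds$j] - 1)) - 3 * tri else 0
  kappa1 <- if (nb > 0) A * (A - 1)^2 / nb^2 else 0
  kappa2 <- if (p2 > 0) (A - 1) * (A - 2)^2 / p2^2 else 0
  kappa3 <- if (p3 > 0) {
    if (A %% 2 == 0) (A - 3) * (A - 2)^2 / p3^2 else (A - 1) * (A - 3)^2 / p3^2
  } else 0
  balaban <- 0
  if (nb > 0) {
    s <- rowSums(ifelse(is.finite(D), D, 0))
    cyc <- ri$n_rings
    ss <- s[g$bonds$i] * s[g$bonds$j]
    ss[ss <= 0] <- 1
    balaban <- nb / (cyc + 1) * sum(1 / sqrt(ss))
  }
  topo <- c(Wiener = wiener,
            MeanDist = if (length(finiteD)) mean(finiteD) else 0,
            TopoDiameter = if (length(finiteD)) max(finiteD) else 0,
            TopoRadius = if (g$n) min(ecc) else 0,
            Zagreb1 = zag1, Zagreb2 = zag2, Randic = randic, Chi0 = chi0,
            BalabanJ = balaban, Kappa1 = kappa1, Kappa2 = kappa2,
            Kappa3 = kappa3, EccMean = if (g$n) mean(ecc) else 0,
            nTriangle = tri)

  # 2D autocorrelations
  ac <- numeric(0)
  for (p in .autocorr_props) {
    w <- switch(p, degree = as.numeric(deg), hcount = as.numeric(g$hcount),
                .atom_prop(g$element, p))
    wbar <- mean(w)
    varw <- sum((w - wbar)^2)
    vals <- numeric(0)
    for (type in .autocorr_types) {
      for (d in 0:.autocorr_maxlag) {
        if (d == 0) {
          pairsum <- switch(type,
            ATS = sum(w^2), AATS = mean(w^2), ATSC = varw / max(1, g$n),
            Moran = if (varw > 0) 1 else 0, Geary = 0)
          vals <- c(vals, pairsum)
          next
        }
        idx <- which(D == d, arr.ind = TRUE)
        idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
        np <- nrow(idx)
        v <- if (np == 0) 0 else switch(type,
          ATS = sum(w[idx[, 1]] * w[idx[, 2]]),
          AATS = mean(w[idx[, 1]] * w[idx[, 2]]),
          ATSC = sum((w[idx[, 1]] - wbar) * (w[idx[, 2]] - wbar)) / np,
          Moran = if (varw > 0)
            (sum((w[idx[, 1]] - wbar) * (w[idx[, 2]] - wbar)) / np) /
              (varw / g$n) else 0,
          Geary = if (varw > 0 && g$n > 1)
            (sum((w[idx[, 1]] - w[idx[, 2]])^2) / (2 * np)) /
              (varw / (g$n - 1)) else 0)
        vals <- c(vals, v)
      }
    }
    ac <- c(ac, vals)
  }
  names(ac) <- unlist(lapply(.autocorr_props, function(p)
    unlist(lapply(.autocorr_types, function(t)
      paste0(t, "_", p, "_d", 0:.autocorr_maxlag)))))

  # Burden-matrix eigenvalue descriptors
  burden <- numeric(0)
  for (p in c("mass", "en", "polar")) {
    w <- .atom_prop(g$element, p)
    if (g$n == 1L) {
      ev <- c(w, w)
    } else {
      B <- matrix(0.001, g$n, g$n)
      diag(B) <- w
      if (nb > 0) {
        off <- ifelse(g$bonds$aromatic, 0.15, g$bonds$order * 0.1)
        B[cbind(g$bonds$i, g$bonds$j)] <- off
        B[cbind(g$bonds$j, g$bonds$i)] <- off
      }
      ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
    }
    hi <- ev[seq_len(min(2, length(ev)))]
    lo <- rev(ev)[seq_len(min(2, length(ev)))]
    burden <- c(burden, c(hi, rep(hi[length(hi)], 2 - length(hi)))[1:2],
                c(lo, rep(lo[length(lo)], 2 - length(lo)))[1:2])
  }
  names(burden) <- as.vector(outer(c("hi1", "hi2", "lo1", "lo2"),
                                   c("mass", "en", "polar"),
                                   function(a, b) paste0("BCUT_", b, "_", a)))
  c(const, degcnt, elcnt, topo, ac, burden)
}

#' Raw descriptor matrix for a set of molecules
#'
#' Computes the fixed-width raw (un-normalized) descriptor panel for each
#' molecule: Open Babel physicochemical properties (hydrogen-bond
#' acceptors/donors, logP, molar refractivity, molecular weight, fluorine
#' count, topological polar surface area) followed by the graph-derived
#' blocks of [descriptor_names()]. Non-finite raw values are replaced by 0.
#'
#' @param smiles Character vector of canonical SMILES.
#' @param width Vector width (default 995).
#' @param graphs Optional list of pre-parsed `mol_graph` objects (one per
#'   SMILES) to reuse ring perception.
#' @return Numeric matrix `length(smiles) x width` with column names from
#'   [descriptor_names()].
#' @export
compute_raw_descriptors <- function(smiles, width = 995L, graphs = NULL) {
  stopifnot(length(smiles) > 0L)
  nms <- descriptor_names(width)
  out <- matrix(0, nrow = length(smiles), ncol = width,
                dimnames = list(NULL, nms))
  obcols <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  ob <- tryCatch({
    sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, sprintf("m%06d", seq_along(smiles))))
    p <- ChemmineR::propOB(sdf)
    as.matrix(p[, obcols, drop = FALSE])
  }, error = function(e) {
    warning("bulk property computation failed (", conditionMessage(e),
            "); physicochemical block set to 0", call. = FALSE)
    matrix(0, nrow = length(smiles), ncol = length(obcols))
  })
  if (nrow(ob) == length(smiles)) out[, obcols] <- ob
  for (i in seq_along(smiles)) {
    g <- if (!is.null(graphs)) graphs[[i]] else parse_smiles(smiles[i])
    gd <- .graph_descriptors(g)
    out[i, names(gd)] <- gd
  }
  out[!is.finite(out)] <- 0
  out
}

#' Fit a per-descriptor min-max normalizer
#'
#' Learns the per-column minimum and maximum of a raw descriptor matrix
#' (the base-training set). Constant columns are flagged and always
#' transform to 0; held-out values outside the training range are clipped
#' into `[0, 1]`.
#'
#' @param train_matrix Numeric matrix of raw descriptors (>= 2 rows).
#' @return An object of class `descriptor_normalizer`.
#' @export
fit_descriptor_normalizer <- function(train_matrix) {
  if (is.null(dim(train_matrix)) || nrow(train_matrix) < 2L)
    stop("need at least 2 rows to fit a normalizer", call. = FALSE)
  mn <- apply(train_matrix, 2, min)
  mx <- apply(train_matrix, 2, max)
  structure(list(min = mn, max = mx, constant = mx <= mn,
                 names = colnames(train_matrix)),
            class = "descriptor_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' @param normalizer A [fit_descriptor_normalizer()] object.
#' @param x Numeric matrix (or vector) of raw descriptors with the same
#'   column layout the normalizer was fitted on.
#' @return Matrix/vector of the same shape with all entries in `[0, 1]`.
#' @export
apply_descriptor_normalizer <- function(normalizer, x) {
  stopifnot(inherits(normalizer, "descriptor_normalizer"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  rng <- normalizer$max - normalizer$min
  rng[normalizer$constant] <- 1
  out <- sweep(sweep(x, 2, normalizer$min), 2, rng, "/")
  out[, normalizer$constant] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (vec) out[1, ] else out
}

#' Serialize / restore a descriptor normalizer as JSON
#'
#' @param normalizer A [fit_descriptor_normalizer()] object.
#' @param path JSON file path.
#' @export
write_descriptor_normalizer <- function(normalizer, path) {
  jsonlite::write_json(
    list(names = normalizer$names, min = unname(normalizer$min),
         max = unname(normalizer$max)),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_descriptor_normalizer
#' @export
read_descriptor_normalizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mn <- stats::setNames(as.numeric(obj$min), obj$names)
  mx <- stats::setNames(as.numeric(obj$max), obj$names)
  structure(list(min = mn, max = mx, constant = mx <= mn, names = obj$names),
            class = "descriptor_normalizer")
}

#' Normalized descriptor vector for one molecule
#'
#' Convenience wrapper: raw panel via [compute_raw_descriptors()], then
#' [apply_descriptor_normalizer()]. Deterministic for a fixed canonical
#' SMILES and fitted normalizer.
#'
#' @param smiles A canonical SMILES string.
#' @param normalizer A fitted [fit_descriptor_normalizer()].
#' @return Named numeric vector in `[0, 1]` of the normalizer's width.
#' @export
compute_descriptor_vector <- function(smiles, normalizer) {
  raw <- compute_raw_descriptors(smiles, width = length(normalizer$min))
  apply_descriptor_normalizer(normalizer, raw[1, ])
}
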