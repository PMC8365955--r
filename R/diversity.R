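#' Tanimoto similarity between two bit fingerprints
#'
#' `|a AND b| / |a OR b|`. Two all-zero fingerprints are defined to have
#' similarity 1 (identical objects); an all-zero against a non-zero
#' fingerprint gives 0.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprints must have equal length", call. = FALSE)
  ca <- sum(a != 0); cb <- sum(b != 0); cab <- sum(a != 0 & b != 0)
  denom <- ca + cb - cab
  if (denom == 0) return(1)
  cab / denom
}

# Stack a list of equal-length fingerprints into a 0/1 matrix (rows = mols)
.fp_matrix <- function(fps) {
  if (is.matrix(fps)) return((fps != 0) * 1)
  lens <- vapply(fps, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("fingerprints must share one length", call. = FALSE)
  (do.call(rbind, fps) != 0) * 1
}

#' Mean pairwise Tanimoto similarity of a dataset
#'
#' Exact mean over all unordered distinct pairs (self-pairs excluded),
#' computed with blocked matrix arithmetic — no sampling. Lower values
#' indicate a more diverse set.
#'
#' @param fps List of equal-length 0/1 fingerprints, or a 0/1 matrix with
#'   one row per molecule.
#' @return Mean Tanimoto similarity; `NA` (with warning) for fewer than 2
#'   fingerprints.
#' @export
dataset_tanimoto_mean <- function(fps) {
  M <- .fp_matrix(fps)
  n <- nrow(M)
  if (n < 2L) {
    warning("need >= 2 fingerprints for a pairwise mean", call. = FALSE)
    return(NA_real_)
  }
  popcnt <- rowSums(M)
  total <- 0
  block <- 512L
  starts <- seq(1L, n, by = block)
  for (si in seq_along(starts)) {
    ri <- starts[si]:min(starts[si] + block - 1L, n)
    inter_all <- M[ri, , drop = FALSE] %*% t(M)
    for (sj in si:length(starts)) {
      rj <- starts[sj]:min(starts[sj] + block - 1L, n)
      inter <- inter_all[, rj, drop = FALSE]
      uni <- outer(popcnt[ri], popcnt[rj], "+") - inter
      sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
      if (si == sj) {
        total <- total + sum(sim[upper.tri(sim)])
      } else {
        total <- total + sum(sim)
      }
    }
  }
  total / (n * (n - 1) / 2)
}

#' Per-query maximum Tanimoto similarity against a reference set
#'
#' For each query fingerprint, the maximum Tanimoto similarity over all
#' reference fingerprints — the quantity plotted in cross-set similarity
#' analyses (e.g. each external test molecule against the whole training
#' set).
#'
#' @param query_set,reference_set Lists of equal-length 0/1 fingerprints or
#'   0/1 matrices (rows = molecules).
#' @return Numeric vector of per-query maxima.
#' @export
cross_set_max_similarity <- function(query_set, reference_set) {
  Q <- .fp_matrix(query_set); R <- .fp_matrix(reference_set)
  if (nrow(Q) == 0L) stop("empty query set", call. = FALSE)
  if (nrow(R) == 0L) stop("empty reference set", call. = FALSE)
  if (ncol(Q) != ncol(R))
    stop("query and reference fingerprints must share one length", call. = FALSE)
  pq <- rowSums(Q); pr <- rowSums(R)
  out <- numeric(nrow(Q))
  block <- 1024L
  for (s in seq(1L, nrow(Q), by = block)) {
    idx <- s:min(s + block - 1L, nrow(Q))
    inter <- Q[idx, , drop = FALSE] %*% t(R)
    uni <- outer(pq[idx], pr, "+") - inter
    sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
    out[idx] <- apply(sim, 1, max)
  }
  out
}

#' Diversity fingerprints for a set of SMILES
#'
#' The 2048-bit radius-2 Morgan fingerprints used by the chemical-diversity
#' analysis (distinct from the 1024-bit fingerprints embedded by the base
#' models).
#'
#' @param smiles Character vector of canonical SMILES.
#' @param n_bits Fingerprint length (default 2048).
#' @param radius Morgan radius (default 2).
#' @return 0/1 matrix `length(smiles) x n_bits`.
#' @export
diversity_fingerprints <- function(smiles, n_bits = 2048L, radius = 2L) {
  t(vapply(smiles, function(s) morgan_fingerprint(s, radius, n_bits),
           integer(n_bits), USE.NAMES = FALSE))
}

#' Diversity report table
#'
#' Per-dataset summary: class counts and within-set mean Tanimoto
#' similarity (2048-bit radius-2 fingerprints).
#'
#' @param datasets Named list of [labeled_dataset()] objects.
#' @return data.frame with columns `dataset`, `n_blockers`,
#'   `n_nonblockers`, `total`, `tanimoto_mean`.
#' @export
diversity_report <- function(datasets) {
  rows <- lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    fp <- diversity_fingerprints(ds$records$smiles)
    data.frame(dataset = nm,
               n_blockers = sum(ds$records$label == 1L),
               n_nonblockers = sum(ds$records$label == 0L),
               total = nrow(ds$records),
               tanimoto_mean = dataset_tanimoto_mean(fp))
  })
  do.call(rbind, rows)
}

#' Two-dimensional t-SNE projection of fingerprints
#'
#' Exact (non-approximated) t-SNE with the standard perplexity calibration
#' and early exaggeration, suitable for the desk-scale set sizes of the
#' diversity analysis. Seeded and deterministic.
#'
#' @param fps List of 0/1 fingerprints or a 0/1 matrix (rows = molecules,
#'   n >= 5).
#' @param seed Integer seed for the initial embedding.
#' @param perplexity Target perplexity (default 30, reduced automatically
#'   for small n).
#' @param n_iter Gradient-descent iterations (default 500).
#' @return Numeric matrix `n x 2` of embedding coordinates.
#' @export
tsne_projection <- function(fps, seed = 42L, perplexity = 30, n_iter = 500L) {
  X <- .fp_matrix(fps)
  n <- nrow(X)
  if (n < 5L) stop("t-SNE needs at least 5 points", call. = FALSE)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  # squared Euclidean distances on the bit vectors
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * X %*% t(X)
  D2[D2 < 0] <- 0
  diag(D2) <- Inf
  # per-point precision calibration to the target perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    di <- D2[i, ]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      p[i] <- 0
      sump <- sum(p)
      if (sump <= 0) { H <- 0; p[] <- 0 } else {
        H <- log(sump) + beta * sum(di[p > 0] * p[p > 0]) / sump
        p <- p / sump
      }
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, ] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  # gradient descent with early exaggeration and adaptive gains
  ex_factor <- 12; ex_end <- min(250L, max(50L, n_iter %/% 2))
  lr <- max(50, n / ex_factor)
  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    ex <- if (it <= ex_end) ex_factor else 1
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + outer(sqy, sqy, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    W <- (ex * P - Q) * num
    grad <- 4 * (Y * rowSums(W) - W %*% Y)
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - lr * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == ex_end) momentum <- 0.8
  }
  Y
}
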