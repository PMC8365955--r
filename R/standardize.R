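#' Standardize a SMILES string to canonical form
#'
#' Standardization pipeline: parse, keep the largest fragment (salt/solvent
#' stripping), neutralize formal charges where chemically possible, and emit
#' the canonical SMILES. Parsing, neutralization and canonicalization are
#' delegated to Open Babel via \pkg{ChemmineOB}; fragment selection keeps the
#' fragment with the most heavy atoms (ties broken by the longer SMILES,
#' then lexicographically).
#'
#' The pipeline is idempotent: `standardize_molecule(standardize_molecule(s))`
#' equals `standardize_molecule(s)`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param neutralize Neutralize formal charges (default `TRUE`).
#' @return Character vector of canonical SMILES. Unparseable inputs yield
#'   `NA_character_` (use [read_dataset_csv()] for skip-and-count semantics);
#'   a single unparseable input raises an error naming the offending string.
#' @examples
#' \donttest{
#' standardize_molecule("OCC")          # "CCO"
#' standardize_molecule("CC(=O)[O-].[Na+]")  # acetic acid, salt stripped
#' }
#' @export
standardize_molecule <- function(smiles, neutralize = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) {
    can1 <- .ob_canonical(smiles[ok], neutralize = neutralize)
    # strip salts: keep largest fragment, then re-canonicalize once more so
    # fragment choice cannot change the final form
    frag <- vapply(can1, .largest_fragment, character(1), USE.NAMES = FALSE)
    has_dot <- !is.na(frag) & frag != can1
    if (any(has_dot, na.rm = TRUE)) {
      idx <- which(has_dot)
      frag[idx] <- .ob_canonical(frag[idx], neutralize = neutralize)
    }
    out[ok] <- frag
  }
  if (length(smiles) == 1L && is.na(out)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  out
}

# Batched Open Babel canonicalization; returns NA for unparseable entries.
.ob_canonical <- function(smiles, neutralize = TRUE) {
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else
    data.frame(names = character(0), args = character(0))
  res <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, collapse = "\n"),
                              options = opts)
  )
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  vals <- sub("\t.*$", "", lines)
  # Open Babel drops invalid entries from its output; recover alignment by
  # converting one-by-one when counts disagree.
  if (length(vals) == length(smiles) && all(nzchar(vals))) return(vals)
  vapply(smiles, function(s) {
    r <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", s, options = opts))
    v <- sub("[\t\n].*$", "", r)
    if (!nzchar(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
}

.largest_fragment <- function(smiles) {
  if (is.na(smiles)) return(NA_character_)
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(smiles)
  heavy <- vapply(parts, function(p) {
    g <- tryCatch(parse_smiles(p), error = function(e) NULL)
    if (is.null(g)) -1L else g$n
  }, integer(1))
  ord <- order(-heavy, -nchar(parts), parts)
  parts[ord[1]]
}
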