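# SMILES parsing and native fingerprint computation via Open Babel
# (ChemmineOB). MACCS keys are returned by Open Babel padded to 256 bits and
# the FP4 substructure keys padded to 512; only the 166 defined MACCS keys
# and 307 FP4 patterns are kept.

.MACCS_NBITS <- 166L
.SUBSTRUCTURE_NBITS <- 307L

.parse_one_smiles <- function(smiles) {
  tryCatch({
    mols <- ChemmineOB::forEachMol("SMILES", smiles, identity)
    length(mols) == 1L
  }, error = function(e) FALSE)
}

#' Read a SMILES file
#'
#' Reads a `.smi`-style file: one molecule per line, `SMILES[ whitespace id]`.
#' Lines without an identifier get the id `M<line number>`. Each SMILES is
#' checked against the chemistry backend (Open Babel); unparseable entries are
#' flagged in the `valid` column, never dropped.
#'
#' @param path path to the SMILES file.
#' @param validate check each SMILES with the chemistry backend
#'   (default `TRUE`).
#' @return A `molecule_set`: a data frame with columns `molecule_id`,
#'   `smiles`, `valid`.
#' @export
read_smiles <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) {
    out <- data.frame(molecule_id = character(), smiles = character(),
                      valid = logical(), stringsAsFactors = FALSE)
    class(out) <- c("molecule_set", class(out))
    return(out)
  }
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) >= 2) parts[[k]][[2]] else paste0("M", keep[k])
  }, character(1))
  explicit <- vapply(parts, function(p) length(p) >= 2, logical(1))
  dup <- duplicated(ids) & explicit
  if (any(dup))
    stop("duplicate explicit molecule id(s): ",
         paste(unique(ids[dup]), collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate molecule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  valid <- if (validate) vapply(smiles, .parse_one_smiles, logical(1),
                                USE.NAMES = FALSE) else rep(TRUE, length(smiles))
  out <- data.frame(molecule_id = ids, smiles = smiles, valid = valid,
                    stringsAsFactors = FALSE)
  class(out) <- c("molecule_set", class(out))
  out
}

#' Assemble a molecule set from SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param ids optional molecule ids; defaults to `M1`, `M2`, ...
#' @param validate check each SMILES with the chemistry backend.
#' @return A `molecule_set` data frame (see [read_smiles()]).
#' @export
molecule_set <- function(smiles, ids = NULL, validate = TRUE) {
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  if (anyDuplicated(ids))
    stop("duplicate molecule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  valid <- if (validate) vapply(smiles, .parse_one_smiles, logical(1),
                                USE.NAMES = FALSE) else rep(TRUE, length(smiles))
  out <- data.frame(molecule_id = as.character(ids), smiles = smiles,
                    valid = valid, stringsAsFactors = FALSE)
  class(out) <- c("molecule_set", class(out))
  out
}

#' Compute binary fingerprints from structures
#'
#' Computes a named binary fingerprint matrix for a set of molecules using
#' Open Babel: `"maccs"` gives the 166 MACCS structural keys (columns
#' `MACCSFP1` ... `MACCSFP166`), `"substructure"` the 307 FP4
#' functional-group/substructure keys (columns `SubFP1` ... `SubFP307`).
#' Deterministic for fixed input and backend version.
#'
#' @param mols a `molecule_set` (see [read_smiles()]) or character vector of
#'   SMILES.
#' @param scheme `"maccs"` or `"substructure"`.
#' @param on_invalid `"error"` to abort on an unparseable molecule (reporting
#'   its id), `"skip"` to drop it from the result.
#' @return Integer 0/1 matrix, one row per molecule (row names = molecule
#'   ids), one column per fingerprint bit.
#' @export
compute_fingerprints <- function(mols, scheme = c("maccs", "substructure"),
                                 on_invalid = c("error", "skip")) {
  scheme <- match.arg(scheme)
  on_invalid <- match.arg(on_invalid)
  if (is.character(mols)) mols <- molecule_set(mols)
  bad <- mols$molecule_id[!mols$valid]
  if (length(bad)) {
    if (on_invalid == "error")
      stop("unparseable molecule(s): ", paste(bad, collapse = ", "))
    mols <- mols[mols$valid, , drop = FALSE]
  }
  ob_name <- switch(scheme, maccs = "MACCS", substructure = "FP4")
  nbits <- switch(scheme, maccs = .MACCS_NBITS, substructure = .SUBSTRUCTURE_NBITS)
  prefix <- switch(scheme, maccs = "MACCSFP", substructure = "SubFP")
  if (nrow(mols) == 0L) {
    m <- matrix(integer(), nrow = 0, ncol = nbits,
                dimnames = list(character(), paste0(prefix, seq_len(nbits))))
    return(m)
  }
  refs <- ChemmineOB::forEachMol("SMILES",
                                 paste(mols$smiles, collapse = "\n"),
                                 identity)
  fp <- ChemmineOB::fingerprint_OB(refs, ob_name)
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = length(refs))
  m <- fp[, seq_len(nbits), drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- list(mols$molecule_id, paste0(prefix, seq_len(nbits)))
  m
}
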