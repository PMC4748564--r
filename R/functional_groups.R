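#' Read a functional-group definition file
#'
#' The file has one `name<TAB>SMARTS` pair per line; lines starting with
#' `#` are comments (SMARTS atom numbers like `#6` are untouched).
#' A curated default vocabulary (alcohols, ethers, ketones, esters, amines,
#' nitro, halides, ...) ships with the package, see
#' `system.file("extdata", "functional_groups.tsv", package = "potencyscreen")`.
#'
#' @param path path to the definition file; default: the shipped vocabulary.
#' @return Data frame with columns `group`, `pattern`.
#' @export
read_group_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "functional_groups.tsv",
                        package = "potencyscreen")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2))
    stop("each definition line must be 'name<TAB>pattern'")
  out <- data.frame(group = vapply(parts, `[[`, character(1), 1L),
                    pattern = vapply(parts, `[[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$group))
    stop("duplicate group name(s): ",
         paste(unique(out$group[duplicated(out$group)]), collapse = ", "))
  out
}

#' Count functional-group occurrences in molecules
#'
#' Matches each SMARTS pattern against each molecule with the chemistry
#' backend and counts distinct, symmetry-deduplicated substructure matches.
#'
#' @param mols a `molecule_set` (see [read_smiles()]) or character vector of
#'   SMILES; unparseable molecules are not allowed.
#' @param defs group definitions (data frame `group`, `pattern`), default
#'   the shipped vocabulary.
#' @return Integer count matrix, molecules x groups.
#' @export
match_groups <- function(mols, defs = read_group_definitions()) {
  if (is.character(mols)) mols <- molecule_set(mols)
  if (any(!mols$valid))
    stop("unparseable molecule(s): ",
         paste(mols$molecule_id[!mols$valid], collapse = ", "))
  refs <- ChemmineOB::forEachMol("SMILES",
                                 paste(mols$smiles, collapse = "\n"),
                                 identity)
  counts <- vapply(seq_len(nrow(defs)), function(k) {
    res <- tryCatch(
      ChemmineOB::smartsSearch_OB(refs, defs$pattern[k], uniqueMatches = TRUE),
      error = function(e) stop("invalid pattern for group '", defs$group[k],
                               "': ", conditionMessage(e)))
    as.integer(res)
  }, integer(nrow(mols)))
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = nrow(mols))
  dimnames(counts) <- list(mols$molecule_id, defs$group)
  counts
}

#' Per-class functional-group frequency
#'
#' Percentage of molecules of the class containing the group at least once.
#'
#' @param counts count matrix (molecules x groups), e.g. from
#'   [match_groups()].
#' @param labels class labels, one per molecule.
#' @param class `"active"` or `"inactive"`.
#' @return Named numeric vector of frequencies in `[0, 100]`, one per group.
#' @export
group_frequency <- function(counts, labels, class = "active") {
  labels <- normalize_labels(labels)
  idx <- which(labels == class)
  if (!length(idx)) stop("class '", class, "' is empty")
  100 * colSums(counts[idx, , drop = FALSE] >= 1) / length(idx)
}

#' Per-class mean count of a functional group
#'
#' @inheritParams group_frequency
#' @return Named numeric vector of mean occurrence counts, one per group.
#' @export
group_mean_count <- function(counts, labels, class = "active") {
  labels <- normalize_labels(labels)
  idx <- which(labels == class)
  if (!length(idx)) stop("class '", class, "' is empty")
  colSums(counts[idx, , drop = FALSE]) / length(idx)
}

#' Functional-group profile of both classes
#'
#' @inheritParams group_frequency
#' @return Data frame with one row per group and class: `group`, `class`,
#'   `frequency` (percent of class molecules containing the group),
#'   `mean_count`.
#' @export
group_profile <- function(counts, labels) {
  labels <- normalize_labels(labels)
  rows <- lapply(levels(labels)[table(labels)[levels(labels)] > 0],
                 function(cl) {
    data.frame(group = colnames(counts), class = cl,
               frequency = group_frequency(counts, labels, cl),
               mean_count = group_mean_count(counts, labels, cl),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
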