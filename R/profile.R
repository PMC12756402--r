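#' Phylogenetic profile matrices
#'
#' A `profile_matrix` stores per-species copy numbers for a set of gene or
#' domain families (families in rows, species in columns) together with a
#' per-family filter status. Statuses are `kept`, `removed_largest`
#' (total copy number above the size threshold), `removed_outgroup_only`
#' (absent from every ingroup species) and `removed_inference_failure`
#' (numerical failure during posterior computation).
#'
#' @param counts integer matrix, families x species, with row and column
#'   names (family IDs and species labels).
#' @return an object of class `profile_matrix`.
#' @export
profile_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stopf("counts must have species column names")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("fam", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) stopf("duplicate family IDs")
  if (anyDuplicated(colnames(counts))) stopf("duplicate species labels")
  if (any(!is.finite(counts))) stopf("counts contain missing or non-finite values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stopf("negative count at family '%s', species '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stopf("non-integer count at family '%s', species '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  storage.mode(counts) <- "integer"
  structure(list(
    counts = counts,
    status = stats::setNames(rep("kept", nrow(counts)), rownames(counts))
  ), class = "profile_matrix")
}

#' Read a phylogenetic profile matrix from TSV
#'
#' Expects a tab-delimited file whose header row holds the species labels
#' and whose first column holds family IDs; all cells must be non-negative
#' integers. All families start with status `kept`.
#'
#' @param path path to the TSV file.
#' @param tree optional [species_tree]; when given, the column set must
#'   equal the tree's leaf set (in any order) and columns are reordered to
#'   match the tree.
#' @return a [profile_matrix].
#' @export
read_profile_matrix <- function(path, tree = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stopf("profile TSV needs a family-ID column plus species columns")
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stopf("cell is not a number at family '%s', species '%s'",
          ids[bad[1]], colnames(num)[bad[2]])
  }
  pm <- profile_matrix(num)
  if (!is.null(tree)) pm <- align_profile_to_tree(pm, tree)
  pm
}

align_profile_to_tree <- function(pm, tree) {
  leaves <- tree$node_labels[seq_len(tree$n_tips)]
  extra <- setdiff(colnames(pm$counts), leaves)
  missing <- setdiff(leaves, colnames(pm$counts))
  if (length(extra) || length(missing)) {
    stopf("profile columns do not match tree leaves%s%s",
          if (length(extra)) paste0("; not in tree: ", paste(extra, collapse = ", ")) else "",
          if (length(missing)) paste0("; missing species: ", paste(missing, collapse = ", ")) else "")
  }
  pm$counts <- pm$counts[, leaves, drop = FALSE]
  pm
}

#' Write a profile matrix to TSV
#'
#' @param pm a [profile_matrix].
#' @param path output path.
#' @param kept_only write only families with status `kept`.
#' @export
write_profile_matrix <- function(pm, path, kept_only = FALSE) {
  stopifnot(inherits(pm, "profile_matrix"))
  counts <- pm$counts
  if (kept_only) counts <- counts[pm$status == "kept", , drop = FALSE]
  df <- data.frame(family = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the kept-family count matrix
#'
#' @param pm a [profile_matrix].
#' @return integer matrix restricted to families with status `kept`.
#' @export
kept_counts <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  pm$counts[pm$status == "kept", , drop = FALSE]
}

#' Apply the study's family filters
#'
#' Two filters are applied, mirroring standard practice for copy-number
#' matrices used with birth-death-gain models: (1) families whose total
#' copy number across all species exceeds `size_threshold` are flagged
#' `removed_largest` (very large families inflate duplication-rate
#' estimates); (2) families with zero copies in every non-outgroup species
#' are flagged `removed_outgroup_only`. Counts themselves are never
#' modified, and filtering is idempotent. Instead of an absolute
#' threshold, the top fraction of families by total size can be removed
#' via `size_quantile`.
#'
#' @param pm a [profile_matrix].
#' @param size_threshold remove families with total count strictly greater
#'   than this value (default 3300).
#' @param outgroups character vector of outgroup species labels.
#' @param size_quantile optional fraction in (0, 1); when given, overrides
#'   `size_threshold` with the (1 - size_quantile) quantile of total
#'   counts (e.g. 0.025 removes the largest 2.5%).
#' @return the [profile_matrix] with updated statuses.
#' @export
apply_study_filters <- function(pm, size_threshold = 3300, outgroups = character(),
                                size_quantile = NULL) {
  stopifnot(inherits(pm, "profile_matrix"))
  bad <- setdiff(outgroups, colnames(pm$counts))
  if (length(bad)) stopf("outgroups not among species: %s", paste(bad, collapse = ", "))
  totals <- rowSums(pm$counts)
  if (!is.null(size_quantile)) {
    if (size_quantile <= 0 || size_quantile >= 1) stopf("size_quantile must be in (0,1)")
    size_threshold <- stats::quantile(totals, 1 - size_quantile, names = FALSE)
  }
  if (size_threshold <= 0) stopf("size_threshold must be positive")
  status <- stats::setNames(rep("kept", nrow(pm$counts)), rownames(pm$counts))
  status[pm$status == "removed_inference_failure"] <- "removed_inference_failure"
  status[totals > size_threshold] <- "removed_largest"
  ingroup <- setdiff(colnames(pm$counts), outgroups)
  ing_present <- rowSums(pm$counts[, ingroup, drop = FALSE] > 0) > 0
  status[!ing_present & status == "kept"] <- "removed_outgroup_only"
  if (!any(status == "kept")) stopf("filters removed all families")
  pm$status <- status
  pm
}

#' Descriptive summaries of a profile matrix
#'
#' Computed on kept families only: per clade, the number of core families
#' (non-zero in every clade member); the number of species-specific
#' families (non-zero in exactly one species overall); and per species the
#' fraction of families present and the fraction present in more than one
#' copy.
#'
#' @param pm a [profile_matrix].
#' @param clades named list of character vectors of species labels.
#' @return a list with elements `clades` (data frame: clade, core
#'   families), `species_specific` (count), and `per_species` (data frame:
#'   species, fraction_present, fraction_multicopy).
#' @export
profile_summaries <- function(pm, clades = list()) {
  counts <- kept_counts(pm)
  if (length(clades)) {
    for (nm in names(clades)) {
      cl <- clades[[nm]]
      if (length(cl) == 0) stopf("clade '%s' is empty", nm)
      bad <- setdiff(cl, colnames(counts))
      if (length(bad)) stopf("clade '%s' names unknown species: %s", nm,
                             paste(bad, collapse = ", "))
    }
  }
  core <- vapply(clades, function(cl) {
    sum(rowSums(counts[, cl, drop = FALSE] > 0) == length(cl))
  }, integer(1))
  present_n <- rowSums(counts > 0)
  list(
    clades = data.frame(clade = names(clades), core_families = unname(core),
                        stringsAsFactors = FALSE),
    species_specific = sum(present_n == 1),
    per_species = data.frame(
      species = colnames(counts),
      fraction_present = colMeans(counts > 0),
      fraction_multicopy = colMeans(counts > 1),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("kept", "removed_largest",
                                           "removed_outgroup_only",
                                           "removed_inference_failure")))
  cat(sprintf("profile_matrix: %d families x %d species\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  kept %d | removed_largest %d | removed_outgroup_only %d | removed_inference_failure %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}
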