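#' Family function annotations
#'
#' Maps each family to at most one general and one detailed functional
#' category, following the structure of curated domain-function
#' ontologies in which detailed functions nest inside a handful of
#' general ones. The detailed categories `"general"` and
#' `"unknown function"` are treated as uninformative and flagged so that
#' functional analyses can exclude them.
#'
#' @param family character vector of family IDs.
#' @param general character vector of general-function categories.
#' @param detailed character vector of detailed-function categories.
#' @param uninformative detailed categories considered uninformative.
#' @return a data frame of class `function_annotation` with columns
#'   `family`, `general`, `detailed`, `informative`.
#' @export
function_annotation <- function(family, general, detailed,
                                uninformative = c("general", "unknown function")) {
  if (anyDuplicated(family)) stopf("family annotated more than once: %s",
                                   paste(unique(family[duplicated(family)]), collapse = ", "))
  ann <- data.frame(family = as.character(family),
                    general = as.character(general),
                    detailed = as.character(detailed),
                    stringsAsFactors = FALSE)
  ann$informative <- !(ann$detailed %in% uninformative)
  class(ann) <- c("function_annotation", "data.frame")
  ann
}

#' Read a family annotation TSV
#'
#' Expects three tab-separated columns: family ID, general function,
#' detailed function (header row required).
#'
#' @param path path to the TSV file.
#' @inheritParams function_annotation
#' @return a [function_annotation].
#' @export
read_function_annotation <- function(path,
                                     uninformative = c("general", "unknown function")) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3) stopf("annotation TSV needs columns: family, general, detailed")
  function_annotation(df[[1]], df[[2]], df[[3]], uninformative = uninformative)
}

#' Write a family annotation TSV
#' @param ann a [function_annotation].
#' @param path output path.
#' @export
write_function_annotation <- function(ann, path) {
  utils::write.table(ann[, c("family", "general", "detailed")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
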