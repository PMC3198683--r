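# Readers/writers for the Broad expression-analysis text dialects (GCT, CLS,
# GMT) plus the small CSV/TIFF/JSON carriers used by the pipeline. The Broad
# formats are simple enough that the parsers live here; GMT reading is
# cross-checked against fgsea in the test suite.

#' Write an expression matrix as GCT
#'
#' GCT is the Broad tab-separated expression format: a `#1.2` version line, a
#' dimensions line, then a header and one row per gene with `Name` and
#' `Description` columns ahead of the sample columns.
#'
#' @param exprs numeric matrix, genes x samples, with row and column names.
#' @param path output file path.
#' @param descriptions optional per-gene description column (defaults to "na").
#' @return Invisibly, `path`.
#' @export
write_gct <- function(exprs, path, descriptions = NULL) {
  stopifnot(is.matrix(exprs), !is.null(rownames(exprs)), !is.null(colnames(exprs)))
  descriptions <- descriptions %||% rep("na", nrow(exprs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(exprs), ncol(exprs), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(exprs)), collapse = "\t"), con)
  body <- cbind(rownames(exprs), descriptions,
                format(exprs, trim = TRUE, digits = 12, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a GCT expression matrix
#'
#' @param path GCT file path.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#1.2")) stop_param("not a #1.2 GCT file: %s", path)
  dims <- as.integer(strsplit(lines[2L], "\t")[[1L]][1:2])
  header <- strsplit(lines[3L], "\t")[[1L]]
  body <- strsplit(lines[3L + seq_len(dims[1L])], "\t")
  mat <- t(vapply(body, function(f) as.numeric(f[-(1:2)]), numeric(dims[2L])))
  if (dims[2L] == 1L) mat <- matrix(mat, ncol = 1L)
  rownames(mat) <- vapply(body, `[[`, character(1L), 1L)
  colnames(mat) <- header[-(1:2)]
  mat
}

#' Write a two-class phenotype CLS file
#'
#' @param classes character or factor vector of per-sample class labels, in
#'   sample order; exactly two distinct labels.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cls <- function(classes, path) {
  classes <- as.character(classes)
  lev <- unique(classes)
  if (length(lev) != 2L) stop_param("CLS writer expects exactly two classes")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(length(classes), 2L, 1L),
               paste("#", paste(lev, collapse = " ")),
               paste(match(classes, lev) - 1L, collapse = " ")), con)
  invisible(path)
}

#' Read a two-class CLS phenotype file
#'
#' @param path CLS file path.
#' @return Character vector of per-sample class labels.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  lev <- strsplit(sub("^#\\s*", "", lines[2L]), "\\s+")[[1L]]
  idx <- strsplit(trimws(lines[3L]), "\\s+")[[1L]]
  if (all(idx %in% lev)) return(idx)  # label dialect
  lev[as.integer(idx) + 1L]
}

#' Write a gene-set collection as GMT
#'
#' One tab-separated line per set: name, description, then member genes.
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param path output file path.
#' @param descriptions optional per-set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, d, genes) paste(c(nm, d, genes), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  sets
}

#' Write a cohort table as CSV
#'
#' @param cohort data frame with columns `animal_id`, `arm`, `tumor_weight`,
#'   `metastasis`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV with columns `animal_id`, `arm`, `tumor_weight`,
#'   `metastasis`.
#' @return Validated cohort data frame (`metastasis` coerced to logical).
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "arm", "tumor_weight", "metastasis")
  if (!all(need %in% names(df))) {
    stop_param("cohort CSV must have columns: %s", paste(need, collapse = ", "))
  }
  df$metastasis <- as.logical(df$metastasis)
  if (anyDuplicated(df$animal_id)) stop_param("duplicate animal_id in cohort")
  df
}

#' Write a Cq matrix (genes x samples) with a gene-role column as CSV
#'
#' @param cq numeric matrix of quantification cycles, genes x samples.
#' @param roles character vector, `"reference"` or `"target"`, one per gene.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cq_csv <- function(cq, roles, path) {
  stopifnot(nrow(cq) == length(roles))
  df <- data.frame(gene = rownames(cq), role = roles, cq, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a Cq matrix CSV written by [write_cq_csv()]
#'
#' @param path CSV path.
#' @return List with `cq` (matrix) and `roles` (character vector).
#' @export
read_cq_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cq <- as.matrix(df[, setdiff(names(df), c("gene", "role")), drop = FALSE])
  rownames(cq) <- df$gene
  list(cq = cq, roles = df$role)
}

#' Write a grayscale image as 16-bit TIFF
#'
#' Intensities are clipped to `[0, 1]` and stored at 16-bit depth.
#'
#' @param img numeric matrix with values nominally in `[0, 1]`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_gray_tiff <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF as a numeric matrix in `[0, 1]`
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path TIFF file path.
#' @return Numeric matrix.
#' @export
read_gray_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img
}
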