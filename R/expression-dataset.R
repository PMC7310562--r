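#' Construct an expression dataset
#'
#' An `expression_dataset` bundles a gene-by-sample expression matrix with the
#' per-sample metadata that every downstream stage of the pipeline needs:
#' species, brain region and age in postconception days (PCD). It is the
#' universal currency of the package: preprocessing, demarcation clustering,
#' DNB scoring, differential expression, heterochrony and network analysis all
#' consume and return this container.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (row names).
#' @param samples Data frame of sample metadata with columns `sample_id`,
#'   `species` (`"human"` or `"macaque"`), `region`, `age_pcd` (positive,
#'   postconception days) and optionally `stage` (`"early"`/`"late"`).
#' @param scale Either `"linear"` or `"log2"`; records the scale `values` are
#'   on so that transforms can enforce their preconditions.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `samples` and `scale`.
#' @seealso [load_expression()], [filter_expressed()], [log2_z_transform()],
#'   [split_by_age()]
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               samples, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids)) stop("gene_ids are required (or row names on 'values')")
  gene_ids <- as.character(gene_ids)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "species", "region", "age_pcd")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0)
    stop("missing column in sample metadata: ", paste(missing_cols, collapse = ", "))
  if (nrow(values) != length(gene_ids))
    stop("row count of values (", nrow(values), ") != number of gene ids (",
         length(gene_ids), ")")
  if (ncol(values) != nrow(samples))
    stop("column count of values (", ncol(values), ") != number of samples (",
         nrow(samples), ")")
  if (anyDuplicated(gene_ids)) stop("duplicate gene id")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample id")
  if (!all(samples$species %in% c("human", "macaque")))
    stop("species must be 'human' or 'macaque'")
  samples$age_pcd <- as.numeric(samples$age_pcd)
  if (anyNA(samples$age_pcd) || any(samples$age_pcd <= 0))
    stop("age_pcd must be a positive number")
  rownames(values) <- gene_ids
  colnames(values) <- samples$sample_id
  rownames(samples) <- NULL
  structure(list(values = values, gene_ids = gene_ids, samples = samples,
                 scale = scale),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", length(x$gene_ids), " genes x ",
      nrow(x$samples), " samples (", x$scale, " scale)\n", sep = "")
  cat("  species: ", paste(unique(x$samples$species), collapse = ", "),
      "; regions: ", paste(unique(x$samples$region), collapse = ", "), "\n",
      sep = "")
  cat("  age range: ", min(x$samples$age_pcd), "-", max(x$samples$age_pcd),
      " PCD\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset an expression dataset by genes and/or samples
#'
#' @param x An `expression_dataset`.
#' @param i Gene index (integer, logical or character gene ids).
#' @param j Sample index (integer, logical or character sample ids).
#' @param ... Ignored.
#' @return The subsetted `expression_dataset`.
#' @export
`[.expression_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$gene_ids)
  if (missing(j)) j <- seq_len(nrow(x$samples))
  if (is.character(i)) i <- match(i, x$gene_ids)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  expression_dataset(x$values[i, j, drop = FALSE], x$gene_ids[i],
                     x$samples[j, , drop = FALSE], x$scale)
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and gene
#' ids in the first column. The metadata file is tab-separated with columns
#' `sample_id`, `species`, `region`, `age_pcd` and optionally `stage`.
#' Columns of the returned dataset follow the metadata order.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @param scale Scale the stored values are on (`"linear"` or `"log2"`).
#' @return An [expression_dataset()].
#' @export
load_expression <- function(matrix_path, meta_path, scale = "linear") {
  mat <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA)
  gene_ids <- as.character(mat[[1L]])
  values <- as.matrix(mat[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric cell in expression matrix")
  if (anyDuplicated(gene_ids)) stop("duplicate gene id in expression matrix")
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  required <- c("sample_id", "species", "region", "age_pcd")
  miss <- setdiff(required, names(meta))
  if (length(miss) > 0)
    stop("missing column in sample metadata: ", paste(miss, collapse = ", "))
  idx <- match(meta$sample_id, colnames(values))
  if (anyNA(idx) || ncol(values) != nrow(meta))
    stop("sample mismatch between expression matrix and metadata")
  expression_dataset(values[, idx, drop = FALSE], gene_ids, meta, scale)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [load_expression()]: writes the expression matrix (gene ids in
#' the first column, one column per sample) and the sample metadata table.
#'
#' @param ds An `expression_dataset`.
#' @param matrix_path Output path for the matrix TSV.
#' @param meta_path Output path for the metadata TSV.
#' @return Invisibly, `ds`.
#' @export
write_expression <- function(ds, matrix_path, meta_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene_id = ds$gene_ids, ds$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Construct a gene-set collection
#'
#' @param sets Named list mapping set names to character vectors of gene ids.
#' @param universe Optional character vector: the gene universe enrichment
#'   tests are computed against.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    if (length(s) == 0) stop("empty gene set")
    s
  })
  structure(list(sets = sets,
                 universe = if (is.null(universe)) NULL else unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection: ", length(x$sets), " sets",
      if (!is.null(x$universe)) paste0(", universe of ", length(x$universe), " genes"),
      "\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Each GMT line is `set-name <TAB> description <TAB> member1 <TAB> member2 ...`.
#'
#' @param path Path to a GMT file.
#' @param universe Optional gene universe attached to the collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) stop("malformed GMT line (need name, description, >=1 member)")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, universe)
}

#' Write gene sets in GMT format
#'
#' @param gsc A [gene_set_collection()] or named list of gene id vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gsc, path, descriptions = NULL) {
  sets <- if (inherits(gsc, "gene_set_collection")) gsc$sets else gsc
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members)
    paste(c(nm, desc, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
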