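#' Read a delimited gene-by-sample (or sample-by-drug) matrix
#'
#' Reads a delimited text file with one header row of ids and one id column
#' into a numeric matrix. The first column supplies row ids, the header row
#' supplies column ids. Cells that cannot be parsed as numbers become `NA`.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"rows-are-genes"` (expression / dependency screens) or
#'   `"rows-are-samples"` (drug-sensitivity tables). Only recorded as an
#'   attribute; the matrix is returned as stored in the file.
#' @param sep Field delimiter (default comma, the DepMap convention).
#' @return A numeric matrix with `rownames` / `colnames` set from the file,
#'   and an `"orientation"` attribute.
#' @export
read_matrix <- function(path,
                        orientation = c("rows-are-genes", "rows-are-samples"),
                        sep = ",") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", row.names = NULL)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty or id-only matrix file: ", path)
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  check_unique_ids(row_ids, "row")
  check_unique_ids(col_ids, "column")
  values <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  values <- matrix(values, nrow = length(row_ids),
                   dimnames = list(row_ids, col_ids))
  attr(values, "orientation") <- orientation
  values
}

#' Write a matrix in the delimited format `read_matrix()` reads
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param id_header Name for the leading id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sep = ",", id_header = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_header
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) stop("missing ", what, " id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " id(s): ", paste(head(dup, 5L), collapse = ", "))
  invisible(ids)
}

#' Align expression, sensitivity and dependency tables on common samples
#'
#' Restricts all three tables to the samples present in each of them that
#' additionally have no missing sensitivity value for any of the requested
#' drugs (cell lines are matched across the assays "without missing values").
#' Samples are returned in lexicographic order so every downstream stage is
#' deterministic regardless of input file order.
#'
#' @param expr Genes x samples expression matrix.
#' @param sens Samples x drugs sensitivity matrix.
#' @param dep Genes x samples dependency-screen matrix.
#' @param drug_ids Drugs whose sensitivity must be observed for a sample to
#'   be retained.
#' @param regulator_ids,target_ids Optional candidate-regulator and target
#'   gene sets (default: all expression genes).
#' @return An `aligned_dataset`: list with components `expression`,
#'   `sensitivity`, `dependency`, `regulator_ids`, `target_ids`,
#'   `sample_ids`.
#' @export
align_samples <- function(expr, sens, dep, drug_ids,
                          regulator_ids = NULL, target_ids = NULL) {
  stopifnot(is.matrix(expr), is.matrix(sens), is.matrix(dep))
  if (!all(drug_ids %in% colnames(sens)))
    stop("unknown drug id(s): ",
         paste(setdiff(drug_ids, colnames(sens)), collapse = ", "))
  common <- intersect(intersect(colnames(expr), rownames(sens)),
                      colnames(dep))
  if (length(common) == 0L) stop("no samples common to all three tables")
  keep <- common[rowSums(is.na(sens[common, drug_ids, drop = FALSE])) == 0L]
  if (length(keep) == 0L)
    stop("no common sample has complete sensitivity for the requested drugs")
  keep <- sort(keep)

  expr <- expr[, keep, drop = FALSE]
  dep <- dep[, keep, drop = FALSE]
  sens <- sens[keep, , drop = FALSE]
  if (anyNA(expr)) stop("missing expression values for retained samples")
  if (anyNA(dep)) stop("missing dependency values for retained samples")

  if (is.null(regulator_ids)) regulator_ids <- rownames(expr)
  if (is.null(target_ids)) target_ids <- rownames(expr)
  if (!all(regulator_ids %in% rownames(expr)))
    stop("regulator id(s) absent from expression matrix")
  if (!all(target_ids %in% rownames(expr)))
    stop("target id(s) absent from expression matrix")

  structure(list(expression = expr, sensitivity = sens, dependency = dep,
                 regulator_ids = regulator_ids, target_ids = target_ids,
                 sample_ids = keep),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("aligned_dataset:", length(x$sample_ids), "samples,",
      nrow(x$expression), "genes,", ncol(x$sensitivity), "drugs\n")
  cat("  regulators:", length(x$regulator_ids),
      " targets:", length(x$target_ids), "\n")
  invisible(x)
}

#' Top-k highest-variance genes
#'
#' Helper for assembling a candidate-regulator list when no curated list is
#' available (the usual practice combines curated regulators with the
#' highest-variance genes).
#'
#' @param expr Genes x samples expression matrix.
#' @param k Number of genes.
#' @return Character vector of gene ids, by decreasing variance.
#' @export
top_variance_genes <- function(expr, k) {
  stopifnot(is.matrix(expr), k >= 1L)
  v <- apply(expr, 1L, var)
  names(sort(v, decreasing = TRUE))[seq_len(min(k, nrow(expr)))]
}

#' Edge tables
#'
#' An edge list is a data frame with columns `target`, `regulator`,
#' `weight` and optionally `sample`; `(target, regulator, sample)` triples
#' are unique and weights are finite.
#'
#' @param edges Edge-list data frame.
#' @param path File path.
#' @param sep Field delimiter (default tab).
#' @return `write_edge_table()` returns `path` invisibly;
#'   `read_edge_table()` returns the edge-list data frame.
#' @export
write_edge_table <- function(edges, path, sep = "\t") {
  edges <- validate_edge_list(edges)
  write.table(edges, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path, sep = "\t") {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty edge table: ", path)
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  need <- c("target", "regulator", "weight")
  if (!all(need %in% header))
    stop("edge table must have columns target, regulator, weight")
  n_fields <- length(header)
  body <- lines[-1L]
  out <- data.frame(target = character(0), regulator = character(0),
                    weight = numeric(0), stringsAsFactors = FALSE)
  if ("sample" %in% header) out$sample <- character(0)
  if (length(body)) {
    parts <- strsplit(body, sep, fixed = TRUE)
    bad <- which(lengths(parts) != n_fields)
    if (length(bad))
      stop("malformed edge-table row at line ", bad[1L] + 1L)
    m <- do.call(rbind, parts)
    colnames(m) <- header
    w <- suppressWarnings(as.numeric(m[, "weight"]))
    if (anyNA(w))
      stop("non-numeric weight at line ",
           which(is.na(w))[1L] + 1L)
    out <- data.frame(target = m[, "target"], regulator = m[, "regulator"],
                      weight = w, stringsAsFactors = FALSE)
    if ("sample" %in% header) out$sample <- m[, "sample"]
  }
  validate_edge_list(out)
}

validate_edge_list <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("target", "regulator", "weight") %in% colnames(edges)))
  if (nrow(edges)) {
    if (any(!is.finite(edges$weight))) stop("non-finite edge weight")
    key <- paste(edges$target, edges$regulator,
                 if ("sample" %in% colnames(edges)) edges$sample else "",
                 sep = "\r")
    if (anyDuplicated(key)) stop("duplicate (target, regulator, sample) triple")
  }
  edges
}
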