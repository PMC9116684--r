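#' Persist and reload a network stack
#'
#' The stack is stored as a sparse per-sample edge table (tab-delimited)
#' plus a JSON manifest of axis ids, bandwidths and the modulator drug, so
#' everything round-trips through plain text.
#'
#' @param stack A `network_stack`.
#' @param dir Directory (created if needed).
#' @return `dir` invisibly; `read_network_stack()` returns the stack.
#' @export
write_network_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "network_stack"))
  need_jsonlite()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_table(stack_edge_list(stack), file.path(dir, "edges.tsv"))
  manifest <- list(sample_ids = stack$sample_ids,
                   target_ids = stack$target_ids,
                   regulator_ids = stack$regulator_ids,
                   bandwidths = as.list(stack$bandwidths),
                   modulator_drug = stack$modulator_drug,
                   penalty = unclass(stack$penalty))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_network_stack
#' @export
read_network_stack <- function(dir) {
  need_jsonlite()
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  edges <- read_edge_table(file.path(dir, "edges.tsv"))
  coefs <- array(0, dim = c(length(manifest$sample_ids),
                            length(manifest$target_ids),
                            length(manifest$regulator_ids)),
                 dimnames = list(manifest$sample_ids, manifest$target_ids,
                                 manifest$regulator_ids))
  if (nrow(edges))
    coefs[cbind(match(edges$sample, manifest$sample_ids),
                match(edges$target, manifest$target_ids),
                match(edges$regulator, manifest$regulator_ids))] <- edges$weight
  penalty <- manifest$penalty
  penalty$lambda <- if (is.null(penalty$lambda)) NULL else penalty$lambda
  structure(list(coefficients = coefs,
                 bandwidths = unlist(manifest$bandwidths),
                 sample_ids = manifest$sample_ids,
                 target_ids = manifest$target_ids,
                 regulator_ids = manifest$regulator_ids,
                 modulator_drug = manifest$modulator_drug,
                 penalty = structure(penalty, class = "penalty_config")),
            class = "network_stack")
}

#' Persist and reload a feature matrix
#'
#' @param features A `feature_matrix`.
#' @param dir Directory (created if needed).
#' @return `dir` invisibly; `read_features()` returns the
#'   `feature_matrix`.
#' @export
write_features <- function(features, dir) {
  stopifnot(inherits(features, "feature_matrix"))
  need_jsonlite()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(features$x, file.path(dir, "features.csv"),
               id_header = "sample")
  write.table(features$column_map, file.path(dir, "column_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(labels = as.list(features$y),
               modulator_drug = features$modulator_drug,
               response_drug = features$response_drug)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_features
#' @export
read_features <- function(dir) {
  need_jsonlite()
  x <- read_matrix(file.path(dir, "features.csv"), "rows-are-samples")
  attr(x, "orientation") <- NULL
  column_map <- read.delim(file.path(dir, "column_map.tsv"), sep = "\t",
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(x = x, y = unlist(meta$labels)[rownames(x)],
                 column_map = column_map,
                 modulator_drug = meta$modulator_drug,
                 response_drug = meta$response_drug),
            class = "feature_matrix")
}

need_jsonlite <- function() {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the jsonlite package is required for JSON serialization")
}
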