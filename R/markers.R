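#' Edges present in every sample's network
#'
#' An edge is "pan-cancer" when its coefficient exceeds `tol` in absolute
#' value in every sample of the stack. The reported weight is the
#' across-sample mean coefficient (membership, not weight, is what defines
#' the set).
#'
#' @param stack A `network_stack`.
#' @param tol Presence tolerance on the coefficient scale.
#' @return Edge-list data frame (`target`, `regulator`, `weight`).
#' @export
pan_cancer_edges <- function(stack, tol = 1e-12) {
  stopifnot(inherits(stack, "network_stack"))
  coefs <- stack$coefficients
  d <- dim(coefs)
  present <- apply(abs(coefs) > tol, c(2L, 3L), all) # L x J
  idx <- which(present, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(target = character(0), regulator = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  wt <- vapply(seq_len(nrow(idx)),
               function(i) mean(coefs[, idx[i, 1L], idx[i, 2L]]), 0)
  out <- data.frame(target = stack$target_ids[idx[, 1L]],
                    regulator = stack$regulator_ids[idx[, 2L]],
                    weight = wt, stringsAsFactors = FALSE)
  out[order(out$target, out$regulator), , drop = FALSE]
}

#' Drug-drug similarity network from shared crucial edges
#'
#' Two drugs are connected if their crucial-edge sets share at least one
#' (target, regulator) pair; the edge weight is the size of the
#' intersection.
#'
#' @param crucial_sets Named list (by drug) of `crucial_edges` objects or
#'   data frames with `target` / `regulator` columns.
#' @return A `drug_network`: data frame (`drug_a`, `drug_b`,
#'   `n_common_crucial`) with the drug ids as attribute `"nodes"`.
#' @export
drug_similarity_network <- function(crucial_sets) {
  if (length(crucial_sets) < 2L) stop("need at least 2 drugs")
  drugs <- names(crucial_sets)
  if (is.null(drugs) || any(!nzchar(drugs)))
    stop("crucial_sets must be a named list")
  keys <- lapply(crucial_sets, function(s) {
    e <- if (inherits(s, "crucial_edges")) s$edges else s
    unique(paste(e$target, e$regulator, sep = "\r"))
  })
  rows <- list()
  for (i in seq_len(length(drugs) - 1L)) {
    for (j in (i + 1L):length(drugs)) {
      n_common <- length(intersect(keys[[i]], keys[[j]]))
      if (n_common >= 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          drug_a = drugs[i], drug_b = drugs[j],
          n_common_crucial = n_common, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(drug_a = character(0), drug_b = character(0),
                         n_common_crucial = integer(0),
                         stringsAsFactors = FALSE)
  structure(out, nodes = drugs, class = c("drug_network", "data.frame"))
}

#' Sensitive- and resistant-specific marker edges
#'
#' A candidate edge is a sensitive marker when its regulatory effect
#' exceeds `tol` in at least one sensitive sample and stays within `tol`
#' in every resistant sample; resistant markers are the mirror image. Only
#' samples labelled sensitive or resistant are considered. The two marker
#' lists are disjoint by construction.
#'
#' @param tensor A `re_tensor`.
#' @param labels A `sensitivity_labels` covering the tensor's samples.
#' @param edges Candidate edges (data frame with `target`, `regulator`);
#'   default all L x J pairs.
#' @param tol Presence tolerance on the regulatory-effect scale.
#' @return A `marker_set`: `sensitive_markers` / `resistant_markers` edge
#'   data frames, `tol`, `drug`.
#' @export
sensitivity_specific_markers <- function(tensor, labels, edges = NULL,
                                         tol = 1e-12) {
  stopifnot(inherits(tensor, "re_tensor"),
            inherits(labels, "sensitivity_labels"))
  lab <- labels$labels[tensor$sample_ids]
  sens_idx <- which(lab == "sensitive")
  res_idx <- which(lab == "resistant")
  if (!length(sens_idx) || !length(res_idx))
    stop("need at least one sample in each class")
  if (is.null(edges))
    edges <- expand.grid(target = tensor$target_ids,
                         regulator = tensor$regulator_ids,
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  cls <- character(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    l <- match(edges$target[i], tensor$target_ids)
    j <- match(edges$regulator[i], tensor$regulator_ids)
    if (is.na(l) || is.na(j))
      stop("candidate edge outside the tensor: ", edges$target[i],
           " <- ", edges$regulator[i])
    re_s <- abs(tensor$values[sens_idx, l, j])
    re_r <- abs(tensor$values[res_idx, l, j])
    cls[i] <- if (any(re_s > tol) && all(re_r <= tol)) "sensitive"
              else if (any(re_r > tol) && all(re_s <= tol)) "resistant"
              else "unclassified"
  }
  sens_m <- edges[cls == "sensitive", , drop = FALSE]
  res_m <- edges[cls == "resistant", , drop = FALSE]
  stopifnot(nrow(merge(sens_m, res_m)) == 0L) # disjointness invariant
  structure(list(sensitive_markers = sens_m, resistant_markers = res_m,
                 tol = tol, drug = labels$response_drug),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set (", x$drug, "): ", nrow(x$sensitive_markers),
      " sensitive-specific, ", nrow(x$resistant_markers),
      " resistant-specific edges\n", sep = "")
  invisible(x)
}

#' Export a samples-by-edges regulatory-effect table
#'
#' Writes the table behind a class-annotated heatmap: one row per
#' sensitive/resistant sample, one column per selected edge
#' (`regulator>target` headers) plus a leading label column.
#'
#' @param tensor A `re_tensor`.
#' @param labels A `sensitivity_labels`.
#' @param edges Data frame of edges (`target`, `regulator`) to export.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
export_regulatory_effect_table <- function(tensor, labels, edges, path) {
  stopifnot(inherits(tensor, "re_tensor"),
            inherits(labels, "sensitivity_labels"), is.data.frame(edges))
  lab <- labels$labels[tensor$sample_ids]
  keep <- which(lab != "intermediate")
  out <- data.frame(sample = tensor$sample_ids[keep], label = lab[keep],
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(edges))) {
    l <- match(edges$target[i], tensor$target_ids)
    j <- match(edges$regulator[i], tensor$regulator_ids)
    if (is.na(l) || is.na(j))
      stop("edge outside the tensor: ", edges$target[i], " <- ",
           edges$regulator[i])
    out[[paste0(edges$regulator[i], ">", edges$target[i])]] <-
      tensor$values[keep, l, j]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
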