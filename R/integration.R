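## Candidate selection: intersect per-metabolite linear-model hits with
## trait-associated network modules; overlap bookkeeping across time points
## and breeds; exploratory clustering of RFI-significant metabolites.

#' Intersect linear-model hits with selected modules
#'
#' For every (module, trait) pair selected by the module-trait screen, the
#' candidate members are the metabolites that are both significant in the
#' per-metabolite association for that trait (p <= alpha) and assigned to
#' that module.  The per-group unique union removes metabolites selected by
#' several traits.
#'
#' @param assoc_tables Named list of `association_table`s, one per trait.
#' @param partition A `module_partition`.
#' @param module_trait A `module_trait_table`.
#' @param alpha Association significance threshold (default 0.05,
#'   inclusive).
#' @return A `candidate_set`: list with `sets` (data.frame module, trait,
#'   n, members as list-column), `members_long` (data.frame module, trait,
#'   metabolite_id), `unique_union` (deduplicated IDs).
#' @export
intersect_candidates <- function(assoc_tables, partition, module_trait,
                                 alpha = 0.05) {
  sel <- module_trait[module_trait$selected, , drop = FALSE]
  rows <- list()
  long <- list()
  for (i in seq_len(nrow(sel))) {
    mod <- sel$module[i]; tr <- sel$trait[i]
    at <- assoc_tables[[tr]]
    assert_that(!is.null(at), paste("no association table for trait", tr))
    hits <- at$metabolite_id[!is.na(at$p_value) & at$p_value <= alpha]
    members <- names(partition$colors)[partition$colors == mod]
    cand <- sort(intersect(hits, members))
    rows[[i]] <- data.frame(module = mod, trait = tr, n = length(cand),
                            stringsAsFactors = FALSE)
    if (length(cand) > 0)
      long[[i]] <- data.frame(module = mod, trait = tr,
                              metabolite_id = cand, stringsAsFactors = FALSE)
  }
  sets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), trait = character(), n = integer())
  members_long <- if (length(long)) do.call(rbind, long) else
    data.frame(module = character(), trait = character(),
               metabolite_id = character())
  structure(list(sets = sets, members_long = members_long,
                 unique_union = sort(unique(members_long$metabolite_id))),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d (module, trait) pairs, %d unique metabolites\n",
              nrow(x$sets), length(x$unique_union)))
  invisible(x)
}

#' Overlap of candidate sets across time points and breeds
#'
#' @param sets Named list of character vectors of metabolite IDs, keyed
#'   `"<breed>_TP1"` / `"<breed>_TP2"`.
#' @return List (class `overlap_summary`): per breed `common`,
#'   `unique_tp1`, `unique_tp2` (IDs and counts), plus `cross_breed`
#'   pairwise intersections of each breed's union.
#' @export
timepoint_overlap <- function(sets) {
  keys <- names(sets)
  breeds <- unique(sub("_TP[12]$", "", keys))
  per_breed <- list()
  for (b in breeds) {
    k1 <- paste0(b, "_TP1"); k2 <- paste0(b, "_TP2")
    assert_that(all(c(k1, k2) %in% keys),
                paste("missing group key for breed", b))
    s1 <- sets[[k1]]; s2 <- sets[[k2]]
    per_breed[[b]] <- list(common = sort(intersect(s1, s2)),
                           unique_tp1 = sort(setdiff(s1, s2)),
                           unique_tp2 = sort(setdiff(s2, s1)),
                           n_tp1 = length(s1), n_tp2 = length(s2),
                           n_common = length(intersect(s1, s2)))
  }
  cross <- list()
  if (length(breeds) >= 2) {
    cmb <- utils::combn(breeds, 2)
    for (i in seq_len(ncol(cmb))) {
      b1 <- cmb[1, i]; b2 <- cmb[2, i]
      u1 <- union(sets[[paste0(b1, "_TP1")]], sets[[paste0(b1, "_TP2")]])
      u2 <- union(sets[[paste0(b2, "_TP1")]], sets[[paste0(b2, "_TP2")]])
      cross[[paste(b1, b2, sep = "_x_")]] <- sort(intersect(u1, u2))
    }
  }
  structure(list(per_breed = per_breed, cross_breed = cross),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  for (b in names(x$per_breed)) {
    pb <- x$per_breed[[b]]
    cat(sprintf("%s: %d common of TP1 = %d / TP2 = %d\n", b, pb$n_common,
                pb$n_tp1, pb$n_tp2))
  }
  invisible(x)
}

#' Cluster RFI-significant metabolites for a heatmap
#'
#' Rows (metabolites) are z-scored across samples; both rows and columns are
#' clustered with complete-linkage hierarchical clustering on Euclidean
#' distance, and the row dendrogram is cut into `k` clusters (default 4).
#' Leaf ordering and cluster labels are deterministic for a given input.
#'
#' @param values Matrix with metabolites in rows and samples in columns
#'   (adjusted log concentrations of the significant metabolites).
#' @param k Number of metabolite clusters.
#' @return A `cluster_heatmap`: list with `clusters` (named integer),
#'   `row_order`, `col_order`, `scaled` matrix, `row_tree`, `col_tree`.
#' @export
rfi_cluster_heatmap <- function(values, k = 4) {
  assert_that(is.matrix(values) && nrow(values) >= 1, "values must be a matrix")
  assert_that(k >= 1 && k <= nrow(values),
              "k must be between 1 and the number of metabolites")
  Z <- t(scale(t(values)))
  Z[is.na(Z)] <- 0     # constant rows carry no profile
  row_tree <- stats::hclust(stats::dist(Z), method = "complete")
  col_tree <- stats::hclust(stats::dist(t(Z)), method = "complete")
  clusters <- stats::cutree(row_tree, k = k)
  structure(list(clusters = clusters, row_order = row_tree$order,
                 col_order = col_tree$order, scaled = Z,
                 row_tree = row_tree, col_tree = col_tree, k = k),
            class = "cluster_heatmap")
}

#' Plot a clustered heatmap (requires pheatmap)
#'
#' @param x A `cluster_heatmap`.
#' @param filename Optional output file passed to pheatmap.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @export
plot_cluster_heatmap <- function(x, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap is required for plotting", call. = FALSE)
  ann <- data.frame(cluster = factor(x$clusters),
                    row.names = rownames(x$scaled))
  pheatmap::pheatmap(x$scaled, clustering_method = "complete",
                     annotation_row = ann, filename = filename, ...)
}
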