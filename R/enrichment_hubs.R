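## Pathway over-representation (hypergeometric) over user-supplied GMT
## annotations, and compound-gene bipartite network construction with hub
## calling.  These replace hosted web services with local, auditable
## statistics; the pathway content itself is an input, not a claim.

#' Load a pathway database from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.  Duplicate members
#' within a line are collapsed.
#'
#' @param path GMT file.
#' @return A `pathway_db`: list with `sets` (named list of compound-ID
#'   vectors), `description`, `source`.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 fields", call. = FALSE)
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, description = desc, source = basename(path)),
            class = "pathway_db")
}

#' Write a pathway database to GMT
#' @param db A `pathway_db`.
#' @param path Output file.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, if (!is.null(db$description[nm]) && !is.na(db$description[nm]))
      db$description[nm] else "NA", db$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db (%s): %d pathways, sizes %d-%d\n", x$source,
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Hypergeometric pathway over-representation analysis
#'
#' Pathway members are first restricted to the measured universe (the
#' annotated metabolites that survived the group's filter); pathways with no
#' member in the universe are skipped.  For each pathway of (restricted)
#' size K, with n selected compounds of which k overlap the pathway in a
#' universe of size N, the upper-tail hypergeometric probability
#' `P(X >= k)` is the enrichment p-value; Benjamini-Hochberg q-values are
#' computed across the tested pathways.
#'
#' @param selected Character vector of selected compound IDs (must be a
#'   subset of `universe`).
#' @param universe Character vector of measurable compound IDs.
#' @param db A `pathway_db`.
#' @return An `ora_table` data.frame: pathway, description, N, K, n, k,
#'   p_value, q_value, overlap (semicolon-joined IDs), ordered by p.
#' @export
ora_hypergeometric <- function(selected, universe, db) {
  selected <- unique(selected); universe <- unique(universe)
  extra <- setdiff(selected, universe)
  assert_that(length(extra) == 0,
              paste("selected compounds outside the universe:",
                    paste(utils::head(extra, 5), collapse = ", ")))
  N <- length(universe); n <- length(selected)
  rows <- list()
  for (nm in names(db$sets)) {
    members <- intersect(db$sets[[nm]], universe)
    K <- length(members)
    if (K == 0) next
    ov <- intersect(selected, members)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(
      pathway = nm,
      description = if (!is.na(db$description[nm])) db$description[nm] else "",
      N = N, K = K, n = n, k = k, p_value = p,
      overlap = paste(sort(ov), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(pathway = character(), description = character(),
                  N = integer(), K = integer(), n = integer(), k = integer(),
                  p_value = numeric(), overlap = character())
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_table", "data.frame")
  out
}

#' Build a compound-gene bipartite network
#'
#' Connects candidate compounds to genes via a user-supplied mapping table.
#' Candidates absent from the mapping are retained as isolated nodes
#' (degree 0) and flagged.
#'
#' @param candidates Character vector of compound IDs.
#' @param mapping Data.frame with columns `compound_id`, `gene_id`
#'   (duplicate rows collapsed).
#' @return A `compound_gene_network`: list with `edges` (data.frame),
#'   `compound_degree` (named integer incl. isolated candidates),
#'   `gene_degree`, `graph` (igraph bipartite object), `unmapped`.
#' @export
build_compound_gene_network <- function(candidates, mapping) {
  assert_that(is.data.frame(mapping) &&
                all(c("compound_id", "gene_id") %in% names(mapping)),
              "mapping needs compound_id and gene_id columns")
  assert_that(nrow(mapping) > 0, "empty mapping")
  candidates <- unique(candidates)
  edges <- unique(mapping[mapping$compound_id %in% candidates,
                          c("compound_id", "gene_id")])
  rownames(edges) <- NULL
  cdeg <- table(factor(edges$compound_id, levels = candidates))
  cdeg <- stats::setNames(as.integer(cdeg), names(cdeg))
  gdeg <- sort(table(edges$gene_id), decreasing = TRUE)
  unmapped <- candidates[cdeg[candidates] == 0]
  g <- igraph::make_empty_graph(directed = FALSE)
  verts <- c(candidates, unique(edges$gene_id))
  g <- igraph::add_vertices(g, length(verts), name = verts,
                            type = c(rep(TRUE, length(candidates)),
                                     rep(FALSE, length(unique(edges$gene_id)))))
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(match(edges$compound_id, verts),
                                    match(edges$gene_id, verts)))
  structure(list(edges = edges, compound_degree = cdeg,
                 gene_degree = stats::setNames(as.integer(gdeg), names(gdeg)),
                 graph = g, unmapped = unmapped),
            class = "compound_gene_network")
}

#' @export
print.compound_gene_network <- function(x, ...) {
  cat(sprintf("compound_gene_network: %d compounds (%d unmapped), %d genes, %d edges\n",
              length(x$compound_degree), length(x$unmapped),
              length(x$gene_degree), nrow(x$edges)))
  invisible(x)
}

#' Export a compound-gene network
#'
#' Writes the edge list as TSV and, optionally, the graph as GraphML.
#'
#' @param network A `compound_gene_network`.
#' @param edge_path TSV output path.
#' @param graphml_path Optional GraphML output path.
#' @export
write_compound_gene_network <- function(network, edge_path,
                                        graphml_path = NULL) {
  write_tsv_strict(network$edges, edge_path)
  if (!is.null(graphml_path))
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  invisible(edge_path)
}

#' Find hub metabolites
#'
#' A hub is a compound connected to more than one gene in the bipartite
#' network.  Hubs are returned sorted by degree (descending), ties broken
#' by compound ID.
#'
#' @param network A `compound_gene_network`.
#' @param min_degree Minimum gene degree to qualify (default 2).
#' @return Data.frame: compound_id, degree.
#' @export
find_hubs <- function(network, min_degree = 2) {
  deg <- network$compound_degree
  deg <- deg[deg >= min_degree]
  if (length(deg) == 0)
    return(data.frame(compound_id = character(), degree = integer()))
  ord <- order(-deg, names(deg))
  data.frame(compound_id = names(deg)[ord], degree = unname(deg[ord]),
             stringsAsFactors = FALSE)
}

#' Shared hubs across analysis groups
#'
#' @param hub_lists Named list (>= 2 groups) of hub data.frames from
#'   [find_hubs()] or character vectors of compound IDs.
#' @return List: `pairwise` (list of intersections keyed
#'   `"<g1>_x_<g2>"`), `global` (IDs present in every group), `by_hub`
#'   (data.frame compound_id, groups, n_groups for hubs in >= 2 groups).
#' @export
shared_hubs <- function(hub_lists) {
  assert_that(length(hub_lists) >= 2, "need at least 2 groups")
  ids <- lapply(hub_lists, function(h)
    if (is.data.frame(h)) h$compound_id else as.character(h))
  keys <- names(ids)
  pairwise <- list()
  cmb <- utils::combn(keys, 2)
  for (i in seq_len(ncol(cmb)))
    pairwise[[paste(cmb[1, i], cmb[2, i], sep = "_x_")]] <-
      sort(intersect(ids[[cmb[1, i]]], ids[[cmb[2, i]]]))
  global <- Reduce(intersect, ids)
  all_ids <- sort(unique(unlist(ids)))
  grp <- vapply(all_ids, function(a)
    paste(keys[vapply(ids, function(s) a %in% s, logical(1))],
          collapse = ";"), character(1))
  ng <- lengths(regmatches(grp, gregexpr(";", grp))) + 1L
  by_hub <- data.frame(compound_id = all_ids, groups = unname(grp),
                       n_groups = unname(ng), stringsAsFactors = FALSE)
  by_hub <- by_hub[by_hub$n_groups >= 2, , drop = FALSE]
  rownames(by_hub) <- NULL
  list(pairwise = pairwise, global = sort(global), by_hub = by_hub)
}
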