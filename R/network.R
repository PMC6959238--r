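## Signed weighted metabolite co-abundance network.
##
## Spearman correlation -> signed soft-threshold adjacency ((1+r)/2)^beta
## -> scale-free fit / beta selection -> topological overlap -> average-
## linkage clustering with an adaptive tree cut -> module eigen-profiles ->
## module-trait screening.  All steps are authored here so their numerics
## are auditable and covered by brute-force oracles in the test suite.

## Conventional module color sequence (largest module first; "grey" is the
## unassigned background label).
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "skyblue", "saddlebrown",
                   "steelblue", "paleturquoise", "violet", "darkolivegreen",
                   "darkmagenta")

#' Spearman correlation matrix of metabolites
#'
#' Symmetric rank correlation (average ranks for ties) across samples, with
#' unit diagonal.  Constant columns cannot be ranked meaningfully and are
#' excluded, with their IDs attached as attribute `excluded`.
#'
#' @param adjusted Samples x metabolites matrix (`adjusted_matrix` or plain).
#' @return Metabolite x metabolite correlation matrix.
#' @export
spearman_matrix <- function(adjusted) {
  M <- unclass(adjusted)
  assert_that(nrow(M) >= 4, "Spearman matrix needs at least 4 samples")
  sds <- apply(M, 2, stats::sd)
  excluded <- colnames(M)[sds == 0]
  if (length(excluded) > 0) {
    log_stage("network", length(excluded), " constant metabolites excluded")
    M <- M[, sds > 0, drop = FALSE]
  }
  R <- stats::cor(M, method = "spearman")
  diag(R) <- 1
  attr(R, "excluded") <- excluded
  R
}

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + r_ij) / 2)^beta`: correlations are mapped from \[-1, 1\] to
#' \[0, 1\] preserving sign information, then raised to the soft-threshold
#' power so weak connections decay toward 0.  Diagonal is set to 1.
#'
#' @param corr Symmetric correlation matrix.
#' @param beta Soft-threshold power, >= 1.
#' @return An adjacency matrix in \[0, 1\] with attribute `beta`.
#' @export
signed_adjacency <- function(corr, beta) {
  assert_that(beta >= 1, "beta must be >= 1")
  A <- ((1 + corr) / 2)^beta
  diag(A) <- 1
  attr(A, "beta") <- beta
  A
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Connectivity `k_i = sum_{j != i} a_ij` is binned into `n_bins`
#' equal-width bins; OLS of log10(bin frequency) on log10(mean k per bin)
#' gives R^2, signed by minus the slope's sign so that scale-free-like
#' (decreasing) degree distributions score positively.  Degenerate inputs
#' that collapse to fewer than 3 usable bins return 0 by convention.
#'
#' @param adjacency Adjacency matrix.
#' @param n_bins Number of connectivity bins (default 10).
#' @return List: `r_squared` (signed), `slope`, `mean_connectivity`, `n_bins_used`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  assert_that(nrow(adjacency) >= 20, "scale-free fit needs >= 20 nodes")
  k <- rowSums(adjacency) - diag(adjacency)
  if (diff(range(k)) == 0)
    return(list(r_squared = 0, slope = NA_real_,
                mean_connectivity = mean(k), n_bins_used = 1L))
  bin <- cut(k, n_bins, include.lowest = TRUE)
  freq <- as.vector(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  use <- freq > 0 & kmean > 0
  x <- log10(kmean[use]); y <- log10(freq[use])
  if (length(x) < 3 || stats::sd(x) == 0)
    return(list(r_squared = 0, slope = NA_real_,
                mean_connectivity = mean(k), n_bins_used = sum(use)))
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(r_squared = unname(r2 * -sign(slope)), slope = unname(slope),
       mean_connectivity = mean(k), n_bins_used = length(x))
}

#' Choose the soft-threshold power
#'
#' Scans candidate powers (default 12 to 22) and returns the smallest one
#' whose signed scale-free R^2 exceeds `r2_min` (default 0.8).  If none
#' qualifies, the power with maximal signed R^2 is returned with
#' `criterion_met = FALSE`.
#'
#' @param corr Correlation matrix.
#' @param scan Candidate powers.
#' @param r2_min Required signed R^2.
#' @return List (class `beta_choice`): `beta`, `criterion_met`, `scan`
#'   (data.frame beta, r_squared, mean_connectivity).
#' @export
pick_beta <- function(corr, scan = 12:22, r2_min = 0.8) {
  assert_that(length(scan) >= 1, "empty beta scan")
  rows <- lapply(scan, function(b) {
    sf <- scale_free_fit(signed_adjacency(corr, b))
    data.frame(beta = b, r_squared = sf$r_squared,
               mean_connectivity = sf$mean_connectivity)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$r_squared > r2_min)
  if (length(ok) > 0) {
    beta <- tab$beta[ok[1]]
    met <- TRUE
  } else {
    beta <- tab$beta[which.max(tab$r_squared)]
    met <- FALSE
  }
  structure(list(beta = beta, criterion_met = met, scan = tab),
            class = "beta_choice")
}

#' @export
print.beta_choice <- function(x, ...) {
  cat(sprintf("beta = %d (scale-free criterion %s)\n", x$beta,
              if (x$criterion_met) "met" else "NOT met; argmax fallback"))
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' for i != j, with connectivity k excluding the diagonal; `TOM_ii = 1`.
#' Two metabolites overlap strongly when they are directly connected and
#' share their neighborhoods.
#'
#' @param adjacency Adjacency matrix in \[0, 1\].
#' @return TOM matrix in \[0, 1\].
#' @export
tom <- function(adjacency) {
  A <- adjacency
  diag(A) <- 1
  k <- rowSums(A) - 1
  A2 <- A %*% A
  num <- A2 - A          # = sum_{u != i,j} a_iu a_uj + a_ij  (diag(A) = 1)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - A
  TOM <- num / denom
  diag(TOM) <- 1
  TOM[denom <= 0] <- 1   # only reachable when a_ij = 1 and k = 0
  dimnames(TOM) <- dimnames(adjacency)
  TOM
}

#' Cut a dendrogram into co-abundance modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by an adaptive tree cut: merges above the configured quantile of
#' merge heights (default 0.99) are always split, and below that height a
#' branch is further decomposed whenever both of its children hold at least
#' `min_module_size` leaves -- this peels apart loosely joined branches
#' (e.g. background noise agglomerated onto a tight module) while leaving
#' homogeneous modules, whose top merges peel off single leaves, intact.
#' Branches smaller than `min_module_size` end up in the unassigned "grey"
#' background, as do candidate branches that fail a density check: a real
#' module must be denser inside than toward the rest of the network (mean
#' within-branch TOM at least `min_density_ratio` times the mean TOM between
#' the branch and all other metabolites); loose agglomerations of background
#' noise fail this and stay grey.  Modules are labeled by descending size
#' with the conventional color sequence; size ties are broken by the lowest
#' member index, so labeling is deterministic.
#'
#' @param tom_matrix TOM (or any similarity in \[0, 1\]).
#' @param min_module_size Minimum metabolites per module (default 30).
#' @param cut_quantile Quantile of merge heights used as cut height
#'   (default 0.99).
#' @param min_density_ratio Required ratio of mean within-branch TOM to mean
#'   branch-to-rest TOM (default 10).
#' @return A `module_partition`: list with `colors` (named character),
#'   `sizes`, `dendrogram` (hclust), `cut_height`.
#' @export
cluster_modules <- function(tom_matrix, min_module_size = 30,
                            cut_quantile = 0.99, min_density_ratio = 10) {
  p <- nrow(tom_matrix)
  ids <- colnames(tom_matrix)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  tree <- stats::hclust(stats::as.dist(1 - tom_matrix), method = "average")
  if (p < min_module_size) {
    warning("fewer metabolites than min_module_size; all grey", call. = FALSE)
    return(structure(list(colors = stats::setNames(rep("grey", p), ids),
                          sizes = c(grey = p), dendrogram = tree,
                          cut_height = NA_real_),
                     class = "module_partition"))
  }
  h <- stats::quantile(tree$height, cut_quantile)

  ## leaf counts per internal node
  n_nodes <- nrow(tree$merge)
  count <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    kids <- tree$merge[i, ]
    count[i] <- sum(ifelse(kids < 0, 1L, count[pmax(kids, 1L)]))
  }
  leaves_under <- function(node) {
    if (node < 0) return(-node)
    out <- integer(0); stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      kids <- tree$merge[nd, ]
      for (kd in kids) {
        if (kd < 0) out <- c(out, -kd) else stack <- c(stack, kd)
      }
    }
    out
  }
  node_size <- function(node) if (node < 0) 1L else count[node]
  ## recursive branch decomposition from the root
  clusters <- list()
  stack <- n_nodes
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (nd < 0) { clusters[[length(clusters) + 1L]] <- -nd; next }
    kids <- tree$merge[nd, ]
    s1 <- node_size(kids[1]); s2 <- node_size(kids[2])
    if (tree$height[nd] > h ||
        (s1 >= min_module_size && s2 >= min_module_size)) {
      stack <- c(stack, kids)
    } else {
      clusters[[length(clusters) + 1L]] <- leaves_under(nd)
    }
  }
  sizes <- lengths(clusters)
  keep <- which(sizes >= min_module_size)
  if (length(keep) > 0) {
    dense <- vapply(keep, function(ci) {
      m <- clusters[[ci]]
      if (length(m) == p) return(TRUE)   # single all-covering module
      sub <- tom_matrix[m, m]
      w <- (sum(sub) - length(m)) / (length(m) * (length(m) - 1))
      b <- mean(tom_matrix[m, -m])
      is.finite(w) && is.finite(b) && b > 0 && w / b >= min_density_ratio
    }, logical(1))
    keep <- keep[dense]
  }
  lab <- rep(0L, p)
  if (length(keep) > 0) {
    ## order surviving branches by size desc, ties by lowest member index
    firsts <- vapply(clusters[keep], min, integer(1))
    ord <- keep[order(-sizes[keep], firsts)]
    for (i in seq_along(ord)) lab[clusters[[ord[i]]]] <- i
  }
  palette <- c(MODULE_COLORS, paste0("module", seq_len(p)))
  colors <- rep("grey", p)
  colors[lab > 0L] <- palette[lab[lab > 0L]]
  colors <- stats::setNames(colors, ids)
  structure(list(colors = colors,
                 sizes = sort(table(colors[colors != "grey"]),
                              decreasing = TRUE),
                 dendrogram = tree, cut_height = unname(h)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d metabolites, %d modules (+%d grey)\n",
              length(x$colors), length(x$sizes), sum(x$colors == "grey")))
  if (length(x$sizes) > 0)
    print(utils::head(x$sizes, 10))
  invisible(x)
}

#' Export a module dendrogram in Newick format
#'
#' @param partition A `module_partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(partition, path) {
  hc <- partition$dendrogram
  lab <- hc$labels
  if (is.null(lab)) lab <- paste0("V", seq_along(partition$colors))
  node <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%g", lab[-i], parent_h))
    kids <- hc$merge[i, ]
    sprintf("(%s,%s):%g", node(kids[1], hc$height[i]),
            node(kids[2], hc$height[i]),
            max(parent_h - hc$height[i], 0))
  }
  n <- length(lab)
  root <- nrow(hc$merge)
  txt <- paste0("(", node(hc$merge[root, 1], hc$height[root]), ",",
                node(hc$merge[root, 2], hc$height[root]), ");")
  writeLines(txt, path)
  invisible(path)
}

#' Module eigen-profiles (eigen-metabolites)
#'
#' Per module, columns are standardized (mean 0, sd 1) and the first
#' principal-component score vector, scaled to unit variance, summarizes the
#' module across samples.  The sign is flipped when the mean correlation
#' with the module members is negative, so the eigen-profile points "along"
#' its module.  Single-member modules return the standardized member itself,
#' flagged.
#'
#' @param adjusted Samples x metabolites matrix.
#' @param partition A `module_partition` (grey is skipped).
#' @return An `eigen_table`: list with `scores` (samples x modules matrix),
#'   `var_explained` (fraction per module), `flagged` (single-member
#'   modules).
#' @export
module_eigenmetabolites <- function(adjusted, partition) {
  M <- unclass(adjusted)
  mods <- names(partition$sizes)
  scores <- matrix(NA_real_, nrow(M), length(mods),
                   dimnames = list(rownames(M), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  flagged <- character(0)
  n <- nrow(M)
  for (mod in mods) {
    members <- names(partition$colors)[partition$colors == mod]
    members <- intersect(members, colnames(M))
    Xs <- scale(M[, members, drop = FALSE])
    if (length(members) == 1) {
      scores[, mod] <- Xs[, 1]
      ve[mod] <- 1
      flagged <- c(flagged, mod)
      next
    }
    sv <- svd(Xs, nu = 1, nv = 0)
    me <- sv$u[, 1]
    me <- me / stats::sd(me)
    if (mean(stats::cor(me, Xs)) < 0) me <- -me
    scores[, mod] <- me
    ve[mod] <- sv$d[1]^2 / ((n - 1) * length(members))
  }
  structure(list(scores = scores, var_explained = ve, flagged = flagged),
            class = "eigen_table")
}

#' Module-trait correlation screening
#'
#' Spearman correlation between each module eigen-profile and each
#' phenotype, with the t-approximation p-value on n - 2 degrees of freedom.
#' A module is selected for a trait when `|r| >= cor_min` and
#' `p <= p_max` (defaults 0.2 and 0.1); negative correlations qualify, as
#' both directions of co-variation are biologically interpretable.
#'
#' @param eigen An `eigen_table`.
#' @param phenotypes A `phenotype_table`.
#' @param metadata Sample metadata mapping eigen-profile samples to animals.
#' @param traits Traits to screen (default all five).
#' @param cor_min,p_max Selection thresholds.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `module_trait_table` data.frame: module, trait, r, p_value,
#'   selected, n.
#' @export
module_trait_correlation <- function(eigen, phenotypes, metadata,
                                     traits = TRAITS, cor_min = 0.2,
                                     p_max = 0.1,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  md <- metadata[match(rownames(eigen$scores), metadata$sample_id), ,
                 drop = FALSE]
  rows <- list()
  for (mod in colnames(eigen$scores)) {
    me <- eigen$scores[, mod]
    for (tr in traits) {
      y <- phenotypes[[tr]][match(md$animal_id, phenotypes$animal_id)]
      ok <- !is.na(y) & !is.na(me)
      n <- sum(ok)
      assert_that(n >= 5, "fewer than 5 paired observations")
      r <- stats::cor(me[ok], y[ok], method = method)
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      pv <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
      rows[[paste(mod, tr)]] <- data.frame(
        module = mod, trait = tr, r = r, p_value = pv,
        selected = abs(r) >= cor_min && pv <= p_max, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("module_trait_table", "data.frame")
  out
}

#' Run the full network stage on an adjusted matrix
#'
#' Convenience wrapper: Spearman correlation, beta selection, adjacency,
#' TOM, module detection, eigen-profiles.
#'
#' @param adjusted Samples x metabolites matrix.
#' @param beta_scan Candidate soft-threshold powers.
#' @param r2_min Scale-free R^2 requirement.
#' @param min_module_size,cut_quantile Passed to [cluster_modules()].
#' @return List (class `network_model`): `corr`, `beta` (a `beta_choice`),
#'   `adjacency`, `tom`, `partition`, `eigen`.
#' @export
build_network <- function(adjusted, beta_scan = 12:22, r2_min = 0.8,
                          min_module_size = 30, cut_quantile = 0.99,
                          min_density_ratio = 10) {
  R <- spearman_matrix(adjusted)
  bc <- pick_beta(R, beta_scan, r2_min)
  A <- signed_adjacency(R, bc$beta)
  TOM <- tom(A)
  part <- cluster_modules(TOM, min_module_size, cut_quantile,
                          min_density_ratio)
  keep <- setdiff(colnames(unclass(adjusted)), attr(R, "excluded"))
  eig <- module_eigenmetabolites(unclass(adjusted)[, keep, drop = FALSE], part)
  structure(list(corr = R, beta = bc, adjacency = A, tom = TOM,
                 partition = part, eigen = eig),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d metabolites, beta = %d, %d modules\n",
              nrow(x$corr), x$beta$beta, length(x$partition$sizes)))
  invisible(x)
}
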