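random_adjacency <- function(p, seed) {
  set.seed(seed)
  r <- matrix(stats::runif(p * p), p)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(paste0("M", 1:p), paste0("M", 1:p))
  r
}

test_that("Spearman matrix honors rank invariance and hand examples", {
  set.seed(1)
  x <- stats::rnorm(20)
  M <- cbind(a = x, b = exp(2 * x), c = stats::rnorm(20))
  rownames(M) <- paste0("S", 1:20)
  R <- spearman_matrix(M)
  expect_equal(R["a", "a"], 1)
  expect_equal(R["a", "b"], 1, tolerance = 1e-12)   # monotone transform
  M2 <- cbind(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3),
              z = c(5, 6, 7, 8))
  rownames(M2) <- paste0("S", 1:4)
  expect_equal(spearman_matrix(M2)["x", "y"], 0.6, tolerance = 1e-12)
  ## constant columns excluded, not fatal
  M3 <- cbind(M, const = 1)
  expect_equal(attr(spearman_matrix(M3), "excluded"), "const")
  expect_error(spearman_matrix(M2[1:3, ]), "4 samples")
})

test_that("signed adjacency maps correlation into [0,1] as ((1+r)/2)^beta", {
  r <- matrix(c(1, 1, -1, 0, 1, 1, -1, 0, -1, -1, 1, 0, 0, 0, 0, 1), 4)
  a <- signed_adjacency(r, 12)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 4], 0.5^12)
  expect_equal(a[1, 4], 2.44140625e-4)
  expect_error(signed_adjacency(r, 0.5), "beta")
  ## raising beta never increases an off-diagonal entry
  R <- stats::cov2cor(crossprod(matrix(stats::rnorm(400), 20)))
  for (b in c(12, 14, 18)) {
    a1 <- signed_adjacency(R, b)
    a2 <- signed_adjacency(R, b + 1)
    expect_true(all(a2[upper.tri(a2)] <= a1[upper.tri(a1)] + 1e-15))
  }
})

test_that("scale-free fit matches an independent regression oracle", {
  sf_oracle <- function(adjacency, n_bins = 10) {
    k <- rowSums(adjacency) - diag(adjacency)
    bin <- cut(k, n_bins, include.lowest = TRUE)
    freq <- tapply(k, bin, length) / length(k)
    km <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0 & km > 0
    x <- log10(km[ok]); y <- log10(freq[ok])
    fit <- stats::lm(y ~ x)
    unname(summary(fit)$r.squared * -sign(stats::coef(fit)[2]))
  }
  for (s in 1:5) {
    a <- random_adjacency(40, s)^6
    diag(a) <- 1
    got <- scale_free_fit(a)
    expect_equal(got$r_squared, sf_oracle(a), tolerance = 1e-10)
  }
  expect_error(scale_free_fit(random_adjacency(10, 1)), "20 nodes")
  ## all-equal connectivity resolves to 0 by convention, not an error
  ones <- matrix(1, 25, 25)
  expect_equal(scale_free_fit(ones)$r_squared, 0)
})

test_that("scale-free sign convention penalizes increasing degree distributions", {
  ## hub-like decreasing degree distribution: positive signed R^2
  set.seed(4)
  p <- 60
  w <- sort(stats::rexp(p, 1), decreasing = TRUE)
  a <- outer(w, w); a <- a / max(a); diag(a) <- 1
  dec <- scale_free_fit(a)
  expect_gt(dec$r_squared, 0)
  expect_lt(dec$slope, 0)
})

test_that("beta selection defaults to the 12..22 scan with argmax fallback", {
  expect_equal(eval(formals(pick_beta)$scan), 12:22)
  bench <- network_benchmark()
  bc <- bench$net$beta
  expect_true(bc$criterion_met)
  expect_true(bc$beta %in% 12:22)
  expect_equal(bc$beta, min(bc$scan$beta[bc$scan$r_squared > 0.8]))
  ## small noise matrix: nothing qualifies, argmax returned with flag
  set.seed(8)
  M <- matrix(stats::rnorm(25 * 30), 25, 30,
              dimnames = list(paste0("S", 1:25), paste0("M", 1:30)))
  bc0 <- pick_beta(spearman_matrix(M))
  expect_false(bc0$criterion_met)
  expect_equal(bc0$beta, bc0$scan$beta[which.max(bc0$scan$r_squared)])
})

test_that("topological overlap matches hand-worked and limiting cases", {
  a05 <- matrix(0.5, 3, 3); diag(a05) <- 1
  t05 <- tom(a05)
  expect_equal(t05[1, 2], 0.5, tolerance = 1e-12)  # (0.25+0.5)/(1+1-0.5)
  full <- matrix(1, 4, 4)
  expect_true(all(tom(full) == 1))
  empty <- diag(4)
  expect_equal(unique(tom(empty)[upper.tri(empty)]), 0)
})

test_that("TOM equals the triple-loop brute-force oracle", {
  tom_oracle <- function(A) {
    p <- nrow(A); diag(A) <- 1
    k <- rowSums(A) - 1
    out <- diag(p)
    for (i in 1:p) for (j in 1:p) if (i != j) {
      s <- 0
      for (u in 1:p) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
      out[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
    out
  }
  for (s in 1:5) {
    A <- signed_adjacency(2 * random_adjacency(15, s) - 1, 6)
    got <- tom(A)
    expect_lt(max(abs(got - tom_oracle(A))), 1e-10)
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
    expect_equal(got, t(got), tolerance = 1e-12)
  }
})

test_that("module detection is deterministic and permutation-equivariant", {
  bench <- network_benchmark()
  TOM <- bench$net$tom
  p1 <- cluster_modules(TOM)
  p2 <- cluster_modules(TOM)
  expect_identical(p1$colors, p2$colors)
  set.seed(3)
  perm <- sample(ncol(TOM))
  p3 <- cluster_modules(TOM[perm, perm])
  expect_equal(adjusted_rand_index(p1$colors[colnames(TOM)[perm]],
                                   p3$colors), 1)
  tiny <- TOM[1:10, 1:10]
  expect_warning(ptiny <- cluster_modules(tiny, min_module_size = 30),
                 "grey")
  expect_true(all(ptiny$colors == "grey"))
})

test_that("pure-noise data stays almost entirely unassigned", {
  cfg <- simulation_config(n_animals_per_breed = c(A = 50),
                           n_metabolites = 300, module_sizes = integer(0),
                           n_minor_factors = 0, n_trait_metabolites = 0,
                           low_var_frac = 0, loading = 0,
                           breed_effect_sd = 0, batch_effect_sd = 0,
                           pen_effect_sd = 0, seed = 3)
  st <- simulate_study(cfg)
  net <- build_network(log(st$intensities$values))
  expect_gte(mean(net$partition$colors == "grey"), 0.9)
})

test_that("eigen-profiles match a power-iteration oracle and flag singletons", {
  set.seed(5)
  M <- matrix(stats::rnorm(5 * 3), 5, 3,
              dimnames = list(paste0("S", 1:5), paste0("M", 1:3)))
  part <- structure(list(colors = stats::setNames(rep("blue", 3),
                                                  colnames(M)),
                         sizes = c(blue = 3)), class = "module_partition")
  eig <- module_eigenmetabolites(M, part)
  ## oracle: power iteration on the correlation matrix of standardized cols
  Xs <- scale(M)
  C <- crossprod(Xs) / (nrow(M) - 1)
  v <- rep(1, 3)
  for (i in 1:500) { v <- C %*% v; v <- v / sqrt(sum(v^2)) }
  me_oracle <- as.vector(Xs %*% v)
  me_oracle <- me_oracle / stats::sd(me_oracle)
  if (mean(stats::cor(me_oracle, Xs)) < 0) me_oracle <- -me_oracle
  expect_equal(unname(eig$scores[, "blue"]), me_oracle, tolerance = 1e-8)
  ## two identical standardized profiles: ME is that profile, 100% variance
  M2 <- cbind(a = M[, 1], b = 2 * M[, 1] + 1, c = M[, 2])
  rownames(M2) <- rownames(M)
  part2 <- structure(list(colors = stats::setNames(c("red", "red", "grey"),
                                                   colnames(M2)),
                          sizes = c(red = 2)), class = "module_partition")
  eig2 <- module_eigenmetabolites(M2, part2)
  expect_equal(unname(abs(stats::cor(eig2$scores[, "red"], M2[, "a"]))), 1,
               tolerance = 1e-10)
  expect_equal(unname(eig2$var_explained["red"]), 1, tolerance = 1e-10)
  part3 <- structure(list(colors = stats::setNames(c("red", "grey", "grey"),
                                                   colnames(M2)),
                          sizes = c(red = 1)), class = "module_partition")
  expect_equal(module_eigenmetabolites(M2, part3)$flagged, "red")
})

test_that("module-trait screening applies |r| >= 0.2 and p <= 0.1", {
  set.seed(12)
  n <- 60
  me <- stats::rnorm(n)
  scores <- cbind(assoc = me, anti = stats::rnorm(n), null = stats::rnorm(n))
  rownames(scores) <- sprintf("A%03d_T1", 1:n)
  eig <- structure(list(scores = scores), class = "eigen_table")
  meta <- data.frame(sample_id = rownames(scores),
                     animal_id = sprintf("A%03d", 1:n))
  ph <- data.frame(animal_id = meta$animal_id,
                   FE = 0.6 * me + stats::rnorm(n, sd = 1),
                   RFI = -0.6 * me + stats::rnorm(n, sd = 1),
                   EDG = stats::rnorm(n))
  mt <- module_trait_correlation(eig, ph, meta, traits = c("FE", "RFI", "EDG"))
  sel <- function(mod, tr) mt$selected[mt$module == mod & mt$trait == tr]
  expect_true(sel("assoc", "FE"))
  expect_true(sel("assoc", "RFI"))     # negative correlations qualify
  expect_false(sel("null", "EDG"))
  ## r agrees with base Spearman, p with the t-approximation
  row <- mt[mt$module == "assoc" & mt$trait == "FE", ]
  r0 <- stats::cor(me, ph$FE, method = "spearman")
  expect_equal(row$r, r0, tolerance = 1e-12)
  t0 <- r0 * sqrt((n - 2) / (1 - r0^2))
  expect_equal(row$p_value, 2 * stats::pt(-abs(t0), n - 2), tolerance = 1e-12)
  expect_equal(row$selected, abs(row$r) >= 0.2 && row$p_value <= 0.1)
})

test_that("dendrogram export writes parseable Newick", {
  bench <- network_benchmark()
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(bench$net$partition, path)
  tree <- ape::read.tree(path)
  expect_equal(ape::Ntip(tree), ncol(bench$net$tom))
  expect_setequal(tree$tip.label, colnames(bench$net$tom))
})
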