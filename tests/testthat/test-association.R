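make_adjusted <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("A%03d_T1", 1:n), sprintf("M%03d", 1:p)))
  structure(M, class = c("adjusted_matrix", "matrix", "array"))
}

make_meta <- function(n, age = NULL) {
  if (is.null(age)) age <- 70 + seq_len(n) %% 15
  data.frame(sample_id = sprintf("A%03d_T1", 1:n),
             animal_id = sprintf("A%03d", 1:n), breed = "D", batch = "B1",
             pen = "P1", time_point = 1L, sampling_age = age,
             stringsAsFactors = FALSE)
}

test_that("a noiseless linear trait is fit exactly", {
  n <- 30
  adj <- make_adjusted(n, 3, seed = 2)
  meta <- make_meta(n)
  ph <- data.frame(animal_id = sprintf("A%03d", 1:n),
                   FE = 2 * adj[, 2], stringsAsFactors = FALSE)
  at <- associate_trait(adj, ph, "FE", meta)
  row <- at[at$metabolite_id == "M002", ]
  expect_equal(row$slope, 2, tolerance = 1e-8)
  expect_lte(row$p_value, 1e-12)
  expect_equal(unique(at$n_used), n)
})

test_that("age-collinear metabolites are flagged, tiny groups rejected", {
  n <- 30
  meta <- make_meta(n)
  adj <- make_adjusted(n, 2, seed = 3)
  adj[, 1] <- meta$sampling_age * 0.1   # perfectly collinear with age
  ph <- data.frame(animal_id = meta$animal_id, FE = stats::rnorm(n))
  at <- associate_trait(adj, ph, "FE", meta)
  expect_true(at$flagged[at$metabolite_id == "M001"])
  expect_true(is.na(at$p_value[at$metabolite_id == "M001"]))
  expect_error(associate_trait(make_adjusted(4, 2), ph[1:4, ], "FE",
                               make_meta(4)), "fewer than 5")
  expect_error(associate_trait(adj, ph, "WEIGHT", meta), "unknown trait")
})

test_that("null phenotypes give calibrated per-metabolite tests", {
  st <- simulate_null_study(null_config(31))
  at <- assoc_tp1(st, "FE")
  rate <- mean(at$p_value <= 0.05)
  ## 200 independent nulls: 95% binomial band around 0.05 is ~ [0.02, 0.08]
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
  expect_gt(ks_uniformity_test(at$p_value)$p_value, 0.001)
})

test_that("planted trait effects are detected with good power", {
  cfg <- null_config(32)
  cfg$n_trait_metabolites <- 20L
  cfg$trait_effect <- 3
  st <- simulate_study(cfg)
  at <- assoc_tp1(st, "TDG")
  hit <- at$p_value[at$metabolite_id %in% st$truth$trait_metabolites]
  expect_gte(mean(hit <= 0.05), 0.5)
})

test_that("KS uniformity statistic matches closed-form cases", {
  one <- ks_uniformity_test(0.5)
  expect_equal(one$statistic, 0.5, tolerance = 1e-12)
  for (n in c(9, 19, 99)) {
    grid <- seq_len(n) / (n + 1)
    expect_equal(ks_uniformity_test(grid)$statistic, 1 / (n + 1),
                 tolerance = 1e-12)
  }
  expect_error(ks_uniformity_test(numeric(0)), "no finite")
  expect_error(ks_uniformity_test(c(0.5, 2)), "outside")
})

test_that("BH q-values match the step-up enumeration oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    q_sorted <- p[ord] * m / seq_len(m)
    q_sorted <- rev(cummin(rev(q_sorted)))   # step-up: q_i = min_{j>=i} p_(j) m/j
    pmin(q_sorted, 1)[order(ord)]
  }
  set.seed(99)
  for (i in 1:300) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  ## invariants: q >= p, q monotone in the rank of p
  p <- stats::runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) > -1e-15))
})

test_that("temporal stability handles exact fits, nulls and shared-animal pairing", {
  n <- 20; p <- 15
  set.seed(7)
  V1 <- matrix(stats::rnorm(n * p), n, p,
               dimnames = list(sprintf("A%02d_T1", 1:n), sprintf("M%02d", 1:p)))
  V2 <- V1 * 1.3 + 0.2
  rownames(V2) <- sprintf("A%02d_T2", 1:n)
  meta <- data.frame(sample_id = c(rownames(V1), rownames(V2)),
                     animal_id = rep(sprintf("A%02d", 1:n), 2))
  ts <- temporal_stability(V1, V2, meta)
  expect_true(all(ts$table$exact_fit))
  expect_equal(ts$fraction_significant, 1)
  V2r <- matrix(stats::rnorm(n * p), n, p, dimnames = dimnames(V2))
  tsr <- temporal_stability(V1, V2r, meta)
  expect_lt(tsr$fraction_significant, 0.35)
  expect_error(temporal_stability(V1[1:4, ], V2[1:4, ], meta[c(1:4, 21:24), ]),
               "fewer than 5")
})

test_that("temporal correlation of the latent factors drives observed stability", {
  base <- simulation_config(n_animals_per_breed = c(A = 100),
                            n_metabolites = 300,
                            module_sizes = c(90, 80, 60),
                            breed_effect_sd = 0, batch_effect_sd = 0,
                            pen_effect_sd = 0, low_var_frac = 0,
                            temporal_rho = 0.6, seed = 11)
  st <- simulate_study(base)
  lg <- log_transform(st$intensities)
  tp1 <- st$metadata$sample_id[st$metadata$time_point == 1]
  tp2 <- st$metadata$sample_id[st$metadata$time_point == 2]
  ts <- temporal_stability(lg$values[tp1, ], lg$values[tp2, ], st$metadata)
  expect_gt(ts$fraction_significant, 0.5)
})

test_that("significant_set applies the inclusive threshold", {
  tab <- data.frame(metabolite_id = paste0("M", 1:5),
                    p_value = c(0.01, 0.05, 0.051, 0.2, 0.9),
                    q_value = c(0.05, 0.125, 0.085, 0.25, 0.9))
  got <- significant_set(tab)
  expect_equal(got$metabolites, c("M1", "M2"))   # p = 0.05 included
  expect_equal(got$n, 2)
  ann <- stats::setNames(c(TRUE, FALSE, TRUE, TRUE, FALSE), tab$metabolite_id)
  expect_equal(significant_set(tab, annotated = ann)$annotated, "M1")
  none <- significant_set(data.frame(metabolite_id = "M1", p_value = 0.5,
                                     q_value = 0.5))
  expect_equal(none$n, 0)
})
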