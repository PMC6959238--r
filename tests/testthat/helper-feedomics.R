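options(feedomics.verbose = FALSE)

## Adjusted Rand index between two labelings (contingency-table form).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

## Session-level cache so expensive fixtures are built once.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## The seeded co-abundance benchmark: 100 samples (50 animals x 2 time
## points), 500 metabolites, 4 planted modules of 150/130/100/80 members,
## mean loading 0.8, noise sd 1.  Network stage runs on the adjusted log
## intensities (the generator plants no dilution, so no total-intensity
## scaling is involved here).
network_benchmark <- function() {
  cached("network_benchmark", {
    cfg <- simulation_config(
      n_animals_per_breed = c(Benchmark = 50), n_metabolites = 500,
      module_sizes = c(150, 130, 100, 80), loading = 0.8, noise_sd = 1,
      n_trait_metabolites = 0, seed = 7)
    st <- simulate_study(cfg)
    lg <- log_transform(st$intensities)
    m <- fit_effects_model(lg$values, st$metadata, pen_method = "fixed")
    adj <- adjust_metabolites(m, lg$values)
    net <- build_network(adj)
    list(study = st, adjusted = adj, net = net)
  })
}

## Per-sample realization of a planted latent factor.
factor_realization <- function(study, samples, m) {
  meta <- study$metadata[match(samples, study$metadata$sample_id), ]
  ai <- match(meta$animal_id, rownames(study$truth$factors_tp1))
  ifelse(meta$time_point == 1,
         study$truth$factors_tp1[ai, m], study$truth$factors_tp2[ai, m])
}

## Two-breed design with planted batch (+0.5/-0.5) and breed (+0.25/-0.25)
## shifts, pen random effects, unit noise: used for adjustment-recovery
## checks.  Batch alternates within pens so the factors are not aliased.
effect_design <- function(n, tag) {
  data.frame(sample_id = sprintf("%s%03d", tag, seq_len(n)),
             animal_id = sprintf("A%s%03d", tag, seq_len(n)),
             breed = rep(c("D", "L"), each = n / 2),
             batch = rep(c("B1", "B2"), n / 2),
             pen = rep(sprintf("P%d", seq_len(n / 10)), each = 10),
             time_point = 1L, sampling_age = 78,
             stringsAsFactors = FALSE)
}

effect_matrix <- function(md, eff_seed, noise_seed, p = 100,
                          batch_delta = 1, breed_delta = 0.5,
                          pen_sd = 0.3, n_pens = 10) {
  n <- nrow(md)
  set.seed(eff_seed)
  pen_eff <- matrix(stats::rnorm(n_pens * p, sd = pen_sd), n_pens)
  set.seed(noise_seed)
  Y <- matrix(stats::rnorm(n * p), n, p) +
    ifelse(md$batch == "B1", batch_delta / 2, -batch_delta / 2) +
    ifelse(md$breed == "D", breed_delta / 2, -breed_delta / 2) +
    pen_eff[as.integer(factor(md$pen, levels = sprintf("P%d", 1:n_pens))), ]
  dimnames(Y) <- list(md$sample_id, sprintf("MET%03d", seq_len(p)))
  Y
}

## Association on the TP1 group of a simulated study, via log transform,
## fixed-effect adjustment and Eq.-2-style regression (with age covariate).
assoc_tp1 <- function(study, trait) {
  lg <- log_transform(study$intensities)
  tp1 <- study$metadata$sample_id[study$metadata$time_point == 1]
  Y <- lg$values[tp1, , drop = FALSE]
  m <- fit_effects_model(Y, study$metadata, pen_method = "fixed")
  associate_trait(adjust_metabolites(m, Y), study$phenotypes, trait,
                  study$metadata)
}

## A small but structurally complete study for fast unit tests.
small_study <- function() {
  cached("small_study", simulate_study(simulation_config(
    n_animals_per_breed = c(Duroc = 20, Landrace = 16), n_metabolites = 120,
    module_sizes = c(35, 30), n_trait_metabolites = 12, n_minor_factors = 5,
    seed = 101)))
}

## Minimal null configuration for calibration runs: independent metabolites.
null_config <- function(seed, n_animals = 100, n_metabolites = 200) {
  simulation_config(n_animals_per_breed = c(Calib = n_animals),
                    n_metabolites = n_metabolites,
                    module_sizes = integer(0), n_minor_factors = 0,
                    low_var_frac = 0, seed = seed)
}
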