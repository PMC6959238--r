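test_that("default study has the emulated design dimensions", {
  st <- cached("default_study", simulate_study(simulation_config(seed = 1)))
  expect_equal(dim(st$intensities$values), c(218, 729))
  expect_equal(nrow(st$phenotypes), 109)
  expect_equal(sort(unique(st$metadata$breed)), c("Duroc", "Landrace"))
  expect_equal(sum(st$metadata$time_point == 1), 109)
  ## every sample maps to exactly one animal x time point
  expect_false(anyDuplicated(paste(st$metadata$animal_id,
                                   st$metadata$time_point)) > 0)
  ## module truth partitions the planted members
  expect_equal(unname(tabulate(st$truth$module)), c(150, 130, 100, 80))
  expect_true(all(st$intensities$values >= 0))
})

test_that("identical seeds give bit-identical studies", {
  cfg <- simulation_config(n_animals_per_breed = c(A = 12, B = 10),
                           n_metabolites = 60, module_sizes = c(15, 12),
                           seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$intensities$values, s2$intensities$values)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(simulation_config(n_animals_per_breed = c(A = 12, B = 10),
                                         n_metabolites = 60,
                                         module_sizes = c(15, 12), seed = 43))
  expect_false(identical(s1$intensities$values, s3$intensities$values))
})

test_that("structureless configuration yields near-zero correlations", {
  cfg <- simulation_config(n_animals_per_breed = c(A = 40), n_metabolites = 60,
                           module_sizes = integer(0), n_minor_factors = 0,
                           n_trait_metabolites = 0, low_var_frac = 0,
                           loading = 0, breed_effect_sd = 0,
                           batch_effect_sd = 0, pen_effect_sd = 0,
                           noise_sd = 1, seed = 9)
  st <- simulate_study(cfg)
  X <- log(st$intensities$values)
  n <- nrow(X)
  R <- stats::cor(X, method = "spearman")
  offdiag <- abs(R[upper.tri(R)])   # 1770 metabolite pairs
  expect_lt(mean(offdiag), 2 / sqrt(n))
})

test_that("planted module structure is recoverable in raw correlations", {
  cfg <- simulation_config(n_animals_per_breed = c(A = 50), n_metabolites = 200,
                           module_sizes = c(50, 40), loading = 1.2,
                           noise_sd = 1, n_trait_metabolites = 0,
                           low_var_frac = 0, seed = 21)
  st <- simulate_study(cfg)
  X <- log(st$intensities$values)
  mod <- st$truth$module[colnames(X)]
  R <- stats::cor(X, method = "spearman")
  within <- c(R[mod == 1, mod == 1][upper.tri(R[mod == 1, mod == 1])],
              R[mod == 2, mod == 2][upper.tri(R[mod == 2, mod == 2])])
  between <- R[mod == 1, mod == 2]
  expect_gte(mean(abs(within)) - mean(abs(between)), 0.3)
})

test_that("null studies plant no metabolite-phenotype association", {
  st <- simulate_null_study(null_config(5, n_animals = 30, n_metabolites = 40))
  expect_length(st$truth$trait_metabolites, 0)
  expect_equal(st$truth$trait_effect, 0)
})

test_that("phenotype bookkeeping identities hold", {
  st <- small_study()
  ph <- st$phenotypes
  expect_equal(ph$FE * ph$FC, ph$DW, tolerance = 1e-12)
  expect_equal(ph$TDG * ph$test_days, ph$DW, tolerance = 1e-12)
  expect_equal(ph$RFI, ph$DFI - ph$pDFI, tolerance = 1e-12)
  for (b in unique(ph$breed))
    expect_lt(abs(mean(ph$RFI[ph$breed == b])), 1e-10)
})

test_that("sampling age is confounded with growth as designed", {
  st <- cached("default_study", simulate_study(simulation_config(seed = 1)))
  u <- st$truth$efficiency_factor[st$phenotypes$animal_id]
  expect_lt(stats::cor(st$phenotypes$age_at_start, u), -0.3)
  ## slower pigs (low EDG) are sampled older
  expect_lt(stats::cor(st$phenotypes$age_at_start, st$phenotypes$EDG), 0)
})

test_that("fixtures round-trip through disk exactly", {
  st <- small_study()
  dir <- withr::local_tempdir()
  manifest <- write_fixture(st, dir)
  expect_equal(manifest$intensities$rows, nrow(st$phenotypes) * 2)
  intens2 <- read_intensity_table(file.path(dir, "intensities.tsv"),
                                  file.path(dir, "annotation.tsv"))
  expect_equal(intens2$values, st$intensities$values, tolerance = 1e-12)
  expect_equal(intens2$annotated, st$intensities$annotated)
  md2 <- read_metadata(file.path(dir, "metadata.tsv"), intens2)
  expect_equal(md2$sample_id, st$metadata$sample_id)
  ph2 <- compute_phenotypes(
    read_phenotype_inputs(file.path(dir, "phenotype_inputs.tsv")))
  expect_equal(ph2$RFI, st$phenotypes$RFI, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(unname(tabulate(unlist(truth$module))),
               unname(st$config$module_sizes))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(module_sizes = c(500, 300),
                                 n_metabolites = 700), "exceed")
  expect_error(simulation_config(noise_sd = -1), "non-negative")
  expect_error(simulation_config(temporal_rho = 1.2), "temporal_rho")
  expect_error(simulation_config(n_animals_per_breed = c(10, 10)), "named")
})

test_that("synthetic pathway annotation covers annotated compounds", {
  st <- small_study()
  ann <- simulate_pathway_annotation(st, n_pathways = 12)
  expect_s3_class(ann$pathways, "pathway_db")
  expect_length(ann$pathways$sets, 12)
  cpd <- stats::na.omit(st$truth$compound_id)
  expect_true(all(unlist(ann$pathways$sets) %in% cpd))
  expect_true(all(ann$mapping$compound_id %in% cpd))
  ## seeded determinism
  ann2 <- simulate_pathway_annotation(st, n_pathways = 12)
  expect_identical(ann$pathways$sets, ann2$pathways$sets)
})
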