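## Synthetic-study generator.
##
## Emulates a two-breed growing-pig metabolomics design: blood sampled at two
## time points per animal, untargeted intensities with planted co-abundance
## modules (one latent factor per module), breed/batch/pen nuisance effects,
## a latent metabolic-efficiency factor linking a subset of metabolites to
## the growth/feed phenotypes, and deliberate sampling-age confounding
## (slower-growing animals enter the test phase older).  Every stochastic
## quantity is recorded in `truth` so downstream stages admit
## parameter-recovery tests.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the emulated study design: two breeds of 59 and 50
#' animals, 729 metabolites measured at two time points, four planted
#' co-abundance modules, and a 41--70 day feed-efficiency test phase
#' starting at about 28 kg live weight.
#'
#' @param n_animals_per_breed Named integer vector of animals per breed.
#' @param n_metabolites Total number of metabolites.
#' @param module_sizes Integer vector of planted module sizes (non-overlapping;
#'   sum must not exceed `n_metabolites`).
#' @param loading Mean factor loading linking module members to their
#'   module's latent factor (log-intensity units per factor sd).  Member
#'   loadings are drawn uniformly in `loading * (1 +/- loading_spread)`,
#'   giving each module hub-like strong members and peripheral weak ones --
#'   the connectivity heterogeneity real co-abundance networks show.
#' @param loading_spread Half-width of the relative loading spread
#'   (default 0.5; 0 gives identical loadings).
#' @param n_minor_factors Number of small background factors; background
#'   metabolites each load on one random minor factor with a loading drawn
#'   uniformly in \[0, `bg_loading_max`\].  These weak clumps (below any
#'   sensible minimum module size) give the background a realistic weak
#'   correlation continuum without touching the planted modules.
#' @param bg_loading_max Maximum background loading (default 0.5).
#' @param noise_sd Residual log-intensity standard deviation.
#' @param breed_effect_sd,batch_effect_sd,pen_effect_sd Standard deviations of
#'   the planted per-metabolite design effects (log-intensity units).  Planted
#'   effect vectors are centered to sum to zero across levels.
#' @param n_batches Number of instrument-run batches per time point.
#' @param n_pens Pens per breed; `NULL` means one pen per ~10 animals.
#' @param temporal_rho Correlation of each animal's latent factors between
#'   the two sampling time points, in \[-1, 1\].
#' @param n_trait_metabolites Number of metabolites carrying the animal-level
#'   metabolic-efficiency factor that drives the phenotypes; `NULL` (default)
#'   plants 10% of `n_metabolites`.
#' @param trait_effect Phenotype effect size: kg of extra test-phase weight
#'   gain per unit of the latent efficiency factor (also feeds daily feed
#'   intake at 1/100 of this value in kg/day).  Zero gives a null study.
#' @param test_duration_range Inclusive range of test durations in days.
#' @param start_weight_mean,start_weight_sd Start-of-test weight (kg).
#' @param age_at_start_mean Mean age in days at which animals reach the test
#'   start weight.
#' @param age_confound Days by which one sd of the efficiency factor
#'   *reduces* the age at test start (slower animals are sampled older);
#'   this plants the growth--sampling-age confounding.
#' @param growth_base Baseline test-phase daily gain (kg/day).
#' @param growth_sd Residual sd of test-phase weight gain (kg).
#' @param dfi_sd Residual sd of daily feed intake (kg/day).
#' @param low_var_frac Fraction of metabolites rendered near-constant so the
#'   RSD filter has something to remove.
#' @param annotated_frac Fraction of metabolites flagged as annotated (given
#'   a compound ID usable for pathway analysis).
#' @param dropout_frac Fraction of raw intensity cells set to zero, emulating
#'   below-detection dropout.  Default 0.
#' @param seed Integer seed; fully determines the study.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_animals_per_breed = c(Duroc = 59, Landrace = 50),
                              n_metabolites = 729,
                              module_sizes = c(150, 130, 100, 80),
                              loading = 0.8,
                              loading_spread = 0.5,
                              n_minor_factors = 15,
                              bg_loading_max = 0.5,
                              noise_sd = 1,
                              breed_effect_sd = 0.5,
                              batch_effect_sd = 0.5,
                              pen_effect_sd = 0.3,
                              n_batches = 4,
                              n_pens = NULL,
                              temporal_rho = 0.6,
                              n_trait_metabolites = NULL,
                              trait_effect = 3,
                              test_duration_range = c(41, 70),
                              start_weight_mean = 28,
                              start_weight_sd = 1.5,
                              age_at_start_mean = 78,
                              age_confound = 4,
                              growth_base = 0.95,
                              growth_sd = 3,
                              dfi_sd = 0.12,
                              low_var_frac = 0.05,
                              annotated_frac = 0.5,
                              dropout_frac = 0,
                              seed = 1) {
  cfg <- list(n_animals_per_breed = n_animals_per_breed,
              n_metabolites = as.integer(n_metabolites),
              module_sizes = as.integer(module_sizes),
              loading = loading, loading_spread = loading_spread,
              n_minor_factors = as.integer(n_minor_factors),
              bg_loading_max = bg_loading_max,
              noise_sd = noise_sd,
              breed_effect_sd = breed_effect_sd,
              batch_effect_sd = batch_effect_sd,
              pen_effect_sd = pen_effect_sd,
              n_batches = as.integer(n_batches),
              n_pens = n_pens,
              temporal_rho = temporal_rho,
              n_trait_metabolites = if (is.null(n_trait_metabolites))
                as.integer(round(0.1 * n_metabolites)) else
                  as.integer(n_trait_metabolites),
              trait_effect = trait_effect,
              test_duration_range = as.integer(test_duration_range),
              start_weight_mean = start_weight_mean,
              start_weight_sd = start_weight_sd,
              age_at_start_mean = age_at_start_mean,
              age_confound = age_confound,
              growth_base = growth_base,
              growth_sd = growth_sd,
              dfi_sd = dfi_sd,
              low_var_frac = low_var_frac,
              annotated_frac = annotated_frac,
              dropout_frac = dropout_frac,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  assert_that(length(cfg$n_animals_per_breed) >= 1 &&
                all(cfg$n_animals_per_breed >= 1),
              "n_animals_per_breed must contain positive counts")
  assert_that(!is.null(names(cfg$n_animals_per_breed)),
              "n_animals_per_breed must be named by breed")
  assert_that(sum(cfg$module_sizes) <= cfg$n_metabolites,
              "module_sizes exceed n_metabolites")
  assert_that(all(cfg$module_sizes >= 2), "module sizes must be >= 2")
  sds <- c(cfg$noise_sd, cfg$breed_effect_sd, cfg$batch_effect_sd,
           cfg$pen_effect_sd, cfg$growth_sd, cfg$dfi_sd, cfg$start_weight_sd)
  assert_that(all(sds >= 0), "standard deviations must be non-negative")
  assert_that(cfg$loading_spread >= 0 && cfg$loading_spread <= 1,
              "loading_spread must be in [0, 1]")
  assert_that(cfg$bg_loading_max >= 0, "bg_loading_max must be >= 0")
  assert_that(cfg$n_minor_factors >= 0, "n_minor_factors must be >= 0")
  assert_that(abs(cfg$temporal_rho) <= 1, "|temporal_rho| must be <= 1")
  assert_that(cfg$n_trait_metabolites <= cfg$n_metabolites,
              "n_trait_metabolites exceeds n_metabolites")
  assert_that(cfg$test_duration_range[1] >= 1 &&
                cfg$test_duration_range[2] >= cfg$test_duration_range[1],
              "invalid test_duration_range")
  assert_that(cfg$dropout_frac >= 0 && cfg$dropout_frac < 1,
              "dropout_frac must be in [0, 1)")
  invisible(TRUE)
}

#' Simulate a two-time-point metabolomics feed-efficiency study
#'
#' Log-intensity of metabolite j in sample s (animal i, time point t) is
#' `baseline_j + loading * F[i, module(j), t] + gamma_j * u_i + breed + batch
#'  + pen + noise`, where F are module latent factors with TP1->TP2
#' correlation `temporal_rho`, and u is the animal-level metabolic-efficiency
#' factor carried by the trait metabolites (gamma_j = 1 for those, else 0).
#' Raw intensities are `exp(log-intensity)` with baselines drawn around
#' log(1e4), so the table is positive and right-skewed like real ion counts.
#' Phenotypes are assembled from simulated weights and feed so that
#' FE = DW/FC and RFI = DFI - pDFI hold by construction, with the efficiency
#' factor contributing `trait_effect` kg to test-phase gain (DW) and
#' `trait_effect/100` kg/day to daily feed intake (DFI).
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_study`: list with `intensities`
#'   (an `intensity_table`), `metadata`, `phenotype_inputs`, `phenotypes`
#'   (via [compute_phenotypes()]) and `truth` (planted ground truth).
#' @export
simulate_study <- function(config = simulation_config()) {
  validate_simulation_config(config)
  with_seed(config$seed, simulate_study_impl(config))
}

#' Simulate a null study (no metabolite-phenotype association)
#'
#' Identical to [simulate_study()] but with `trait_effect = 0` and no trait
#' metabolites: phenotypes are independent of the metabolome given the
#' design covariates.  Used for type-I-error and KS-calibration checks.
#'
#' @inheritParams simulate_study
#' @return A `synthetic_study` whose `truth$trait_metabolites` is empty.
#' @export
simulate_null_study <- function(config = simulation_config()) {
  config$trait_effect <- 0
  config$n_trait_metabolites <- 0L
  simulate_study(config)
}

simulate_study_impl <- function(cfg) {
  breeds <- names(cfg$n_animals_per_breed)
  n_animals <- sum(cfg$n_animals_per_breed)
  breed_of <- factor(rep(breeds, cfg$n_animals_per_breed), levels = breeds)
  animal_ids <- sprintf("A%03d", seq_len(n_animals))
  p <- cfg$n_metabolites
  met_ids <- sprintf("MET%04d", seq_len(p))
  n_modules <- length(cfg$module_sizes)

  ## metabolite roles: module members, low-variance, trait carriers
  module <- integer(p)
  pool <- sample.int(p)  # scattered module placement
  off <- 0L
  for (m in seq_len(n_modules)) {
    module[pool[(off + 1L):(off + cfg$module_sizes[m])]] <- m
    off <- off + cfg$module_sizes[m]
  }
  n_low <- round(cfg$low_var_frac * p)
  bg <- which(module == 0L)
  low_var <- if (n_low > 0 && length(bg) > 0)
    sort(sample(bg, min(n_low, length(bg)))) else integer(0)
  eligible <- setdiff(seq_len(p), low_var)
  trait_idx <- if (cfg$n_trait_metabolites > 0)
    sort(sample(eligible, min(cfg$n_trait_metabolites, length(eligible))))
  else integer(0)
  gamma <- numeric(p)
  gamma[trait_idx] <- 1

  ## scale factor shrinking every variance component of near-constant
  ## features; drawn so their raw-count RSD straddles the usual 0.15 filter
  ## threshold and per-group survivor counts differ slightly
  vshrink <- rep(1, p)
  vshrink[low_var] <- stats::runif(length(low_var), 0.04, 0.20)

  annotated <- rep(FALSE, p)
  n_ann <- round(cfg$annotated_frac * p)
  if (n_ann > 0) annotated[sample.int(p, n_ann)] <- TRUE
  compound_id <- ifelse(annotated, sprintf("CPD%04d", cumsum(annotated)), NA)

  ## design: pens nested in breed, batches per time point
  pens_per_breed <- if (is.null(cfg$n_pens))
    pmax(1L, ceiling(cfg$n_animals_per_breed / 10)) else
      rep_len(as.integer(cfg$n_pens), length(breeds))
  pen_of <- character(n_animals)
  for (b in seq_along(breeds)) {
    idx <- which(breed_of == breeds[b])
    pen_of[idx] <- sprintf("%s_P%02d", substr(breeds[b], 1, 1),
                           rep_len(seq_len(pens_per_breed[b]), length(idx)))
  }
  pen_levels <- sort(unique(pen_of))

  ## latent factors: module factors, minor background factors, and the
  ## efficiency factor u.  Drawn jointly and orthogonalized over the
  ## realized animals (when the sample allows) so the planted independence
  ## holds exactly in-sample and the ground-truth partition is identifiable.
  K <- n_modules + cfg$n_minor_factors
  n_draw <- 2L * K + 1L
  draw <- matrix(stats::rnorm(n_animals * n_draw), n_animals)
  if (n_animals > n_draw + 1L && n_draw > 1L) {
    draw <- scale(draw, scale = FALSE)
    draw <- qr.Q(qr(draw)) * sqrt(n_animals - 1)
  } else {
    draw <- scale(draw)
  }
  u <- draw[, n_draw]
  if (K > 0) {
    F1 <- draw[, seq_len(K), drop = FALSE]
    innov <- draw[, K + seq_len(K), drop = FALSE]
    F2 <- cfg$temporal_rho * F1 + sqrt(1 - cfg$temporal_rho^2) * innov
  } else {
    F1 <- F2 <- matrix(0, n_animals, 0)
  }

  ## per-metabolite loadings: module members heterogeneous around `loading`;
  ## background metabolites weakly attached to one minor factor each
  load_vec <- numeric(p)
  factor_of <- rep(NA_integer_, p)
  if (n_modules > 0) {
    memb <- which(module > 0L)
    load_vec[memb] <- cfg$loading *
      stats::runif(length(memb), 1 - cfg$loading_spread, 1 + cfg$loading_spread)
    factor_of[memb] <- module[memb]
  }
  if (cfg$n_minor_factors > 0 && length(bg) > 0) {
    bg_use <- setdiff(bg, low_var)
    factor_of[bg_use] <- n_modules +
      sample.int(cfg$n_minor_factors, length(bg_use), replace = TRUE)
    load_vec[bg_use] <- stats::runif(length(bg_use), 0, cfg$bg_loading_max)
  }

  ## planted per-metabolite design effects, centered across levels
  center_rows <- function(M) M - rowMeans(M)
  breed_eff <- center_rows(matrix(stats::rnorm(p * length(breeds),
                                               sd = cfg$breed_effect_sd), p)) * vshrink
  colnames(breed_eff) <- breeds
  batch_levels <- sprintf("B%02d", seq_len(cfg$n_batches))
  batch_eff <- center_rows(matrix(stats::rnorm(p * cfg$n_batches,
                                               sd = cfg$batch_effect_sd), p)) * vshrink
  colnames(batch_eff) <- batch_levels
  pen_eff <- center_rows(matrix(stats::rnorm(p * length(pen_levels),
                                             sd = cfg$pen_effect_sd), p)) * vshrink
  colnames(pen_eff) <- pen_levels

  baseline <- stats::rnorm(p, mean = log(1e4), sd = 0.5)

  ## samples: animal x time point; batch balanced within each time point
  meta <- data.frame(
    sample_id = c(paste0(animal_ids, "_T1"), paste0(animal_ids, "_T2")),
    animal_id = rep(animal_ids, 2),
    breed = rep(as.character(breed_of), 2),
    pen = rep(pen_of, 2),
    time_point = rep(c(1L, 2L), each = n_animals),
    stringsAsFactors = FALSE)
  meta$batch <- c(sample(rep_len(batch_levels, n_animals)),
                  sample(rep_len(batch_levels, n_animals)))

  ## phenotype raw records (ages in days, weights kg, feed kg)
  test_days <- sample(seq(cfg$test_duration_range[1], cfg$test_duration_range[2]),
                      n_animals, replace = TRUE)
  ## slower-growing animals reach the test-start weight later: sampling age
  ## is negatively associated with the efficiency factor (cor ~ -0.5 at the
  ## defaults), a deliberate confound the association model must handle
  age_start <- round(cfg$age_at_start_mean - cfg$age_confound * u +
                       stats::rnorm(n_animals, sd = 6))
  age_start <- pmax(age_start, 45)
  start_w <- stats::rnorm(n_animals, cfg$start_weight_mean, cfg$start_weight_sd)
  dw <- cfg$growth_base * test_days + cfg$trait_effect * u +
    stats::rnorm(n_animals, sd = cfg$growth_sd)
  dw <- pmax(dw, 5)
  end_w <- start_w + dw
  tdg_obs <- dw / test_days
  mw <- ((start_w + end_w) / 2)^0.75
  dfi <- 0.35 + 1.8 * tdg_obs + 0.006 * mw + (cfg$trait_effect / 100) * u +
    stats::rnorm(n_animals, sd = cfg$dfi_sd)
  dfi <- pmax(dfi, 0.3)
  fc <- dfi * test_days
  pheno_in <- data.frame(animal_id = animal_ids,
                         breed = as.character(breed_of),
                         start_weight = start_w, end_weight = end_w,
                         FC = fc,
                         age_at_start = age_start,
                         age_at_end = age_start + test_days,
                         stringsAsFactors = FALSE)
  meta$sampling_age <- c(age_start, age_start + 45)  # TP2 drawn 45 d later

  ## assemble log-intensity matrix (samples x metabolites)
  n_s <- nrow(meta)
  ai <- match(meta$animal_id, animal_ids)
  tp <- meta$time_point
  X <- matrix(stats::rnorm(n_s * p), n_s, p) * rep(cfg$noise_sd * vshrink, each = n_s)
  X <- X + rep(baseline, each = n_s)
  if (K > 0) {
    Fs <- matrix(0, n_s, K)
    Fs[tp == 1L, ] <- F1[ai[tp == 1L], , drop = FALSE]
    Fs[tp == 2L, ] <- F2[ai[tp == 2L], , drop = FALSE]
    for (m in seq_len(K)) {
      jj <- which(factor_of == m & load_vec > 0)
      if (length(jj) == 0) next
      X[, jj] <- X[, jj] + Fs[, m] %o% (load_vec[jj] * vshrink[jj])
    }
  }
  if (length(trait_idx) > 0)
    X[, trait_idx] <- X[, trait_idx] + u[ai] %o% gamma[trait_idx]
  X <- X + t(breed_eff[, meta$breed, drop = FALSE]) +
    t(batch_eff[, meta$batch, drop = FALSE]) +
    t(pen_eff[, meta$pen, drop = FALSE])

  raw <- exp(X)
  if (cfg$dropout_frac > 0) {
    drop <- stats::runif(length(raw)) < cfg$dropout_frac
    raw[drop] <- 0
  }
  dimnames(raw) <- list(meta$sample_id, met_ids)

  intens <- intensity_table(raw, annotated = stats::setNames(annotated, met_ids))
  phen <- compute_phenotypes(pheno_in)

  fac_names <- c(if (n_modules > 0) paste0("module", seq_len(n_modules)),
                 if (cfg$n_minor_factors > 0)
                   paste0("minor", seq_len(cfg$n_minor_factors)))
  colnames(F1) <- colnames(F2) <- fac_names
  truth <- list(module = stats::setNames(module, met_ids),
                loading = stats::setNames(load_vec, met_ids),
                factor_of = stats::setNames(factor_of, met_ids),
                factors_tp1 = F1, factors_tp2 = F2,
                efficiency_factor = stats::setNames(u, animal_ids),
                trait_metabolites = met_ids[trait_idx],
                trait_effect = cfg$trait_effect,
                low_variance = met_ids[low_var],
                breed_effects = breed_eff, batch_effects = batch_eff,
                pen_effects = pen_eff,
                baseline = stats::setNames(baseline, met_ids),
                compound_id = stats::setNames(compound_id, met_ids))
  rownames(truth$factors_tp1) <- rownames(truth$factors_tp2) <- animal_ids

  structure(list(intensities = intens, metadata = meta,
                 phenotype_inputs = pheno_in, phenotypes = phen,
                 truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d samples x %d metabolites, %d animals, %d breeds\n",
              nrow(x$intensities$values), ncol(x$intensities$values),
              nrow(x$phenotypes), length(unique(x$metadata$breed))))
  cat(sprintf("  planted modules: %s; trait metabolites: %d; seed %d\n",
              paste(tabulate(x$truth$module), collapse = "/"),
              length(x$truth$trait_metabolites), x$config$seed))
  invisible(x)
}

#' Simulate pathway annotation for a synthetic study
#'
#' Builds a pathway database (GMT-style) and a compound-to-gene mapping over
#' the study's annotated metabolites, with pathways enriched for the planted
#' trait metabolites so over-representation analysis has signal to find.
#'
#' @param study A `synthetic_study`.
#' @param n_pathways Number of pathways.
#' @param size_range Pathway size range (compounds).
#' @param genes_per_compound Range of genes linked to each compound.
#' @param seed Seed (defaults to the study's seed + 1).
#' @return List with `pathways` (a `pathway_db`, see [load_gmt()]) and
#'   `mapping` (data.frame compound_id, gene_id).
#' @export
simulate_pathway_annotation <- function(study, n_pathways = 40,
                                        size_range = c(5, 30),
                                        genes_per_compound = c(1, 3),
                                        seed = study$config$seed + 1L) {
  ann <- study$intensities$annotated
  cpd <- study$truth$compound_id[ann]
  assert_that(length(cpd) >= size_range[1], "too few annotated metabolites")
  trait_cpd <- stats::na.omit(study$truth$compound_id[study$truth$trait_metabolites])
  with_seed(seed, {
    sets <- vector("list", n_pathways)
    names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
    for (i in seq_len(n_pathways)) {
      sz <- sample(seq(size_range[1], min(size_range[2], length(cpd))), 1)
      ## a third of the pathways draw preferentially from trait compounds
      if (i %% 3 == 0 && length(trait_cpd) >= 2) {
        k <- min(length(trait_cpd), ceiling(sz / 2))
        sets[[i]] <- unique(c(sample(trait_cpd, k),
                              sample(cpd, sz - k)))
      } else sets[[i]] <- unique(sample(cpd, sz))
    }
    db <- structure(list(sets = sets,
                         description = stats::setNames(
                           sprintf("synthetic pathway %d", seq_len(n_pathways)),
                           names(sets)),
                         source = "synthetic"),
                    class = "pathway_db")
    ngene <- sample(seq(genes_per_compound[1], genes_per_compound[2]),
                    length(cpd), replace = TRUE)
    gene_pool <- sprintf("GENE%04d", seq_len(round(length(cpd) * 1.2)))
    mapping <- data.frame(
      compound_id = rep(cpd, ngene),
      gene_id = sample(gene_pool, sum(ngene), replace = TRUE),
      stringsAsFactors = FALSE)
    mapping <- unique(mapping)
    list(pathways = db, mapping = mapping)
  })
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Writes `intensities.tsv` (sample_id column plus one column per
#' metabolite), `metadata.tsv`, `phenotype_inputs.tsv`, `annotation.tsv`
#' (metabolite_id, annotated, compound_id), `truth.json`, and a
#' `manifest.json` listing each file with row/column counts and an MD5
#' checksum.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly a list.
#' @export
write_fixture <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  intens <- data.frame(sample_id = rownames(study$intensities$values),
                       study$intensities$values, check.names = FALSE,
                       stringsAsFactors = FALSE)
  paths$intensities <- file.path(dir, "intensities.tsv")
  write_tsv_strict(intens, paths$intensities)
  paths$metadata <- file.path(dir, "metadata.tsv")
  write_tsv_strict(study$metadata, paths$metadata)
  paths$phenotype_inputs <- file.path(dir, "phenotype_inputs.tsv")
  write_tsv_strict(study$phenotype_inputs, paths$phenotype_inputs)
  ann <- data.frame(metabolite_id = names(study$intensities$annotated),
                    annotated = unname(study$intensities$annotated),
                    compound_id = unname(study$truth$compound_id),
                    stringsAsFactors = FALSE)
  paths$annotation <- file.path(dir, "annotation.tsv")
  write_tsv_strict(ann, paths$annotation)
  paths$truth <- file.path(dir, "truth.json")
  truth <- study$truth
  truth$factors_tp1 <- as.data.frame(truth$factors_tp1)
  truth$factors_tp2 <- as.data.frame(truth$factors_tp2)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  manifest <- lapply(names(paths), function(nm) {
    pth <- paths[[nm]]
    dims <- if (grepl("[.]tsv$", pth)) {
      tb <- read_tsv_strict(pth)
      c(nrow(tb), ncol(tb))
    } else c(NA, NA)
    list(file = basename(pth), rows = dims[1], cols = dims[2],
         md5 = unname(tools::md5sum(pth)))
  })
  names(manifest) <- names(paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
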