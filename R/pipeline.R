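## End-to-end orchestration: simulate/read -> preprocess -> adjust ->
## associate -> network -> integrate -> enrich, with structured logging and
## a run report whose every count is recomputable from the emitted TSVs.

#' Pipeline configuration
#'
#' @param simulation A [simulation_config()] used when no input paths are
#'   given; its seed is overridden by `seed`.
#' @param intensity_path,metadata_path,phenotype_path,annotation_path Input
#'   TSVs for a real dataset (all of the first three required together).
#' @param gmt_path,mapping_path Pathway GMT and compound-gene mapping TSV;
#'   when absent in simulation mode a synthetic annotation is generated,
#'   otherwise enrichment is skipped.
#' @param rsd_threshold RSD filter cutoff (default 0.15).
#' @param alpha_metabolite Per-metabolite association threshold (default
#'   0.05, inclusive).
#' @param module_cor_min,module_p_max Module-trait selection thresholds
#'   (defaults 0.2 and 0.1).
#' @param beta_scan Soft-threshold scan (default 12:22).
#' @param r2_min Scale-free R^2 requirement (default 0.8).
#' @param min_module_size Minimum module size (default 30).
#' @param cut_quantile Tree-cut height quantile (default 0.99).
#' @param heatmap_k Clusters for the RFI heatmap (default 4).
#' @param traits Traits to analyze (default FE, EDG, TDG, DG, RFI).
#' @param adjust_pen_method `"reml"` or `"fixed"` pen handling.
#' @param ora_alpha Pathway significance threshold on the raw p (default
#'   0.05).
#' @param seed Integer seed for all pipeline randomness.
#' @param out_dir Output directory for TSV/JSON artifacts (`NULL`: no
#'   files written).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            intensity_path = NULL, metadata_path = NULL,
                            phenotype_path = NULL, annotation_path = NULL,
                            gmt_path = NULL, mapping_path = NULL,
                            rsd_threshold = 0.15, alpha_metabolite = 0.05,
                            module_cor_min = 0.2, module_p_max = 0.1,
                            beta_scan = 12:22, r2_min = 0.8,
                            min_module_size = 30, cut_quantile = 0.99,
                            heatmap_k = 4, traits = TRAITS,
                            adjust_pen_method = c("reml", "fixed"),
                            ora_alpha = 0.05,
                            seed = 1, out_dir = NULL) {
  cfg <- list(simulation = simulation, intensity_path = intensity_path,
              metadata_path = metadata_path, phenotype_path = phenotype_path,
              annotation_path = annotation_path, gmt_path = gmt_path,
              mapping_path = mapping_path,
              rsd_threshold = rsd_threshold,
              alpha_metabolite = alpha_metabolite,
              module_cor_min = module_cor_min, module_p_max = module_p_max,
              beta_scan = as.integer(beta_scan), r2_min = r2_min,
              min_module_size = as.integer(min_module_size),
              cut_quantile = cut_quantile,
              heatmap_k = as.integer(heatmap_k),
              traits = traits,
              adjust_pen_method = match.arg(adjust_pen_method),
              ora_alpha = ora_alpha,
              seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  assert_that(cfg$rsd_threshold >= 0, "rsd_threshold must be >= 0")
  assert_that(cfg$alpha_metabolite >= 0 && cfg$alpha_metabolite <= 1,
              "alpha_metabolite must be in [0, 1]")
  assert_that(cfg$module_cor_min >= 0 && cfg$module_cor_min <= 1,
              "module_cor_min must be in [0, 1]")
  assert_that(cfg$module_p_max >= 0 && cfg$module_p_max <= 1,
              "module_p_max must be in [0, 1]")
  assert_that(cfg$ora_alpha >= 0 && cfg$ora_alpha <= 1,
              "ora_alpha must be in [0, 1]")
  assert_that(all(cfg$beta_scan >= 1), "beta_scan powers must be >= 1")
  assert_that(cfg$r2_min > 0 && cfg$r2_min <= 1, "r2_min must be in (0, 1]")
  assert_that(cfg$min_module_size >= 2, "min_module_size must be >= 2")
  assert_that(cfg$cut_quantile > 0 && cfg$cut_quantile <= 1,
              "cut_quantile must be in (0, 1]")
  assert_that(cfg$heatmap_k >= 1, "heatmap_k must be >= 1")
  assert_that(length(cfg$traits) >= 1, "traits must be nonempty")
  unknown <- setdiff(cfg$traits, TRAITS)
  assert_that(length(unknown) == 0,
              paste("unknown trait(s):", paste(unknown, collapse = ", ")))
  paths <- c(cfg$intensity_path, cfg$metadata_path, cfg$phenotype_path)
  assert_that(length(paths) %in% c(0, 3),
              "intensity, metadata and phenotype paths must be given together")
  invisible(TRUE)
}

#' Load and validate a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected; missing keys take the defaults of
#' [pipeline_config()] (noted in the returned object's `defaults_applied`).
#' A `simulation:` block is forwarded to [simulation_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config` with attribute `defaults_applied`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  if (!is.null(raw$simulation)) {
    sim_known <- names(formals(simulation_config))
    sim_unknown <- setdiff(names(raw$simulation), sim_known)
    assert_that(length(sim_unknown) == 0,
                paste("unknown simulation keys:",
                      paste(sim_unknown, collapse = ", ")))
    if (!is.null(raw$simulation$n_animals_per_breed))
      raw$simulation$n_animals_per_breed <-
        unlist(raw$simulation$n_animals_per_breed)
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  cfg <- do.call(pipeline_config, raw)
  attr(cfg, "defaults_applied") <- setdiff(setdiff(known, "simulation"),
                                           names(raw))
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: data acquisition (simulation or TSV input), phenotype
#' derivation, per-group RSD filtering, total-ion-intensity normalization,
#' log transform, PCA overview, temporal-stability regression,
#' per-metabolite design-effect adjustment, trait association with KS
#' global tests, co-abundance network with module-trait screening (per
#' breed x time-point group), candidate intersection, time-point/breed
#' overlaps, RFI heatmap clustering (combined-time-point groups), and
#' pathway/hub analysis when annotation is available.  Identical config and
#' seed give identical results and byte-identical output files.
#'
#' @param config A `pipeline_config`.
#' @return A `run_report` (list); artifacts under `config$out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  t0 <- Sys.time()
  out_dir <- config$out_dir
  emit <- function(sub, x) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_strict(x, file.path(out_dir, sub))
    }
  }

  ## -- data acquisition ------------------------------------------------
  simulated <- is.null(config$intensity_path)
  pathway_db <- mapping <- NULL
  compound_of <- NULL
  if (simulated) {
    log_stage("data", "simulating study (seed ", config$seed, ")")
    sim_cfg <- config$simulation
    sim_cfg$seed <- config$seed
    study <- simulate_study(sim_cfg)
    intens <- study$intensities
    metadata <- study$metadata
    phenotypes <- study$phenotypes
    compound_of <- study$truth$compound_id
    if (is.null(config$gmt_path)) {
      ann <- simulate_pathway_annotation(study)
      pathway_db <- ann$pathways
      mapping <- ann$mapping
    }
  } else {
    log_stage("data", "reading input tables")
    intens <- read_intensity_table(config$intensity_path,
                                   config$annotation_path)
    metadata <- read_metadata(config$metadata_path, intens)
    phenotypes <- compute_phenotypes(
      read_phenotype_inputs(config$phenotype_path))
    study <- NULL
    if (!is.null(config$annotation_path)) {
      at <- read_tsv_strict(config$annotation_path)
      if ("compound_id" %in% names(at))
        compound_of <- stats::setNames(at$compound_id, at$metabolite_id)
    }
  }
  if (!is.null(config$gmt_path)) pathway_db <- load_gmt(config$gmt_path)
  if (!is.null(config$mapping_path)) mapping <- read_tsv_strict(config$mapping_path)

  ## -- preprocessing ---------------------------------------------------
  groups <- split_groups(intens, metadata, config$rsd_threshold)
  normed <- tii_normalize(intens)
  logged <- log_transform(normed)
  log_stage("preprocess", length(groups), " groups; kept counts: ",
            paste(vapply(groups, function(g) length(g$metabolites),
                         integer(1)), collapse = "/"))
  pca <- pca_overview(logged, metadata)
  emit("pca_scores.tsv", pca$scores)

  tp1_ids <- metadata$sample_id[metadata$time_point == 1]
  tp2_ids <- metadata$sample_id[metadata$time_point == 2]
  stab <- temporal_stability(logged$values[tp1_ids, , drop = FALSE],
                             logged$values[tp2_ids, , drop = FALSE],
                             metadata)
  emit("temporal_stability.tsv", stab$table)

  ## -- per-group association + network ---------------------------------
  annotated_flags <- intens$annotated
  group_results <- list()
  candidate_unions <- list()
  for (g in groups) {
    lab <- g$label
    log_stage("group", lab, ": ", length(g$sample_ids), " samples, ",
              length(g$metabolites), " metabolites")
    Yg <- logged$values[g$sample_ids, g$metabolites, drop = FALSE]
    mod <- fit_effects_model(Yg, metadata, pen_method = config$adjust_pen_method)
    adj <- adjust_metabolites(mod, Yg)
    emit(paste0("adjusted_", lab, ".tsv"),
         data.frame(sample_id = rownames(adj), unclass(adj),
                    check.names = FALSE))

    assoc <- list(); ks <- list(); sig <- list()
    for (tr in config$traits) {
      at <- associate_trait(adj, phenotypes, tr, metadata)
      assoc[[tr]] <- at
      ks[[tr]] <- ks_uniformity_test(at$p_value)
      sig[[tr]] <- significant_set(at, config$alpha_metabolite,
                                   annotated = annotated_flags)
      emit(paste0("association_", lab, "_", tr, ".tsv"), at)
    }
    ks_tab <- data.frame(trait = names(ks),
                         D = vapply(ks, `[[`, numeric(1), "statistic"),
                         p_value = vapply(ks, `[[`, numeric(1), "p_value"),
                         n = vapply(ks, `[[`, numeric(1), "n"),
                         n_significant = vapply(sig, `[[`, integer(1), "n"),
                         n_significant_annotated =
                           vapply(sig, `[[`, integer(1), "n_annotated"),
                         n_fdr = vapply(names(ks), function(tr)
                           sum(assoc[[tr]]$q_value <= 0.05, na.rm = TRUE),
                           integer(1)),
                         stringsAsFactors = FALSE)
    emit(paste0("ks_summary_", lab, ".tsv"), ks_tab)

    res <- list(group = g, adjusted = adj, model_method = mod$method,
                assoc = assoc, ks_table = ks_tab, significant = sig)

    single_tp <- length(g$time_points) == 1
    if (single_tp) {
      net <- build_network(adj, config$beta_scan, config$r2_min,
                           config$min_module_size, config$cut_quantile)
      mt <- module_trait_correlation(net$eigen, phenotypes, metadata,
                                     config$traits, config$module_cor_min,
                                     config$module_p_max)
      cand <- intersect_candidates(assoc, net$partition, mt,
                                   config$alpha_metabolite)
      emit(paste0("modules_", lab, ".tsv"),
           data.frame(metabolite_id = names(net$partition$colors),
                      module = unname(net$partition$colors)))
      emit(paste0("module_trait_", lab, ".tsv"), as.data.frame(mt))
      emit(paste0("candidates_", lab, ".tsv"),
           if (nrow(cand$members_long) > 0)
             data.frame(group = lab, cand$members_long) else
               data.frame(group = character(), module = character(),
                          trait = character(), metabolite_id = character()))
      res$network <- net
      res$module_trait <- mt
      res$candidates <- cand
      candidate_unions[[lab]] <- cand$unique_union
    }
    group_results[[lab]] <- res
  }

  ## -- overlaps ---------------------------------------------------------
  overlap <- timepoint_overlap(candidate_unions)
  if (!is.null(out_dir))
    jsonlite::write_json(
      list(per_breed = overlap$per_breed, cross_breed = overlap$cross_breed),
      file.path(out_dir, "overlap_summary.json"), auto_unbox = TRUE)

  ## -- RFI heatmaps on combined-time-point groups -----------------------
  heatmaps <- list()
  for (lab in names(group_results)) {
    g <- group_results[[lab]]$group
    if (length(g$time_points) != 2 || !("RFI" %in% config$traits)) next
    rfi_sig <- group_results[[lab]]$significant$RFI$metabolites
    if (length(rfi_sig) < config$heatmap_k) {
      log_stage("heatmap", lab, ": only ", length(rfi_sig),
                " RFI-significant metabolites; skipped")
      next
    }
    hm <- rfi_cluster_heatmap(
      t(unclass(group_results[[lab]]$adjusted)[, rfi_sig, drop = FALSE]),
      k = config$heatmap_k)
    heatmaps[[lab]] <- hm
    emit(paste0("rfi_clusters_", lab, ".tsv"),
         data.frame(metabolite_id = names(hm$clusters),
                    cluster = unname(hm$clusters)))
  }

  ## -- enrichment and hubs ----------------------------------------------
  enrichment <- list()
  if (!is.null(pathway_db) && !is.null(compound_of)) {
    hub_lists <- list()
    for (lab in names(candidate_unions)) {
      g <- group_results[[lab]]$group
      univ_met <- g$metabolites[annotated_flags[g$metabolites] %in% TRUE]
      universe <- stats::na.omit(compound_of[univ_met])
      cand_met <- candidate_unions[[lab]]
      selected <- stats::na.omit(compound_of[intersect(cand_met, univ_met)])
      if (length(selected) == 0 || length(universe) == 0) next
      ora <- ora_hypergeometric(selected, universe, pathway_db)
      res <- list(ora = ora,
                  n_significant = sum(ora$p_value <= config$ora_alpha))
      if (!is.null(mapping)) {
        net <- build_compound_gene_network(selected, mapping)
        res$network <- net
        res$hubs <- find_hubs(net)
        hub_lists[[lab]] <- res$hubs
      }
      enrichment[[lab]] <- res
      emit(paste0("ora_", lab, ".tsv"), as.data.frame(ora))
      if (!is.null(res$hubs)) emit(paste0("hubs_", lab, ".tsv"), res$hubs)
    }
    if (length(hub_lists) >= 2)
      enrichment$shared_hubs <- shared_hubs(hub_lists)
  }

  report <- structure(
    list(config = config, simulated = simulated,
         n_samples = nrow(intens$values),
         n_metabolites = ncol(intens$values),
         pca_var_explained = pca$var_explained,
         temporal_stability = stab,
         groups = group_results, overlap = overlap, heatmaps = heatmaps,
         enrichment = enrichment,
         truth = if (simulated) study$truth else NULL,
         version = as.character(utils::packageVersion("feedomics")),
         wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(out_dir)) render_report(report, file.path(out_dir, "report"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d samples x %d metabolites, %d groups, %.1f s\n",
              x$n_samples, x$n_metabolites, length(x$groups),
              x$wall_clock_sec))
  invisible(x)
}

#' Summarize a run report as plain tables
#'
#' @param report A `run_report`.
#' @return List of data.frames: `filter_counts`, `ks` (per group x trait),
#'   `modules`, `candidates`, `overlap_counts`.
#' @export
report_tables <- function(report) {
  gs <- report$groups
  filter_counts <- do.call(rbind, lapply(gs, function(r)
    data.frame(group = r$group$label, n_samples = length(r$group$sample_ids),
               n_kept = length(r$group$metabolites),
               n_total = nrow(r$group$filter_report))))
  ks <- do.call(rbind, lapply(gs, function(r)
    data.frame(group = r$group$label, r$ks_table)))
  net_gs <- Filter(function(r) !is.null(r$network), gs)
  modules <- do.call(rbind, lapply(net_gs, function(r)
    data.frame(group = r$group$label,
               module = names(r$network$partition$sizes),
               size = as.integer(r$network$partition$sizes),
               beta = r$network$beta$beta,
               scale_free_met = r$network$beta$criterion_met)))
  candidates <- do.call(rbind, lapply(net_gs, function(r)
    data.frame(group = r$group$label,
               rbind(r$candidates$sets,
                     data.frame(module = "(unique union)", trait = "all",
                                n = length(r$candidates$unique_union))))))
  overlap_counts <- do.call(rbind, lapply(names(report$overlap$per_breed),
    function(b) {
      pb <- report$overlap$per_breed[[b]]
      data.frame(breed = b, n_tp1 = pb$n_tp1, n_tp2 = pb$n_tp2,
                 n_common = pb$n_common)
    }))
  lapply(list(filter_counts = filter_counts, ks = ks, modules = modules,
              candidates = candidates, overlap_counts = overlap_counts),
         function(d) { rownames(d) <- NULL; d })
}

#' Render a run report to Markdown and JSON
#'
#' @param report A `run_report`.
#' @param path_stub Output path without extension; writes `<stub>.md` and
#'   `<stub>.json`.
#' @return The two paths, invisibly.
#' @export
render_report <- function(report, path_stub) {
  tabs <- report_tables(report)
  md <- c(sprintf("# Pipeline run report (feedomics %s)", report$version),
          "",
          sprintf("- samples: %d, metabolites: %d, seed: %d",
                  report$n_samples, report$n_metabolites,
                  report$config$seed),
          sprintf("- PC1/PC2 variance explained: %.1f%% / %.1f%%",
                  report$pca_var_explained[1], report$pca_var_explained[2]),
          sprintf("- temporal stability: %.1f%% of metabolites with p < %g",
                  100 * report$temporal_stability$fraction_significant,
                  report$temporal_stability$alpha),
          sprintf("- wall clock: %.1f s", report$wall_clock_sec),
          "")
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    if (is.null(tb) || nrow(tb) == 0) next
    md <- c(md, sprintf("## %s", nm), "",
            paste("|", paste(names(tb), collapse = " | "), "|"),
            paste("|", paste(rep("---", ncol(tb)), collapse = " | "), "|"),
            vapply(seq_len(nrow(tb)), function(i)
              paste("|", paste(vapply(tb[i, ], function(v)
                if (is.numeric(v)) format(v, digits = 6) else as.character(v),
                character(1)), collapse = " | "), "|"), character(1)),
            "")
  }
  md_path <- paste0(path_stub, ".md")
  writeLines(md, md_path)
  json_path <- paste0(path_stub, ".json")
  jsonlite::write_json(
    c(list(version = report$version, seed = report$config$seed,
           n_samples = report$n_samples,
           n_metabolites = report$n_metabolites,
           wall_clock_sec = report$wall_clock_sec),
      lapply(tabs, function(d) d)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(md_path, json_path))
}
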