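#' Curve-class mixture emulating the published screen
#'
#' 3,826 compounds triaged into 76 actives (class split following the
#' printed top-50 composition: 8/14/11/17 across 1.1/1.2/2.1/2.2), 269
#' inconclusive (class 3) and 3,481 inactive (class 4).
#'
#' @return named proportion vector over the six curve classes.
#' @export
paper_class_mix <- function() {
  active <- 76 * c(8, 14, 11, 17) / 50
  p <- c(active, 269, 3481) / 3826
  stats::setNames(p, c("1.1", "1.2", "2.1", "2.2", "3", "4"))
}

#' Pipeline configuration
#'
#' All tunable thresholds, sizes and seeds of an end-to-end run in one
#' serializable object. Concentrations are uM throughout; combination doses
#' are unit-agnostic (ratios only).
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir output directory.
#' @param stages which stages to run, in pipeline order.
#' @param n_compounds,class_mix,noise_sd screen simulation size/shape.
#' @param top_n hits reported by the screen stage.
#' @param qhts list of [qhts_config()] overrides.
#' @param n_genes,rho,frac_divergent expression-pair simulation parameters.
#' @param fold_threshold fold-change filter cutoff.
#' @param n_drugs,n_targets,n_edges drug-target map size.
#' @param n_hubs hub nodes reported.
#' @param synergy list of [combination_truth()] arguments.
#' @param ci_bands additivity band.
#' @export
pipeline_config <- function(seed = 1,
                            out_dir = "pheoscreen_run",
                            stages = c("simulate", "screen", "enrich",
                                       "meta", "network", "synergy"),
                            n_compounds = 240,
                            class_mix = NULL,
                            noise_sd = 3,
                            top_n = 50,
                            qhts = list(),
                            n_genes = 1753, rho = 0.86,
                            frac_divergent = 0.18,
                            fold_threshold = 2,
                            n_drugs = 22, n_targets = 2129, n_edges = 3091,
                            n_hubs = 20,
                            synergy = list(dm1 = 5, dm2 = 1000, m1 = 0.603,
                                           m2 = 1.145, ratio = 200,
                                           ci_true = 0.55, noise_sd = 0.01),
                            ci_bands = c(0.8, 1.2)) {
  mix <- class_mix %||% as.list(paper_class_mix())
  stopifnot(fold_threshold > 1, ci_bands[1] > 0, ci_bands[1] < ci_bands[2],
            n_hubs >= 1, top_n >= 1)
  cfg <- list(seed = seed, out_dir = out_dir, stages = stages,
              n_compounds = n_compounds, class_mix = mix,
              noise_sd = noise_sd, top_n = top_n, qhts = qhts,
              n_genes = n_genes, rho = rho, frac_divergent = frac_divergent,
              fold_threshold = fold_threshold,
              n_drugs = n_drugs, n_targets = n_targets, n_edges = n_edges,
              n_hubs = n_hubs, synergy = synergy, ci_bands = ci_bands)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Stages, in the screen's order: simulate (generate every input), screen
#' (normalize, fit, classify, triage, rank), enrich (therapeutic-category
#' enrichment), meta (cross-species target correlation), network
#' (drug-target network, eccentricity hubs), synergy (median-effect
#' combination analysis). Each stage writes its tables under
#' `config$out_dir`; a manifest records every artifact with its MD5 hash,
#' and `run.log` records versions, seed and the config hash. A stage error
#' aborts with the stage name; artifacts already written are preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the manifest and per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  qcfg <- do.call(qhts_config, config$qhts)
  artifacts <- character(0)
  results <- list()
  emit <- function(obj, name, writer = write_table) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
    path
  }
  stage <- function(name, code) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    tryCatch(code, error = function(e)
      stop_input("stage '", name, "' failed: ", conditionMessage(e)))
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  artifacts <- c(artifacts, cfg_path)

  sim <- NULL
  stage("simulate", {
    truth <- gen_screen_library(config$n_compounds, config$class_mix,
                                seed = child_seed(config$seed, 1))
    reads <- gen_plate_reads(truth, noise_sd = config$noise_sd,
                             seed = child_seed(config$seed, 2))
    expr <- gen_expression_pair(config$n_genes, rho = config$rho,
                                frac_divergent = config$frac_divergent,
                                seed = child_seed(config$seed, 3))
    dmap <- gen_drug_target_map(config$n_drugs, config$n_targets,
                                config$n_edges,
                                seed = child_seed(config$seed, 4))
    truth_syn <- do.call(combination_truth, config$synergy)
    assay <- gen_combination_assay(truth_syn,
                                   seed = child_seed(config$seed, 5))
    sim <- list(truth = truth, reads = reads, expr = expr, dmap = dmap,
                 assay = assay)
    emit(truth, "library_truth.tsv")
    emit(reads$plates, "plates.tsv")
    emit(reads$map, "compound_map.tsv")
    emit(expr$a, "expression_mouse.tsv", write_expression)
    emit(expr$b, "expression_human.tsv", write_expression)
    emit(dmap, "drug_target_map.tsv")
    results$simulate <- sim
  })
  if (is.null(sim) && any(config$stages != "simulate"))
    stop_input("stage dependencies require the 'simulate' stage")

  calls <- NULL
  stage("screen", {
    calls <- analyze_screen(sim$reads$plates, sim$reads$map, qcfg)
    hits <- rank_hits(calls, config$top_n)
    emit(calls, "screen_calls.tsv")
    emit(hits, "hits.tsv")
    results$screen <- list(calls = calls, hits = hits)
  })

  stage("enrich", {
    if (is.null(calls)) stop("needs the 'screen' stage")
    enr <- category_enrichment(calls)
    emit(enr, "category_enrichment.tsv")
    results$enrich <- enr
  })

  stage("meta", {
    za <- zscore_genes(sim$expr$a)
    zb <- zscore_genes(sim$expr$b)
    merged <- merge_common_genes(za, zb)
    survivors <- fold_change_filter(merged, config$fold_threshold)
    corr <- drug_target_correlation(merged, sim$dmap, genes = survivors)
    emit(corr$drugs, "drug_correlations.tsv")
    results$meta <- list(merged = merged, survivors = survivors,
                          corr = corr,
                          overall_gene_r = overall_gene_correlation(merged,
                                                                    survivors))
  })

  stage("network", {
    net <- build_drug_target_network(sim$dmap)
    sc <- eccentricity_scores(net)
    hubs <- top_hubs(sc, config$n_hubs)
    sif <- file.path(config$out_dir, "network.sif")
    natt <- file.path(config$out_dir, "node_attributes.tsv")
    write_sif(net, sif, natt, sc)
    artifacts <- c(artifacts, sif, natt)
    emit(hubs, "top_hubs.tsv")
    results$network <- list(net = net, scores = sc, hubs = hubs)
  })

  stage("synergy", {
    an <- analyze_combination(sim$assay$single1, sim$assay$single2,
                              sim$assay$combo, bands = config$ci_bands)
    emit(an$rows, "combination_report.tsv")
    emit(an$fa_ci_curve, "fa_ci_curve.tsv")
    results$synergy <- an
  })

  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE
  )
  write_table(manifest, file.path(config$out_dir, "manifest.tsv"))
  writeLines(c(
    paste("pheoscreen", as.character(utils::packageVersion("pheoscreen"))),
    R.version.string,
    paste("seed:", config$seed),
    paste("config_md5:", unname(tools::md5sum(cfg_path))),
    paste("stages:", paste(config$stages, collapse = ", "))
  ), file.path(config$out_dir, "run.log"))
  invisible(list(manifest = manifest, results = results))
}
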