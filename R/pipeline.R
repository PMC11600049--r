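# End-to-end orchestration: simulate -> qc -> markers/annotate -> odds-ratio
# enrichment -> cnv -> gsea -> interactions -> survival, from a single
# config, with per-stage outputs on disk and a deterministic JSON summary.

#' Default pipeline configuration
#'
#' Analysis parameters carry the pipeline's standard defaults (odds-ratio
#' labels at OR > 1.5 / < 0.5 with BH p < 0.01, the four-condition
#' interaction retention rule, arm cutoffs +/- 0.3); QC bounds are scaled
#' to the synthetic fixture's small gene universe. Any entry can be
#' overridden via [run_pipeline()]'s `config` argument; unknown keys are
#' rejected.
#'
#' @param out_dir Output directory for stage results.
#' @param seed Master seed; every stage derives its own substream from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = tempfile("sctme_run_"),
                                    seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = c("simulate", "qc", "markers", "annotate", "enrich", "cnv",
               "gsea", "interact", "survival"),
    sim = list(),            # overrides for simulation_config()
    qc = list(min_genes = 10, max_genes = 5000, max_umi = 30000,
              max_pct_mito = 30),
    markers = list(min_pct = 0.25, max_p_adj = 0.05, min_log2fc = 0.25),
    enrich = list(or_hi = 1.5, or_lo = 0.5, alpha = 0.01),
    cnv = list(gain_cut = 0.3, loss_cut = -0.3),
    gsea = list(n_perm = 200),
    interact = list(n_perm = 100),
    survival = list()        # overrides for survival_simulation_config()
  )
}

merge_config <- function(base, override) {
  known <- names(base)
  unknown <- setdiff(names(override), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      sub_unknown <- setdiff(names(override[[k]]), names(base[[k]]))
      if (length(sub_unknown) && !k %in% c("sim", "survival")) {
        stopf("unknown config key(s) under '%s': %s", k,
              paste(sub_unknown, collapse = ", "))
      }
      base[[k]][names(override[[k]])] <- override[[k]]
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full pipeline from a configuration
#'
#' Stages run in dependency order; each writes its outputs under
#' `out_dir`, and a machine-readable `summary.json` records the key result
#' of every stage together with the seed. The run is deterministic:
#' identical config and seed give a byte-identical summary.
#'
#' @param config A list of overrides merged onto
#'   [default_pipeline_config()], or a path to a YAML file of such
#'   overrides.
#' @return The summary list, invisibly; `summary.json` and per-stage TSV
#'   files are written under `config$out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  summary <- list(seed = seed)
  t0 <- Sys.time()
  log_stage <- function(stage) {
    message(sprintf("[sctme] stage=%s seed=%d elapsed=%.1fs", stage, seed,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  stages <- cfg$stages

  # simulate ---------------------------------------------------------------
  log_stage("simulate")
  sim_cfg <- do.call(simulation_config,
                     c(cfg$sim, list(seed = substream_seed(seed, 1))))
  sim <- generate_dataset(sim_cfg)
  dataset <- sim$dataset
  utils::write.table(sim$truth, file.path(cfg$out_dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$simulate <- list(n_cells = length(dataset$cell_ids),
                           n_genes = length(dataset$gene_ids))

  # qc ---------------------------------------------------------------------
  if ("qc" %in% stages) {
    log_stage("qc")
    qc <- compute_cell_qc(dataset)
    thr <- qc_thresholds(cfg$qc$min_genes, cfg$qc$max_genes, cfg$qc$max_umi,
                         cfg$qc$max_pct_mito)
    filt <- apply_qc_filters(qc, thr)
    dataset <- subset_cells(dataset, filt$kept)
    utils::write.table(qc, file.path(cfg$out_dir, "qc_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$qc <- list(kept = length(filt$kept),
                       removed = as.list(filt$removed))
  }
  dataset <- normalize_log1p(dataset)
  norm <- as.matrix(dataset$norm)

  # markers ----------------------------------------------------------------
  if ("markers" %in% stages) {
    log_stage("markers")
    mk <- do.call(find_all_markers,
                  c(list(norm = norm, clusters = dataset$meta$cluster),
                    cfg$markers))
    utils::write.table(mk, file.path(cfg$out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$markers <- list(n_retained = nrow(mk))
  }

  # annotate ---------------------------------------------------------------
  if ("annotate" %in% stages) {
    log_stage("annotate")
    ann <- suppressWarnings(
      annotate_clusters(norm, dataset$meta$cluster))
    utils::write.table(ann, file.path(cfg$out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$annotate <- stats::setNames(as.list(ann$cell_type), ann$cluster)
  }

  # enrich -----------------------------------------------------------------
  if ("enrich" %in% stages) {
    log_stage("enrich")
    or_tab <- or_preference_matrix(dataset$meta, or_hi = cfg$enrich$or_hi,
                                   or_lo = cfg$enrich$or_lo,
                                   alpha = cfg$enrich$alpha)
    utils::write.table(or_tab, file.path(cfg$out_dir, "or_preference.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- or_tab[or_tab$label == "enriched", c("cluster", "group")]
    summary$enrich <- list(
      enriched = if (nrow(enr)) paste(enr$cluster, enr$group, sep = "@") else
        character(0))
  }

  # cnv --------------------------------------------------------------------
  if ("cnv" %in% stages) {
    log_stage("cnv")
    cnv_cfg <- cnv_simulation_config(seed = substream_seed(seed, 2))
    cnv <- generate_cnv_profiles(cnv_cfg)
    scores <- cnv_score(cnv$profile)
    malignant <- call_malignant(scores, cnv$profile$reference_cell_ids)
    events <- map_events_to_arms(cnv$profile, cnv_cfg$cytoband,
                                 gain_cut = cfg$cnv$gain_cut,
                                 loss_cut = cfg$cnv$loss_cut)
    tumour_cells <- setdiff(cnv$profile$cell_ids,
                            cnv$profile$reference_cell_ids)
    subclones <- collapse_subclones(events[tumour_cells])
    tree <- build_clonal_tree(subclones)
    newick <- serialize_newick(tree)
    writeLines(newick, file.path(cfg$out_dir, "clonal_tree.nwk"))
    summary$cnv <- list(n_malignant = sum(malignant),
                        n_subclones = nrow(subclones), newick = newick)
  }

  # gsea -------------------------------------------------------------------
  if ("gsea" %in% stages) {
    log_stage("gsea")
    cl1 <- sim_cfg$clusters[[1]]
    stats_ <- wilcoxon_auc(norm,
                           which(dataset$meta$cluster == cl1$name),
                           which(dataset$meta$cluster != cl1$name))
    ranked <- rank_by_auc(stats_)
    sets <- stats::setNames(
      lapply(sim_cfg$clusters, `[[`, "marker_genes"),
      paste0(vapply(sim_cfg$clusters, `[[`, character(1), "name"), "_markers"))
    gsea <- nes_fdr(ranked, sets, n_perm = cfg$gsea$n_perm,
                    seed = substream_seed(seed, 3))
    utils::write.table(gsea[, c("set_name", "size", "es", "nes", "p", "fdr")],
                       file.path(cfg$out_dir, "gsea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$gsea <- list(top_set = gsea$set_name[which.max(gsea$nes)],
                         top_nes = max(gsea$nes))
  }

  # interact ---------------------------------------------------------------
  if ("interact" %in% stages) {
    log_stage("interact")
    cl_names <- vapply(sim_cfg$clusters, `[[`, character(1), "name")
    db <- lr_database(data.frame(
      pair_name = c("planted", "decoy"),
      ligand = c(sim_cfg$clusters[[1]]$marker_genes[1], "G0001"),
      receptor = c(sim_cfg$clusters[[2]]$marker_genes[1], "G0002"),
      stringsAsFactors = FALSE))
    it <- interaction_test(dataset, db, sender = cl_names[1],
                           receiver = cl_names[2],
                           n_perm = cfg$interact$n_perm,
                           seed = substream_seed(seed, 4))
    utils::write.table(
      it[, setdiff(names(it), "receptor_subunits")],
      file.path(cfg$out_dir, "interactions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    summary$interact <- list(retained = it$pair_name[it$retained])
  }

  # survival ---------------------------------------------------------------
  if ("survival" %in% stages) {
    log_stage("survival")
    surv_cfg <- do.call(survival_simulation_config,
                        c(cfg$survival, list(seed = substream_seed(seed, 5))))
    cohort <- generate_survival_cohort(surv_cfg)
    sa <- survival_signature_analysis(cohort$table, surv_cfg$signature_genes)
    summary$survival <- list(hr = sa$cox$hr, ci_low = sa$cox$ci_low,
                             ci_high = sa$cox$ci_high,
                             logrank_p = sa$logrank$p)
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
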