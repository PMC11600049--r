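# Synthetic-data generators. Each generator plants the statistical structure
# a downstream stage assumes (group-dependent cluster composition,
# marker-gene elevation over negative-binomial noise, subclonal arm-level
# CNV profiles, survival cohorts with a known hazard ratio) and returns the
# ground truth alongside the data, never embedded in it.

#' Configuration for the single-cell count simulator
#'
#' Defaults emulate a small myeloid-focused comparison: three clusters with
#' three planted marker genes each (2-fold-squared, i.e. 4x, elevation via
#' `marker_log2_shift = 2`), and the F13A1+ macrophage-like cluster planted
#' at 30% of cells in MPLC tumours vs 10% in every other group (a ~3x
#' relative over-representation, odds ratio about 3.9).
#'
#' @param n_genes Total genes in the universe (markers and mitochondrial
#'   genes included; remaining genes are unstructured filler).
#' @param clusters List of `list(name=, marker_genes=, marker_log2_shift=)`.
#' @param composition Matrix of expected cluster proportions, one row per
#'   group in [tme_groups()], one column per cluster; rows sum to 1.
#' @param cells_per_sample,samples_per_group Cohort shape. Defaults give
#'   2000 cells per group.
#' @param nb_mean Median per-gene negative-binomial mean (per-gene means are
#'   log-normal around this value).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param mito_fraction_range Per-cell expected mitochondrial count fraction
#'   is drawn uniformly from this range.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 150,
                              clusters = list(
                                list(name = "Mac_F13A1",
                                     marker_genes = c("F13A1", "SELENOP", "C1QC"),
                                     marker_log2_shift = 2),
                                list(name = "cDC2_CD1C",
                                     marker_genes = c("CD1C", "FCER1A", "CLEC10A"),
                                     marker_log2_shift = 2),
                                list(name = "TNK",
                                     marker_genes = c("CD3D", "CD3E", "NKG7"),
                                     marker_log2_shift = 2)),
                              composition = NULL,
                              cells_per_sample = 1000,
                              samples_per_group = 2,
                              nb_mean = 1,
                              nb_dispersion = 0.5,
                              mito_fraction_range = c(0.02, 0.08),
                              seed = 1) {
  cluster_names <- vapply(clusters, `[[`, character(1), "name")
  if (is.null(composition)) {
    # planted preference: first cluster over-represented in MPLC tumours
    k <- length(clusters)
    composition <- matrix(0, nrow = 4, ncol = k,
                          dimnames = list(tme_groups(), cluster_names))
    composition[, 1] <- 0.10
    composition["MPLC_Tumour", 1] <- 0.30
    composition[, -1] <- (1 - composition[, 1]) / (k - 1)
  }
  cfg <- structure(
    list(n_genes = n_genes, clusters = clusters, composition = composition,
         cells_per_sample = cells_per_sample,
         samples_per_group = samples_per_group,
         nb_mean = nb_mean, nb_dispersion = nb_dispersion,
         mito_fraction_range = mito_fraction_range, seed = seed),
    class = "SimulationConfig")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  comp <- cfg$composition
  if (!is.matrix(comp) || nrow(comp) != 4) {
    stopf("composition must be a 4-row matrix (one row per group)")
  }
  if (any(abs(rowSums(comp) - 1) > 1e-9)) {
    stopf("composition rows must sum to 1 (off by up to %.3g)",
          max(abs(rowSums(comp) - 1)))
  }
  shifts <- vapply(cfg$clusters, `[[`, numeric(1), "marker_log2_shift")
  if (any(shifts < 0)) stopf("marker_log2_shift must be >= 0")
  if (cfg$nb_mean <= 0 || cfg$nb_dispersion <= 0) {
    stopf("nb_mean and nb_dispersion must be positive")
  }
  mr <- cfg$mito_fraction_range
  if (length(mr) != 2 || mr[1] < 0 || mr[2] >= 1 || mr[1] > mr[2]) {
    stopf("mito_fraction_range must be (lo, hi) within [0, 1)")
  }
  markers <- unlist(lapply(cfg$clusters, `[[`, "marker_genes"))
  n_named <- length(unique(markers)) + 5L  # 5 MT- genes
  if (cfg$n_genes < n_named) {
    stopf("n_genes (%d) smaller than the %d named marker + mitochondrial genes",
          cfg$n_genes, n_named)
  }
  invisible(cfg)
}

sim_gene_universe <- function(cfg) {
  markers <- unique(unlist(lapply(cfg$clusters, `[[`, "marker_genes")))
  mito <- c("MT-CO1", "MT-CO2", "MT-ND1", "MT-ND2", "MT-CYB")
  n_fill <- cfg$n_genes - length(markers) - length(mito)
  fillers <- sprintf("G%04d", seq_len(n_fill))
  c(markers, mito, fillers)
}

#' Generate a synthetic single-cell dataset with planted structure
#'
#' Counts are negative binomial with log-normal per-gene means; each
#' cluster's marker genes are elevated by a factor `2^marker_log2_shift` in
#' that cluster's cells; per-sample cluster counts are multinomial draws
#' from the group's composition row; genes prefixed `MT-` carry the
#' configured fraction of each cell's counts in expectation.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (an [expression_dataset()], cluster labels in
#'   `meta$cluster` as pipeline input) and `truth` (per-cell true cluster,
#'   group and sample).
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  genes <- sim_gene_universe(config)
  mito_idx <- grep("^MT-", genes)
  cluster_names <- vapply(config$clusters, `[[`, character(1), "name")
  with_seed(config$seed, {
    base_mean <- stats::rlnorm(length(genes), meanlog = log(config$nb_mean),
                               sdlog = 0.5)
    names(base_mean) <- genes

    cell_cluster <- character(0)
    cell_sample <- character(0)
    cell_group <- character(0)
    for (g in tme_groups()) {
      for (s in seq_len(config$samples_per_group)) {
        sample_id <- sprintf("%s_S%d", g, s)
        n_per_cluster <- as.vector(stats::rmultinom(
          1, config$cells_per_sample, config$composition[g, ]))
        cl <- rep(cluster_names, n_per_cluster)
        cell_cluster <- c(cell_cluster, cl)
        cell_sample <- c(cell_sample, rep(sample_id, length(cl)))
        cell_group <- c(cell_group, rep(g, length(cl)))
      }
    }
    n_cells <- length(cell_cluster)
    cell_ids <- sprintf("C%06d", seq_len(n_cells))

    # per-cell x per-gene NB mean: base mean, marker shift, mito rescaling
    mu <- matrix(base_mean, nrow = n_cells, ncol = length(genes), byrow = TRUE)
    for (cl in config$clusters) {
      rows <- cell_cluster == cl$name
      cols <- match(cl$marker_genes, genes)
      mu[rows, cols] <- mu[rows, cols] * 2^cl$marker_log2_shift
    }
    mito_f <- stats::runif(n_cells, config$mito_fraction_range[1],
                           config$mito_fraction_range[2])
    non_mito_total <- rowSums(mu[, -mito_idx, drop = FALSE])
    base_mito <- base_mean[mito_idx] / sum(base_mean[mito_idx])
    mu[, mito_idx] <- (mito_f / (1 - mito_f)) * non_mito_total %o% base_mito

    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / config$nb_dispersion),
                     nrow = n_cells)
    meta <- data.frame(cell_id = cell_ids, sample_id = cell_sample,
                       group = cell_group, cluster = cell_cluster,
                       stringsAsFactors = FALSE)
    dataset <- expression_dataset(counts, gene_ids = genes,
                                  cell_ids = cell_ids, meta = meta)
    truth <- data.frame(cell_id = cell_ids, true_cluster = cell_cluster,
                        group = cell_group, sample_id = cell_sample,
                        stringsAsFactors = FALSE)
    list(dataset = dataset, truth = truth)
  })
}

#' Build a toy cytoband table
#'
#' Each chromosome gets a p arm `[0, p_len)` and a q arm `[p_len, p_len +
#' q_len)` as single bands.
#'
#' @param chroms Chromosome names.
#' @param p_len,q_len Arm lengths in bp.
#' @return A [cytoband_table()].
#' @export
toy_cytoband <- function(chroms = c("chr1", "chr2", "chr5", "chr7"),
                         p_len = 50e6, q_len = 70e6) {
  cytoband_table(data.frame(
    chrom = rep(chroms, each = 2),
    start = rep(c(0, p_len), length(chroms)),
    end = rep(c(p_len, p_len + q_len), length(chroms)),
    band = rep(c("p11", "q11"), length(chroms)),
    stringsAsFactors = FALSE))
}

#' Tile a cytoband genome into fixed-width windows
#'
#' @param cytoband A [cytoband_table()].
#' @param width Window width in bp.
#' @return Data frame of (chrom, start, end) windows in genomic order.
#' @export
tile_windows <- function(cytoband, width = 1e6) {
  out <- lapply(unique(cytoband$chrom), function(ch) {
    sub <- cytoband[cytoband$chrom == ch, ]
    lo <- min(sub$start); hi <- max(sub$end)
    starts <- seq(lo, hi - 1, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, hi), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Construct an arm-level CNV event
#'
#' @param chrom Chromosome name.
#' @param arm "p" or "q".
#' @param direction "gain" or "loss".
#' @return One-row data frame usable in subclone `arm_events`.
#' @export
arm_event <- function(chrom, arm, direction) {
  stopifnot(arm %in% c("p", "q"), direction %in% c("gain", "loss"))
  data.frame(chrom = chrom, arm = arm, direction = direction,
             stringsAsFactors = FALSE)
}

#' Configuration for the CNV profile simulator
#'
#' Defaults plant two nested subclones on a four-chromosome toy genome:
#' 35% of tumour cells carry a 5q gain, a further 25% carry 5q gain plus 7p
#' loss, and the remaining 40% are copy-neutral.
#'
#' @param cytoband Toy genome as a [cytoband_table()].
#' @param windows Genome windows (default: 1 Mb tiles of `cytoband`).
#' @param subclones List of `list(arm_events=, fraction=, effect_size=)`;
#'   fractions must sum to <= 1, the remainder being diploid tumour cells.
#' @param noise_sd Per-window Gaussian noise SD.
#' @param n_reference_cells,n_tumour_cells Cohort sizes.
#' @param seed Integer seed.
#' @return A `CNVSimulationConfig` list.
#' @export
cnv_simulation_config <- function(cytoband = toy_cytoband(),
                                  windows = NULL,
                                  subclones = list(
                                    list(arm_events = arm_event("chr5", "q", "gain"),
                                         fraction = 0.35, effect_size = 1),
                                    list(arm_events = rbind(
                                           arm_event("chr5", "q", "gain"),
                                           arm_event("chr7", "p", "loss")),
                                         fraction = 0.25, effect_size = 1)),
                                  noise_sd = 0.1,
                                  n_reference_cells = 200,
                                  n_tumour_cells = 400,
                                  seed = 1) {
  if (is.null(windows)) windows <- tile_windows(cytoband)
  fractions <- vapply(subclones, `[[`, numeric(1), "fraction")
  if (sum(fractions) > 1 + 1e-12) {
    stopf("subclone fractions sum to %.3f > 1", sum(fractions))
  }
  effects <- vapply(subclones, `[[`, numeric(1), "effect_size")
  if (any(effects <= 0)) stopf("effect_size must be positive")
  structure(
    list(cytoband = cytoband, windows = windows, subclones = subclones,
         noise_sd = noise_sd, n_reference_cells = n_reference_cells,
         n_tumour_cells = n_tumour_cells, seed = seed),
    class = "CNVSimulationConfig")
}

#' Generate synthetic CNV residual profiles with planted subclones
#'
#' Reference cells receive pure Gaussian noise; each subclone's cells
#' additionally receive `+effect_size` on windows of gained arms and
#' `-effect_size` on windows of lost arms.
#'
#' @param config A [cnv_simulation_config()].
#' @return List with `profile` (a [cnv_profile()]) and `truth` (per-cell
#'   subclone id: "reference", "diploid", or "cloneK").
#' @export
generate_cnv_profiles <- function(config) {
  stopifnot(inherits(config, "CNVSimulationConfig"))
  windows <- config$windows
  arm_of <- assign_windows_to_arms(windows, config$cytoband)
  n_w <- nrow(windows)
  fractions <- vapply(config$subclones, `[[`, numeric(1), "fraction")
  n_clone <- floor(fractions * config$n_tumour_cells)
  n_diploid <- config$n_tumour_cells - sum(n_clone)
  labels <- c(rep("reference", config$n_reference_cells),
              rep("diploid", n_diploid),
              rep(sprintf("clone%d", seq_along(config$subclones)), n_clone))
  n_cells <- length(labels)
  cell_ids <- sprintf("CNV%05d", seq_len(n_cells))
  with_seed(config$seed, {
    res <- matrix(stats::rnorm(n_cells * n_w, 0, config$noise_sd),
                  nrow = n_cells)
    for (k in seq_along(config$subclones)) {
      sc <- config$subclones[[k]]
      rows <- labels == sprintf("clone%d", k)
      ev <- sc$arm_events
      for (i in seq_len(nrow(ev))) {
        cols <- which(arm_of$chrom == ev$chrom[i] & arm_of$arm == ev$arm[i])
        sign <- if (ev$direction[i] == "gain") 1 else -1
        res[rows, cols] <- res[rows, cols] + sign * sc$effect_size
      }
    }
    profile <- cnv_profile(res, windows, cell_ids,
                           reference_cell_ids = cell_ids[labels == "reference"])
    truth <- data.frame(cell_id = cell_ids, subclone = labels,
                        stringsAsFactors = FALSE)
    list(profile = profile, truth = truth)
  })
}

#' Configuration for the survival cohort simulator
#'
#' @param n_patients Cohort size.
#' @param baseline_hazard Exponential event hazard (per month) of the
#'   low-risk group.
#' @param true_hr Planted hazard ratio of the high-risk group.
#' @param signature_genes Genes whose (log2) expression is shifted upward by
#'   +2 in the high-risk group.
#' @param censor_rate Probability that a patient is independently censored
#'   (at a uniform time before their event).
#' @param seed Integer seed.
#' @return A `SurvivalSimulationConfig` list.
#' @export
survival_simulation_config <- function(n_patients = 200,
                                       baseline_hazard = 0.05,
                                       true_hr = 1.5,
                                       signature_genes = sprintf("SIG%02d", 1:10),
                                       censor_rate = 0.2,
                                       seed = 1) {
  if (censor_rate >= 1 || censor_rate < 0) {
    stopf("censor_rate must be in [0, 1)")
  }
  if (baseline_hazard <= 0 || true_hr <= 0) {
    stopf("baseline_hazard and true_hr must be positive")
  }
  structure(
    list(n_patients = n_patients, baseline_hazard = baseline_hazard,
         true_hr = true_hr, signature_genes = signature_genes,
         censor_rate = censor_rate, seed = seed),
    class = "SurvivalSimulationConfig")
}

# log2 expression shift separating the high-risk group's signature genes
SURV_SIGNATURE_SHIFT <- 2

#' Generate a synthetic survival cohort with signature expression
#'
#' Event times are exponential with hazard `baseline_hazard * true_hr^z`
#' where the latent risk group `z` also drives signature-gene expression
#' upward by a fixed +2 log2 shift; censoring is independent Bernoulli at
#' `censor_rate` with censor times uniform before the event.
#'
#' @param config A [survival_simulation_config()].
#' @return List with `table` (patient_id, time, event, one column per
#'   signature gene on the linear expression scale) and `truth` (per-patient
#'   latent risk group).
#' @export
generate_survival_cohort <- function(config) {
  stopifnot(inherits(config, "SurvivalSimulationConfig"))
  n <- config$n_patients
  genes <- config$signature_genes
  with_seed(config$seed, {
    z <- stats::rbinom(n, 1, 0.5)
    hazard <- config$baseline_hazard * config$true_hr^z
    t_event <- stats::rexp(n, rate = hazard)
    censored <- stats::rbinom(n, 1, config$censor_rate)
    time <- ifelse(censored == 1, stats::runif(n) * t_event, t_event)
    mu_g <- stats::runif(length(genes), 2, 6)
    l <- matrix(mu_g, nrow = n, ncol = length(genes), byrow = TRUE) +
      SURV_SIGNATURE_SHIFT * z +
      matrix(stats::rnorm(n * length(genes)), nrow = n)
    expr <- 2^l - 1
    expr[expr < 0] <- 0
    colnames(expr) <- genes
    table <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                        time = time, event = 1L - censored,
                        stringsAsFactors = FALSE)
    table <- cbind(table, as.data.frame(expr))
    truth <- data.frame(patient_id = table$patient_id, risk_group = z,
                        stringsAsFactors = FALSE)
    list(table = table, truth = truth)
  })
}
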