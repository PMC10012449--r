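# Configuration-driven orchestration of the whole synthetic end-to-end
# analysis: simulate -> preprocess -> cell composition -> EWAS -> ORA ->
# proximity enrichment -> replication, with a JSON manifest recording
# seeds, parameters and per-stage row counts so any run can be
# reproduced from the manifest alone.

#' Build a validated pipeline configuration
#'
#' All numeric parameters of every stage in one validated list. Unknown
#' keys are rejected; every parameter is range-checked. The single
#' `seed` fans out to fixed per-stage child seeds recorded in the run
#' manifest.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_samples = 50L, n_probes = 2000L, n_cell_types = 3L,
    noise_sd = 0.1,
    n_interaction_probes = 5L, interaction_t = 8,
    refactor_d = 5L, refactor_t = 500L, refactor_k = 3L,
    detection_p = 0.01, detection_sample_fraction = 0.05,
    m_total = NULL,
    n_gene_sets = 20L, ora_excess = 3,
    gwas_group_size = 200L, cluster_fraction = 0.5,
    cluster_distance = 10000L,
    distances = default_distances(),
    replication_window = 5000L, replication_q = 0.05,
    replication_fraction = 0.5,
    seed = 1L,
    outdir = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  stopifnot(cfg$n_samples >= 10, cfg$n_probes >= 10,
            cfg$n_cell_types >= 1, cfg$noise_sd >= 0,
            cfg$n_interaction_probes >= 0,
            cfg$refactor_k >= 1, cfg$refactor_k <= cfg$refactor_t,
            cfg$detection_p > 0, cfg$detection_p < 1,
            cfg$detection_sample_fraction > 0,
            cfg$detection_sample_fraction < 1,
            all(cfg$distances > 0),
            cfg$replication_window >= 0,
            cfg$replication_q > 0, cfg$replication_q < 1,
            cfg$cluster_fraction >= 0, cfg$cluster_fraction <= 1,
            cfg$seed == as.integer(cfg$seed))
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes all stages in order on synthetic data generated under the
#' configuration, optionally writing every stage table as TSV plus a JSON
#' manifest to `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a results bundle: `samples`, `truth`, `ewas`,
#'   `components`, `plots`, `ora`, `success_ratios`, `group_comparison`,
#'   `locus_enrichment`, `replication`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  # deterministic per-stage child seeds, kept inside 32-bit integer range
  child <- function(i) as.integer((as.numeric(seed) * 131 + i) %% 2147483647)

  t0 <- Sys.time()
  log_stage <- function(name, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(name, ": ", ...)))
  }
  counts <- list()

  # --- simulate -----------------------------------------------------------
  samples <- generate_cohort(config$n_samples, seed = child(1L))
  b3 <- planted_effect_size(samples, t_target = config$interaction_t,
                            noise_sd = max(config$noise_sd, 1e-8))
  effects <- list()
  if (config$n_interaction_probes > 0) {
    effects$interaction <- data.frame(
      probe = seq_len(config$n_interaction_probes), effect = b3)
  }
  sim <- generate_methylome(samples, config$n_probes, config$n_cell_types,
                            effects = effects, noise_sd = config$noise_sd,
                            seed = child(2L))
  counts$samples <- nrow(samples)
  counts$probes_simulated <- config$n_probes
  log_stage("simulate", config$n_samples, " samples x ",
            config$n_probes, " probes")

  # --- preprocess ---------------------------------------------------------
  det <- filter_detection(sim$intensities, config$detection_p,
                          config$detection_sample_fraction)
  beta <- compute_beta(normalize_intensities(det$intensities))
  mvals <- beta_to_m(beta)
  filt <- filter_probes(mvals, sim$annotation)
  counts$probes_after_detection <- nrow(det$intensities$m_signal)
  counts$probes_after_filters <- nrow(filt$matrix)
  log_stage("preprocess", counts$probes_after_filters, " probes kept (",
            nrow(det$dropped), " detection, ",
            sum(filt$counts), " chrY/SNP)")

  # --- cell composition ---------------------------------------------------
  comps <- refactor_components(filt$matrix, d = config$refactor_d,
                               t = min(config$refactor_t,
                                       nrow(filt$matrix)),
                               k = config$refactor_k)
  log_stage("cellcomp", "k = ", config$refactor_k, " components")

  # --- EWAS ---------------------------------------------------------------
  ewas <- run_ewas(filt$matrix, samples, comps, annotation = sim$annotation,
                   m_total = config$m_total)
  plots <- plot_tables(ewas)
  counts$ewas_rows <- nrow(ewas)
  n_gw <- sum(classify_significance(ewas$interaction_p,
                                    ewas$interaction_fdr) == "genome_wide")
  log_stage("ewas", nrow(ewas), " probes tested, ", n_gw,
            " genome-wide (interaction)")

  # --- gene sets / ORA ----------------------------------------------------
  nominal <- ewas$probe_id[ewas$interaction_p < 0.05]
  universe <- map_cpgs_to_genes(ewas$probe_id, sim$annotation)
  query <- map_cpgs_to_genes(nominal, sim$annotation)
  sets <- generate_gene_sets(config$n_gene_sets, universe,
                             enriched_set = list(genes = query,
                                                 excess = config$ora_excess),
                             seed = child(3L))
  ora <- if (length(query)) hypergeom_ora(query, sets, universe) else NULL
  counts$ora_sets <- length(sets)
  log_stage("ora", length(query), " query genes vs ", length(sets), " sets")

  # --- proximity enrichment ----------------------------------------------
  top <- ewas[order(ewas$interaction_p), ][seq_len(min(20L, nrow(ewas))), ]
  targets <- data.frame(cpg_id = top$probe_id, chromosome = top$chromosome,
                        position = top$position, gene = top$gene,
                        stringsAsFactors = FALSE)
  groups <- c(Phen1 = config$gwas_group_size, Phen2 = config$gwas_group_size,
              Phen3 = config$gwas_group_size, Phen4 = config$gwas_group_size)
  catalog <- generate_gwas_catalog(
    groups, probe_targets = targets,
    clustering = list(Phen1 = list(fraction = config$cluster_fraction,
                                   distance = config$cluster_distance)),
    seed = child(4L))
  sr <- success_ratios(targets, catalog, config$distances)
  at_d <- sr[sr$max_distance == config$cluster_distance, ]
  cmp <- compare_groups(at_d$success_ratio[at_d$group == "Phen1"],
                        at_d$success_ratio[at_d$group == "Phen4"])
  enrich <- locus_enrichment(targets, catalog, "Phen1", "Phen4",
                             config$distances)
  counts$snps <- nrow(catalog)
  log_stage("gwasprox", "Phen1 vs Phen4 Mann-Whitney p = ",
            signif(cmp$p_value, 3))

  # --- replication --------------------------------------------------------
  validation <- synth_validation_table(targets, config$replication_window,
                                       config$replication_fraction,
                                       seed = child(5L))
  rep <- vicinity_match(targets, validation,
                        window = config$replication_window,
                        q_threshold = config$replication_q)
  counts$replicated <- sum(rep$results$validated)
  log_stage("replication", counts$replicated, "/", nrow(rep$results),
            " CpGs validated")

  manifest <- list(
    package_version = as.character(utils::packageVersion("interewas")),
    r_version = R.version.string,
    seed = seed,
    child_seeds = stats::setNames(as.list(vapply(1:5, child, 1L)),
                                  c("cohort", "methylome", "gene_sets",
                                    "gwas_catalog", "validation")),
    parameters = unclass(config)[setdiff(names(config), "outdir")],
    row_counts = counts,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  bundle <- list(samples = samples, truth = sim$truth,
                 annotation = sim$annotation, ewas = ewas,
                 components = comps, plots = plots, ora = ora,
                 success_ratios = sr, group_comparison = cmp,
                 locus_enrichment = enrich, replication = rep,
                 manifest = manifest)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    write_tsv_table(samples, out("samples.tsv"))
    write_ewas_results(ewas, out("ewas_interaction.tsv"))
    write_components(comps, out("components.tsv"))
    if (!is.null(plots$manhattan)) {
      write_tsv_table(plots$manhattan, out("manhattan.tsv"))
    }
    write_tsv_table(plots$qq, out("qq.tsv"))
    write_tsv_table(plots$volcano, out("volcano.tsv"))
    if (!is.null(ora)) write_tsv_table(ora, out("ora.tsv"))
    write_tsv_table(sr, out("success_ratios.tsv"))
    write_tsv_table(enrich, out("locus_enrichment.tsv"))
    write_tsv_table(rep$results, out("replication.tsv"))
    write_tsv_table(rep$matches, out("replication_matches.tsv"))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(bundle)
}

#' Synthesise a validation-study association table
#'
#' Places, for a configured fraction of the target CpGs, a significant
#' (q < 0.05) validation site within the replication window; remaining
#' sites are placed far away or left non-significant, so the replication
#' stage has known positives and negatives.
#'
#' @param targets Data.frame `cpg_id`, `chromosome`, `position`.
#' @param window Replication window in bp.
#' @param fraction Fraction of targets given a nearby significant site.
#' @param seed Optional seed.
#' @return Data.frame `site_id`, `chromosome`, `position`, `q_value`.
#' @export
synth_validation_table <- function(targets, window = 5000, fraction = 0.5,
                                   seed = NULL) {
  with_seed(seed, {
    n <- nrow(targets)
    near <- stats::runif(n) < fraction
    offset <- sample(seq(-window, window), n, replace = TRUE)
    pos <- ifelse(near, targets$position + offset,
                  targets$position + window * 50 +
                    sample(1000:100000, n, replace = TRUE))
    q <- ifelse(near, stats::runif(n, 1e-6, 0.049),
                stats::runif(n, 0.05, 1))
    data.frame(site_id = sprintf("val%04d", seq_len(n)),
               chromosome = targets$chromosome,
               position = pmax(1L, as.integer(pos)),
               q_value = q, stringsAsFactors = FALSE)
  })
}

#' Summarise a pipeline results bundle
#'
#' @param bundle Results bundle from [run_pipeline()].
#' @return Character vector of markdown lines (also printed invisibly by
#'   `cat` when assigned).
#' @export
summarize_run <- function(bundle) {
  ew <- bundle$ewas
  lines <- c("# Pipeline run summary", "")
  if (is.null(ew) || nrow(ew) == 0) {
    lines <- c(lines, "No probes tested; zero significant loci.")
    return(lines)
  }
  for (eff in c("interaction", "ic50", "smoking")) {
    tier <- classify_significance(ew[[paste0(eff, "_p")]],
                                  ew[[paste0(eff, "_fdr")]])
    lines <- c(lines, sprintf(
      "- %s effect: %d genome-wide, %d suggestive of %d probes",
      eff, sum(tier == "genome_wide"), sum(tier == "suggestive"),
      nrow(ew)))
  }
  top <- ew[order(ew$interaction_p), ][seq_len(min(5L, nrow(ew))), ]
  lines <- c(lines, "", "Top interaction probes:",
             sprintf("  %s  coef=%.3g  p=%.3g  fdr=%.3g", top$probe_id,
                     top$interaction_coef, top$interaction_p,
                     top$interaction_fdr))
  if (!is.null(bundle$ora) && nrow(bundle$ora)) {
    lines <- c(lines, "", sprintf(
      "- ORA: %d/%d sets with adjusted p < 0.05",
      sum(bundle$ora$p_adjust < 0.05), nrow(bundle$ora)))
  }
  if (!is.null(bundle$group_comparison)) {
    lines <- c(lines, sprintf(
      "- Proximity enrichment (relevant vs control) Mann-Whitney p = %.3g",
      bundle$group_comparison$p_value))
  }
  if (!is.null(bundle$replication)) {
    r <- bundle$replication$results
    lines <- c(lines, sprintf(
      "- Replication: %d/%d CpGs validated (fraction %.2f)",
      sum(r$validated), nrow(r), mean(r$validated)))
  }
  lines
}
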