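# Synthetic cohorts, methylomes, GWAS catalogs and gene sets with recorded
# ground truth. The generator emulates the structure the analysis assumes:
# an EPIC-style intensity table over a small all-female cohort with a
# lifetime-cigarette exposure, an ex vivo IC50 phenotype, latent cell-type
# mixing, and optional planted main/interaction effects on the M-value
# scale.

#' Default cohort generation parameters
#'
#' The defaults reproduce the published cohort's structure: 34 female
#' donors aged 40-66, a 12/16/6 never/past/current smoker mixture,
#' lifetime cigarette counts up to 268,800 (log-uniform among
#' ever-smokers), and IC50 values (µM) from a log-normal centred on the
#' published median 0.28 µM truncated to the published range
#' [0.061, 9.49].
#'
#' @param age_range Integer bounds for age in years.
#' @param smoker_mix Named probabilities for classes never/past/current.
#' @param cig_range Lifetime cigarette count range for ever-smokers
#'   (log-uniform draw).
#' @param ic50_range Truncation bounds for IC50 in µM.
#' @param ic50_meanlog,ic50_sdlog Log-normal parameters for IC50.
#' @return A named list of parameters.
#' @export
cohort_config <- function(age_range = c(40L, 66L),
                          smoker_mix = c(never = 12, past = 16, current = 6) / 34,
                          cig_range = c(500, 268800),
                          ic50_range = c(0.061, 9.49),
                          ic50_meanlog = log(0.28),
                          ic50_sdlog = 1.2) {
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2],
            length(cig_range) == 2L, all(cig_range > 0),
            length(ic50_range) == 2L, all(ic50_range > 0),
            ic50_range[1] < ic50_range[2], ic50_sdlog >= 0)
  if (abs(sum(smoker_mix) - 1) > 1e-8) {
    stop("smoker_mix probabilities must sum to 1")
  }
  if (ic50_sdlog == 0) {
    stop("degenerate IC50 distribution: ic50_sdlog must be > 0")
  }
  if (cig_range[1] >= cig_range[2]) {
    stop("degenerate cigarette distribution: cig_range must have spread")
  }
  list(age_range = age_range, smoker_mix = smoker_mix,
       cig_range = cig_range, ic50_range = ic50_range,
       ic50_meanlog = ic50_meanlog, ic50_sdlog = ic50_sdlog)
}

#' Generate a synthetic donor cohort
#'
#' Draws ages uniformly on the configured range, smoker classes from the
#' configured mixture, lifetime cigarette counts (0 for never-smokers,
#' log-uniform otherwise) and IC50 values from a truncated log-normal.
#'
#' @param n_samples Number of donors (>= 2).
#' @param config See [cohort_config()].
#' @param seed Optional integer seed; the same seed reproduces the table
#'   exactly.
#' @return A data.frame with columns `sample_id`, `age`,
#'   `cigarettes_total`, `ic50`, `smoker_class`.
#' @export
generate_cohort <- function(n_samples, config = cohort_config(), seed = NULL) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2) {
    stop("n_samples must be a single number >= 2")
  }
  n_samples <- as.integer(n_samples)
  with_seed(seed, {
    age <- sample(seq(config$age_range[1], config$age_range[2]),
                  n_samples, replace = TRUE)
    cls <- sample(names(config$smoker_mix), n_samples, replace = TRUE,
                  prob = config$smoker_mix)
    cig <- numeric(n_samples)
    ever <- cls != "never"
    if (any(ever)) {
      lo <- log(config$cig_range[1]); hi <- log(config$cig_range[2])
      cig[ever] <- round(exp(stats::runif(sum(ever), lo, hi)))
    }
    # inverse-CDF draw from the truncated log-normal keeps IC50 inside the
    # configured range with a fixed number of RNG calls
    plo <- stats::plnorm(config$ic50_range[1], config$ic50_meanlog, config$ic50_sdlog)
    phi <- stats::plnorm(config$ic50_range[2], config$ic50_meanlog, config$ic50_sdlog)
    u <- stats::runif(n_samples, plo, phi)
    ic50 <- stats::qlnorm(u, config$ic50_meanlog, config$ic50_sdlog)
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n_samples)),
      age = as.integer(age),
      cigarettes_total = cig,
      ic50 = ic50,
      smoker_class = cls,
      stringsAsFactors = FALSE
    )
  })
}

#' Default methylome generation parameters
#'
#' @param total_intensity Fixed per-probe total signal S; intensities are
#'   synthesised so that beta = m_signal/(m_signal + u_signal + 100) holds
#'   exactly with m_signal + u_signal + 100 = S.
#' @param baseline_mean,baseline_sd Per-probe baseline M-value
#'   distribution.
#' @param dirichlet_alpha Dirichlet concentration for per-sample cell-type
#'   proportions (scalar or one value per cell type).
#' @param informative_frac Fraction of probes carrying cell-type effects.
#' @param cell_effect_sd SD of cell-type effect sizes (M-value units).
#' @param chrX_frac,chrY_frac Fractions of probes placed on the sex
#'   chromosomes (chrY probes exist to exercise the QC filters).
#' @param snp_overlap_frac Fraction of probes flagged as physically
#'   overlapping a SNP.
#' @param multi_gene_frac,empty_gene_frac Fractions of probes annotated to
#'   two ";"-joined genes or to no gene.
#' @param detect_fail_frac Fraction of probes given failing detection
#'   p-values in `detect_fail_samples` samples.
#' @param detect_fail_samples Number of samples failing for such probes.
#' @param genome Data.frame (`chromosome`, `length`) giving the desk-scale
#'   genome model used for probe placement.
#' @return A named parameter list.
#' @export
methylome_config <- function(total_intensity = 10000,
                             baseline_mean = 0,
                             baseline_sd = 1.5,
                             dirichlet_alpha = 2,
                             informative_frac = 0.2,
                             cell_effect_sd = 1,
                             chrX_frac = 0.02,
                             chrY_frac = 0.01,
                             snp_overlap_frac = 0.05,
                             multi_gene_frac = 0.1,
                             empty_gene_frac = 0.2,
                             detect_fail_frac = 0,
                             detect_fail_samples = 2L,
                             genome = default_genome()) {
  stopifnot(total_intensity > 200, baseline_sd >= 0,
            all(dirichlet_alpha > 0),
            informative_frac >= 0, informative_frac <= 1,
            chrX_frac >= 0, chrY_frac >= 0, snp_overlap_frac >= 0)
  list(total_intensity = total_intensity, baseline_mean = baseline_mean,
       baseline_sd = baseline_sd, dirichlet_alpha = dirichlet_alpha,
       informative_frac = informative_frac, cell_effect_sd = cell_effect_sd,
       chrX_frac = chrX_frac, chrY_frac = chrY_frac,
       snp_overlap_frac = snp_overlap_frac,
       multi_gene_frac = multi_gene_frac, empty_gene_frac = empty_gene_frac,
       detect_fail_frac = detect_fail_frac,
       detect_fail_samples = as.integer(detect_fail_samples),
       genome = genome)
}

#' Desk-scale genome model
#'
#' @param n_autosomes Number of autosomes.
#' @param autosome_length Length in bp of each autosome.
#' @param sex_length Length of the X and Y models.
#' @return Data.frame with columns `chromosome` and `length`.
#' @export
default_genome <- function(n_autosomes = 2L, autosome_length = 1e7,
                           sex_length = 5e6) {
  data.frame(
    chromosome = c(as.character(seq_len(n_autosomes)), "X", "Y"),
    length = c(rep(autosome_length, n_autosomes), sex_length, sex_length),
    stringsAsFactors = FALSE
  )
}

#' Dirichlet draw (n rows, one concentration vector)
#' @noRd
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Generate a synthetic methylome with ground truth
#'
#' Composes, per probe j and sample i, an M-value
#' \deqn{M_{ji} = \mu_j + \sum_c w_{ic}\delta_{jc} + b_{1j}\,\mathrm{IC50}_i
#'   + b_{2j}\,\mathrm{Smk}_i + b_{3j}\,\mathrm{IC50}_i\mathrm{Smk}_i
#'   + b_{4j}\,\mathrm{Age}_i + \varepsilon_{ji}}
#' with cell proportions \eqn{w} drawn from a Dirichlet and
#' \eqn{\varepsilon \sim N(0, \mathrm{noise\_sd}^2)}, then converts it to a
#' beta value by the inverse base-2 logit and emits a
#' methylated/unmethylated intensity pair satisfying
#' beta = m/(m + u + 100) exactly at the configured total signal.
#'
#' @param samples Cohort table from [generate_cohort()].
#' @param n_probes Number of probes (>= 1).
#' @param n_cell_types Number of latent cell types (>= 1).
#' @param effects Named list of planted effects; allowed names are
#'   `ic50_main`, `smoking_main`, `interaction`, `age`. Each element is a
#'   data.frame with columns `probe` (index in 1..n_probes) and `effect`
#'   (M-value units per covariate unit).
#' @param noise_sd Residual SD on the M-value scale (>= 0).
#' @param config See [methylome_config()].
#' @param seed Optional integer seed.
#' @return A list with elements `intensities` (an `intensity_table`),
#'   `annotation` (probe annotation data.frame) and `truth` (a
#'   `truth_record` list: `cell_proportions`, `cell_effects`,
#'   `effect_probes`, `noise_sd`, `seed`).
#' @export
generate_methylome <- function(samples, n_probes, n_cell_types = 3L,
                               effects = list(), noise_sd = 0.1,
                               config = methylome_config(), seed = NULL) {
  stopifnot(is.data.frame(samples), n_probes >= 1, n_cell_types >= 1)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  allowed <- c("ic50_main", "smoking_main", "interaction", "age")
  if (length(effects) && !all(names(effects) %in% allowed)) {
    stop("unknown effect kind(s): ",
         paste(setdiff(names(effects), allowed), collapse = ", "))
  }
  for (ef in effects) {
    stopifnot(is.data.frame(ef), all(c("probe", "effect") %in% names(ef)))
    if (any(ef$probe < 1 | ef$probe > n_probes)) {
      stop("effect references a probe outside 1..n_probes")
    }
  }
  n_probes <- as.integer(n_probes)
  n <- nrow(samples)
  probe_ids <- sprintf("cg%07d", seq_len(n_probes))

  with_seed(seed, {
    alpha <- config$dirichlet_alpha
    if (length(alpha) == 1L) alpha <- rep(alpha, n_cell_types)
    w <- rdirichlet(n, alpha)
    rownames(w) <- samples$sample_id
    colnames(w) <- sprintf("cell%d", seq_len(n_cell_types))

    baseline <- stats::rnorm(n_probes, config$baseline_mean, config$baseline_sd)
    delta <- matrix(0, n_probes, n_cell_types,
                    dimnames = list(probe_ids, colnames(w)))
    # planted-effect probes carry no cell-type signal, so recovery of the
    # planted coefficients is scored against the nominal noise level
    has_effect <- logical(n_probes)
    for (ef in effects) has_effect[ef$probe] <- TRUE
    informative <- stats::runif(n_probes) < config$informative_frac &
      !has_effect
    if (any(informative)) {
      delta[informative, ] <- stats::rnorm(sum(informative) * n_cell_types,
                                           sd = config$cell_effect_sd)
    }

    eff_mat <- matrix(0, n_probes, 4L,
                      dimnames = list(NULL, allowed))
    for (kind in names(effects)) {
      ef <- effects[[kind]]
      eff_mat[ef$probe, kind] <- ef$effect
    }
    X_eff <- cbind(ic50_main = samples$ic50,
                   smoking_main = samples$cigarettes_total,
                   interaction = samples$ic50 * samples$cigarettes_total,
                   age = as.numeric(samples$age))

    mvals <- matrix(baseline, n_probes, n, byrow = FALSE) +
      delta %*% t(w) +
      eff_mat %*% t(X_eff)
    if (noise_sd > 0) {
      mvals <- mvals + matrix(stats::rnorm(n_probes * n, sd = noise_sd),
                              n_probes, n)
    }
    dimnames(mvals) <- list(probe_ids, samples$sample_id)

    S <- config$total_intensity
    beta <- 2^mvals / (1 + 2^mvals)
    beta <- pmin(pmax(beta, 1e-6), (S - 100) / S)
    m_signal <- beta * S
    u_signal <- S - m_signal - 100

    detection_p <- matrix(stats::runif(n_probes * n, 0, 0.005), n_probes, n,
                          dimnames = dimnames(mvals))
    if (config$detect_fail_frac > 0) {
      n_fail <- round(config$detect_fail_frac * n_probes)
      if (n_fail > 0) {
        fail_probes <- sample(n_probes, n_fail)
        for (j in fail_probes) {
          cols <- sample(n, min(config$detect_fail_samples, n))
          detection_p[j, cols] <- stats::runif(length(cols), 0.02, 0.5)
        }
      }
    }

    annotation <- random_annotation(probe_ids, config)

    effect_probes <- lapply(effects, function(ef) {
      data.frame(probe_id = probe_ids[ef$probe], effect = ef$effect,
                 stringsAsFactors = FALSE)
    })
    truth <- structure(
      list(cell_proportions = w, cell_effects = delta,
           effect_probes = effect_probes, noise_sd = noise_sd,
           seed = seed),
      class = "truth_record"
    )
    list(
      intensities = intensity_table(m_signal, u_signal, detection_p),
      annotation = annotation,
      truth = truth
    )
  })
}

#' Random probe annotation under the desk-scale genome model
#' @noRd
random_annotation <- function(probe_ids, config) {
  n_probes <- length(probe_ids)
  genome <- config$genome
  autosomes <- genome$chromosome[!genome$chromosome %in% c("X", "Y")]
  u <- stats::runif(n_probes)
  chrom <- character(n_probes)
  chrom[u < config$chrY_frac] <- "Y"
  isX <- u >= config$chrY_frac & u < config$chrY_frac + config$chrX_frac
  chrom[isX] <- "X"
  rest <- chrom == ""
  chrom[rest] <- sample(autosomes, sum(rest), replace = TRUE)
  len <- genome$length[match(chrom, genome$chromosome)]
  position <- floor(stats::runif(n_probes, 1, len + 1))
  snp_overlap <- stats::runif(n_probes) < config$snp_overlap_frac
  gene_pool <- sprintf("GENE%04d", seq_len(max(50L, ceiling(n_probes / 4))))
  g1 <- sample(gene_pool, n_probes, replace = TRUE)
  g2 <- sample(gene_pool, n_probes, replace = TRUE)
  u2 <- stats::runif(n_probes)
  gene <- g1
  gene[u2 < config$multi_gene_frac] <-
    paste(g1[u2 < config$multi_gene_frac],
          g2[u2 < config$multi_gene_frac], sep = ";")
  gene[u2 >= 1 - config$empty_gene_frac] <- ""
  data.frame(probe_id = probe_ids, chromosome = chrom,
             position = as.integer(position), gene = gene,
             snp_overlap = snp_overlap, stringsAsFactors = FALSE)
}

#' Planted effect size for a target t-statistic
#'
#' Given the cohort's realised covariates, returns the per-unit effect b
#' such that the expected OLS t-statistic of the chosen term is
#' approximately `t_target` at residual SD `noise_sd`:
#' b = t_target * noise_sd * sqrt([(X'X)^{-1}]_{kk}) for the design
#' (1, IC50, Smoking, IC50*Smoking, Age).
#'
#' @param samples Cohort table.
#' @param t_target Target expected |t|.
#' @param noise_sd Residual SD on the M-value scale.
#' @param kind One of `ic50_main`, `smoking_main`, `interaction`, `age`.
#' @return A single effect size (M-value units per covariate unit).
#' @export
planted_effect_size <- function(samples, t_target = 8, noise_sd = 0.1,
                                kind = "interaction") {
  X <- cbind(1, samples$ic50, samples$cigarettes_total,
             samples$ic50 * samples$cigarettes_total,
             as.numeric(samples$age))
  k <- match(kind, c("ic50_main", "smoking_main", "interaction", "age")) + 1L
  if (is.na(k)) stop("unknown effect kind: ", kind)
  v <- diag(solve(crossprod(X)))[k]
  t_target * noise_sd * sqrt(v)
}

#' Generate a phenotype-grouped SNP catalog
#'
#' For each phenotype group a configured fraction of SNPs is planted
#' within a configured distance of randomly chosen CpG targets; the
#' remainder are placed uniformly on the genome model. The `planted`
#' column records the ground truth.
#'
#' @param groups Named integer vector: group label -> number of SNPs.
#' @param probe_targets Data.frame (`chromosome`, `position`) of target
#'   CpGs; may be NULL when no group has nonzero clustering.
#' @param clustering Named list: group label -> `list(fraction, distance)`.
#'   Groups absent from the list get fraction 0.
#' @param genome Genome model as in [default_genome()].
#' @param seed Optional integer seed.
#' @return Data.frame with columns `snp_id`, `chromosome`, `position`,
#'   `pvalue`, `group`, `planted`.
#' @export
generate_gwas_catalog <- function(groups, probe_targets = NULL,
                                  clustering = list(),
                                  genome = default_genome(), seed = NULL) {
  stopifnot(length(groups) >= 1, all(groups >= 1), !is.null(names(groups)))
  for (g in names(clustering)) {
    fr <- clustering[[g]]$fraction
    stopifnot(fr >= 0, fr <= 1, clustering[[g]]$distance > 0)
    if (fr > 0 && (is.null(probe_targets) || nrow(probe_targets) == 0)) {
      stop("nonzero clustering fraction requires probe targets")
    }
  }
  placeable <- genome[!genome$chromosome %in% "Y", , drop = FALSE]
  with_seed(seed, {
    out <- lapply(names(groups), function(g) {
      n <- groups[[g]]
      cl <- clustering[[g]] %||% list(fraction = 0, distance = 1)
      n_cl <- round(cl$fraction * n)
      chrom <- character(n); pos <- numeric(n)
      planted <- c(rep(TRUE, n_cl), rep(FALSE, n - n_cl))
      if (n_cl > 0) {
        idx <- sample(nrow(probe_targets), n_cl, replace = TRUE)
        d <- cl$distance
        off <- sample(seq(-(d - 1), d - 1), n_cl, replace = TRUE)
        chrom[seq_len(n_cl)] <- as.character(probe_targets$chromosome[idx])
        lens <- placeable$length[match(norm_chrom(chrom[seq_len(n_cl)]),
                                       norm_chrom(placeable$chromosome))]
        pos[seq_len(n_cl)] <- pmin(pmax(probe_targets$position[idx] + off, 1),
                                   lens)
      }
      if (n_cl < n) {
        i <- seq(n_cl + 1, n)
        ch <- sample(placeable$chromosome, length(i), replace = TRUE,
                     prob = placeable$length)
        chrom[i] <- ch
        pos[i] <- floor(stats::runif(length(i), 1,
                                     placeable$length[match(ch, placeable$chromosome)] + 1))
      }
      data.frame(
        snp_id = sprintf("%s_rs%05d", g, seq_len(n)),
        chromosome = chrom, position = as.integer(pos),
        pvalue = 10^(-stats::runif(n, -log10(5e-6), 12)),
        group = g, planted = planted, stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Generate a gene-set collection
#'
#' Draws `n_sets` random sets from the universe. If `enriched_set` is
#' given, the first set over-samples the provided genes by the stated
#' excess: it contains `excess` times the chance-expected number of those
#' genes (capped by the set and query sizes), so over-representation
#' analysis has planted signal of known strength.
#'
#' @param n_sets Number of sets (0 gives an empty collection).
#' @param universe Character vector of gene symbols.
#' @param set_size_range Bounds for the (uniform) set sizes.
#' @param enriched_set Optional `list(genes = character, excess = numeric)`.
#' @param seed Optional integer seed.
#' @return Named list of character vectors, GMT-writable via [write_gmt()].
#' @export
generate_gene_sets <- function(n_sets, universe, set_size_range = c(10, 50),
                               enriched_set = NULL, seed = NULL) {
  stopifnot(n_sets >= 0, set_size_range[1] >= 1)
  if (set_size_range[2] > length(universe)) {
    stop("requested set size exceeds universe size")
  }
  if (n_sets == 0) return(stats::setNames(list(), character(0)))
  with_seed(seed, {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]),
                    n_sets, replace = TRUE)
    sets <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      if (i == 1L && !is.null(enriched_set)) {
        marked <- intersect(universe, enriched_set$genes)
        expected <- sizes[i] * length(marked) / length(universe)
        n_in <- min(round(enriched_set$excess * expected),
                    sizes[i], length(marked))
        rest <- setdiff(universe, marked)
        sets[[i]] <- c(sample(marked, n_in),
                       sample(rest, sizes[i] - n_in))
      } else {
        sets[[i]] <- sample(universe, sizes[i])
      }
    }
    stats::setNames(sets, sprintf("SET%03d", seq_len(n_sets)))
  })
}

#' Write a truth record to a JSON sidecar
#'
#' @param truth A `truth_record` from [generate_methylome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_record <- function(truth, path) {
  x <- list(
    cell_proportions = as.data.frame(truth$cell_proportions),
    effect_probes = truth$effect_probes,
    noise_sd = truth$noise_sd,
    seed = truth$seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
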