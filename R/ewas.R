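# Per-CpG interaction EWAS. Every probe is regressed on the same design
#   DNAm = b0 + b1*IC50 + b2*Smoking + b3*IC50*Smoking + b4*Age
#          + b5*PC1 + ... + b(4+k)*PCk
# by ordinary least squares, with two-sided t-tests on b1 (IC50 main
# effect), b2 (smoking main effect) and b3 (the smoking-dependent
# association of IC50 with methylation, the headline statistic).
# Because the design is shared across probes the fit is vectorised: one
# QR decomposition, all probes solved at once.

#' Build the interaction design matrix
#' @noRd
build_design <- function(samples, components = NULL, center = FALSE) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "age", "cigarettes_total", "ic50") %in%
                  names(samples)))
  ic50 <- samples$ic50
  smk <- samples$cigarettes_total
  age <- as.numeric(samples$age)
  if (center) {
    ic50 <- ic50 - mean(ic50)
    smk <- smk - mean(smk)
    age <- age - mean(age)
  }
  X <- cbind(`(Intercept)` = 1, ic50 = ic50, smoking = smk,
             interaction = ic50 * smk, age = age)
  if (!is.null(components)) {
    pcs <- if (inherits(components, "composition_components")) {
      components$components
    } else {
      as.matrix(components)
    }
    idx <- match(samples$sample_id, rownames(pcs))
    if (anyNA(idx)) stop("components missing sample(s): ",
                         paste(utils::head(samples$sample_id[is.na(idx)], 3),
                               collapse = ", "))
    X <- cbind(X, pcs[idx, , drop = FALSE])
  }
  rownames(X) <- samples$sample_id
  X
}

#' Vectorised OLS for many probes sharing one design
#' @noRd
ols_many <- function(Y, X) {
  n <- ncol(Y)
  p <- ncol(X)
  if (n <= p) stop("need more samples (", n, ") than predictors (", p, ")")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, p)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- t(qr.coef(qx, t(Y)))              # probes x p
  fitted <- coef %*% t(X)
  res <- Y - fitted
  df <- n - p
  sigma2 <- rowSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))[order(qx$pivot)]
  se <- sqrt(outer(sigma2, xtx_inv_diag))
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df)
  # degenerate probes: zero residual variance makes se = 0; by convention
  # a constant-y probe reports zero effects with p = 1, while an exactly
  # noiseless planted effect reports the smallest representable p
  degen <- sigma2 < 1e-24
  if (any(degen)) {
    zero_coef <- abs(coef[degen, , drop = FALSE]) < 1e-10
    tdeg <- tval[degen, , drop = FALSE]
    pdeg <- pval[degen, , drop = FALSE]
    tdeg[zero_coef] <- 0
    pdeg[zero_coef] <- 1
    pdeg[!zero_coef] <- .Machine$double.xmin
    tval[degen, ] <- tdeg
    pval[degen, ] <- pdeg
  }
  pval <- pmax(pval, .Machine$double.xmin)
  dimnames(coef) <- dimnames(se) <- dimnames(tval) <- dimnames(pval) <-
    list(rownames(Y), colnames(X))
  list(coef = coef, se = se, t = tval, p = pval, df = df,
       sigma2 = sigma2)
}

#' Fit the interaction model for a single probe
#'
#' Ordinary least squares of one probe's M-values on intercept, IC50,
#' smoking (lifetime cigarettes), their product, age, and the supplied
#' cell-composition components, with two-sided t-tests on the three
#' effects of interest using n - p residual degrees of freedom.
#'
#' @param y Numeric vector of M-values, one per sample, aligned to
#'   `samples$sample_id` (or named by sample id).
#' @param samples Cohort covariate table.
#' @param components Optional `composition_components` (or samples x k
#'   matrix with sample rownames).
#' @param center Centre covariates before forming the interaction
#'   (default FALSE: raw scales).
#' @return Data.frame with one row per tested effect (`ic50_main`,
#'   `smoking_main`, `interaction`) and columns `coefficient`, `t_value`,
#'   `p_value`.
#' @export
fit_interaction_model <- function(y, samples, components = NULL,
                                  center = FALSE) {
  if (!is.null(names(y))) y <- y[samples$sample_id]
  stopifnot(length(y) == nrow(samples), !anyNA(y))
  X <- build_design(samples, components, center = center)
  fit <- ols_many(matrix(y, nrow = 1, dimnames = list("y", samples$sample_id)),
                  X)
  eff <- c(ic50_main = "ic50", smoking_main = "smoking",
           interaction = "interaction")
  data.frame(
    effect = names(eff),
    coefficient = as.numeric(fit$coef[1, eff]),
    t_value = as.numeric(fit$t[1, eff]),
    p_value = as.numeric(fit$p[1, eff]),
    stringsAsFactors = FALSE
  )
}

#' Run the interaction EWAS across all probes
#'
#' Applies the interaction model to every probe of an M-value matrix and
#' attaches Benjamini-Hochberg FDR per effect across all tested probes.
#'
#' @param matrix M-value matrix (probes x samples), scale-tagged
#'   `"mvalue"` (see [beta_to_m()]).
#' @param samples Cohort covariate table; `sample_id` must match the
#'   matrix columns.
#' @param components Optional cell-composition components.
#' @param annotation Optional probe annotation; when given, chromosome,
#'   position and gene columns are attached.
#' @param m_total Number of tests used for the FDR adjustment (defaults
#'   to the number of fitted probes).
#' @param center Centre covariates before forming the interaction.
#' @return Data.frame with one row per probe: `probe_id`, per-effect
#'   `<effect>_coef`, `<effect>_t`, `<effect>_p`, `<effect>_fdr` for
#'   effects `ic50`, `smoking`, `interaction`, plus annotation columns if
#'   supplied.
#' @export
run_ewas <- function(matrix, samples, components = NULL, annotation = NULL,
                     m_total = NULL, center = FALSE) {
  stopifnot(is.matrix(matrix))
  sc <- methylation_scale(matrix)
  if (!is.null(sc) && sc != "mvalue") {
    stop("run_ewas expects an M-value matrix; convert with beta_to_m()")
  }
  if (!setequal(colnames(matrix), samples$sample_id)) {
    stop("sample mismatch between methylation matrix and covariate table")
  }
  Y <- matrix[, samples$sample_id, drop = FALSE]
  X <- build_design(samples, components, center = center)
  fit <- ols_many(Y, X)
  m_total <- m_total %||% nrow(Y)
  out <- data.frame(probe_id = rownames(Y), stringsAsFactors = FALSE)
  eff <- c(ic50 = "ic50", smoking = "smoking", interaction = "interaction")
  for (nm in names(eff)) {
    col <- eff[[nm]]
    out[[paste0(nm, "_coef")]] <- fit$coef[, col]
    out[[paste0(nm, "_t")]] <- fit$t[, col]
    out[[paste0(nm, "_p")]] <- fit$p[, col]
    out[[paste0(nm, "_fdr")]] <- bh_fdr(fit$p[, col], m_total)
  }
  if (!is.null(annotation)) {
    idx <- match(out$probe_id, annotation$probe_id)
    out$chromosome <- annotation$chromosome[idx]
    out$position <- annotation$position[idx]
    out$gene <- annotation$gene[idx]
  }
  rownames(out) <- NULL
  attr(out, "df") <- fit$df
  attr(out, "m_total") <- m_total
  out
}

#' Benjamini-Hochberg step-up adjustment with an explicit test count
#'
#' Computes adjusted values
#' \deqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, m\,p_{(j)}/j)}
#' using `m_total` as the number of tests, which may exceed the list
#' length. This supports adjusting a printed top-list (e.g. the 59
#' genome-wide CpGs) against the full epigenome-wide test count.
#'
#' @param pvalues Numeric p-values in (0, 1\].
#' @param m_total Total number of tests, >= `length(pvalues)`.
#' @return Adjusted values in the input order.
#' @export
bh_fdr <- function(pvalues, m_total = length(pvalues)) {
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  if (m_total < m) stop("m_total must be at least length(pvalues)")
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  o <- order(pvalues)
  adj_sorted <- pmin(1, m_total * pvalues[o] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Classify the significance tier of a test
#'
#' `genome_wide` when FDR < 0.05; otherwise `suggestive` when
#' p < 1e-05; otherwise `none`.
#'
#' @param p,fdr Numeric vectors (recycled together).
#' @param p_suggestive Suggestive threshold on the raw p-value.
#' @param fdr_genomewide Genome-wide threshold on the FDR.
#' @return Character vector with levels `none`, `suggestive`,
#'   `genome_wide`.
#' @export
classify_significance <- function(p, fdr, p_suggestive = 1e-5,
                                  fdr_genomewide = 0.05) {
  stopifnot(all(p > 0 & p <= 1), all(fdr >= 0 & fdr <= 1))
  out <- rep("none", length(p))
  out[p < p_suggestive] <- "suggestive"
  out[fdr < fdr_genomewide] <- "genome_wide"
  out
}

#' Export Manhattan, QQ and volcano plot tables
#'
#' @param results An EWAS result table from [run_ewas()] (annotation
#'   columns required for the Manhattan table).
#' @param effect Which effect to tabulate: `interaction` (default),
#'   `ic50`, or `smoking`.
#' @return List of data.frames `manhattan` (`probe_id`, `chromosome`,
#'   `position`, `neglog10_p`), `qq` (`expected`, `observed` -log10
#'   quantiles, sorted; expected uses i/(m+1)), `volcano` (`probe_id`,
#'   `coefficient`, `neglog10_p`, `tier`).
#' @export
plot_tables <- function(results, effect = c("interaction", "ic50",
                                            "smoking")) {
  effect <- match.arg(effect)
  if (nrow(results) == 0) stop("empty result table")
  p <- results[[paste0(effect, "_p")]]
  fdr <- results[[paste0(effect, "_fdr")]]
  coef <- results[[paste0(effect, "_coef")]]
  m <- length(p)
  manhattan <- NULL
  if (all(c("chromosome", "position") %in% names(results))) {
    manhattan <- data.frame(probe_id = results$probe_id,
                            chromosome = results$chromosome,
                            position = results$position,
                            neglog10_p = -log10(p),
                            stringsAsFactors = FALSE)
  }
  o <- order(p)
  qq <- data.frame(expected = -log10(seq_len(m) / (m + 1)),
                   observed = -log10(p[o]))
  volcano <- data.frame(probe_id = results$probe_id,
                        coefficient = coef,
                        neglog10_p = -log10(p),
                        tier = classify_significance(p, fdr),
                        stringsAsFactors = FALSE)
  list(manhattan = manhattan, qq = qq, volcano = volcano)
}

#' Write an EWAS result table as TSV
#'
#' Columns mirror the published top-hits layout (CpG id, coefficient,
#' t-value, p-value, chromosome, position, FDR, gene) for the chosen
#' effect.
#'
#' @param results Result table from [run_ewas()].
#' @param path Output path.
#' @param effect Effect to export.
#' @return `path`, invisibly.
#' @export
write_ewas_results <- function(results, path,
                               effect = c("interaction", "ic50",
                                          "smoking")) {
  effect <- match.arg(effect)
  df <- data.frame(
    cpg_id = results$probe_id,
    coefficient = results[[paste0(effect, "_coef")]],
    t_value = results[[paste0(effect, "_t")]],
    p_value = results[[paste0(effect, "_p")]],
    chromosome = results$chromosome %||% NA,
    position = results$position %||% NA,
    fdr = results[[paste0(effect, "_fdr")]],
    gene = results$gene %||% NA,
    stringsAsFactors = FALSE
  )
  write_tsv_table(df, path)
}
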