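# CpG-SNP proximity enrichment. For a CpG and a phenotype-grouped SNP
# catalog, the "success ratio" at maximal distance D is the fraction of
# the group's SNPs lying strictly within D bp of the CpG on the same
# chromosome. Ratios are computed over an incremental distance ladder and
# compared between a relevant phenotype group and a negative-control
# group by a one-tailed Mann-Whitney U test; per-locus enrichment is
# additionally tested by a one-sided Fisher exact test on within-D
# counts.

#' Default incremental distance ladder (bp)
#' @export
default_distances <- function() c(1000L, 2500L, 5000L, 10000L, 25000L, 50000L)

#' Filter GWAS dataset metadata
#'
#' Keeps datasets flagged high-confidence with estimated SNP heritability
#' h2 > `h2_min` and heritability z-score >= `h2_z_min`.
#'
#' @param metadata Data.frame with columns `confidence`, `h2`, `h2_z`
#'   (other columns pass through).
#' @param h2_min Heritability threshold (strict), default 0.01.
#' @param h2_z_min Heritability z-score threshold (inclusive), default 7.
#' @return The retained rows of `metadata`.
#' @export
filter_gwas_datasets <- function(metadata, h2_min = 0.01, h2_z_min = 7) {
  need <- c("confidence", "h2", "h2_z")
  missing <- setdiff(need, names(metadata))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  keep <- metadata$confidence == "high" & metadata$h2 > h2_min &
    metadata$h2_z >= h2_z_min
  metadata[which(keep), , drop = FALSE]
}

#' Filter a SNP catalog on association p-value
#'
#' By default retains GWAS-suggestive SNPs (p < `p_max`), since proximity
#' enrichment is computed over SNPs showing association; `keep = "above"`
#' inverts the rule.
#'
#' @param catalog SNP catalog with a `pvalue` column.
#' @param p_max Threshold, default 5e-6.
#' @param keep `"below"` (default) or `"above"`.
#' @return The retained catalog rows.
#' @export
filter_snps <- function(catalog, p_max = 5e-6, keep = c("below", "above")) {
  keep <- match.arg(keep)
  sel <- if (keep == "below") catalog$pvalue < p_max else
    catalog$pvalue >= p_max
  catalog[which(sel), , drop = FALSE]
}

#' Per-CpG success ratios over a distance ladder
#'
#' A SNP is a "success" for a CpG at maximal distance D when it lies on
#' the same chromosome and |SNP position - CpG position| < D (strict).
#' Cross-chromosome pairs never count. One row is emitted per CpG x
#' group x distance; a group with zero SNPs yields a missing ratio with a
#' warning.
#'
#' @param cpgs Data.frame with columns `cpg_id`, `chromosome`,
#'   `position`.
#' @param catalog SNP catalog with `chromosome`, `position`, `group`.
#' @param distances Positive distances in bp, default
#'   [default_distances()].
#' @return Data.frame `cpg_id`, `group`, `max_distance`, `successes`,
#'   `group_total`, `success_ratio`.
#' @export
success_ratios <- function(cpgs, catalog, distances = default_distances()) {
  stopifnot(all(distances > 0), nrow(cpgs) > 0)
  distances <- sort(as.integer(distances))
  groups <- unique(catalog$group)
  cat_chrom <- norm_chrom(catalog$chromosome)
  cpg_chrom <- norm_chrom(cpgs$chromosome)
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    in_g <- catalog$group == g
    total <- sum(in_g)
    if (total == 0) {
      warning("group ", g, " has zero SNPs; ratios set to NA")
    }
    gpos <- catalog$position[in_g]
    gchr <- cat_chrom[in_g]
    res <- matrix(0L, nrow(cpgs), length(distances))
    for (i in seq_len(nrow(cpgs))) {
      same <- gchr == cpg_chrom[i]
      if (any(same)) {
        dd <- abs(gpos[same] - cpgs$position[i])
        res[i, ] <- vapply(distances, function(D) sum(dd < D), 0L)
      }
    }
    rows[[gi]] <- data.frame(
      cpg_id = rep(cpgs$cpg_id, times = length(distances)),
      group = g,
      max_distance = rep(distances, each = nrow(cpgs)),
      successes = as.integer(res),
      group_total = total,
      success_ratio = if (total > 0) as.integer(res) / total else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U statistic (with 0.5 per tie)
#' @noRd
mw_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' One-tailed Mann-Whitney U comparison of success ratios
#'
#' Tests whether values in `a` tend to exceed those in `b`
#' (`alternative = "greater"`). For small samples (combined size <=
#' `exact_limit` by default 12) the p-value is exact, computed by
#' enumerating all assignments of the pooled values to the two groups
#' (which handles ties naturally); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative `"greater"` (a tends larger) or `"less"`.
#' @param exact_limit Maximal combined size for exact enumeration.
#' @return List with `U` (statistic for the first sample), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
compare_groups <- function(a, b, alternative = c("greater", "less"),
                           exact_limit = 12L) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (alternative == "less") {
    res <- compare_groups(b, a, "greater", exact_limit)
    return(list(U = mw_u(a, b), p_value = res$p_value, method = res$method))
  }
  u_obs <- mw_u(a, b)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  if (N <= exact_limit) {
    pooled <- c(a, b)
    combs <- utils::combn(N, n1)
    us <- apply(combs, 2L, function(idx) mw_u(pooled[idx], pooled[-idx]))
    p <- mean(us >= u_obs - 1e-9)
    return(list(U = u_obs, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- (u_obs - mu - 0.5) / sigma
  list(U = u_obs, p_value = stats::pnorm(z, lower.tail = FALSE),
       method = "normal")
}

#' Per-locus proximity enrichment (Fisher one-sided)
#'
#' For each CpG and each distance D, counts the relevant-group and
#' control-group SNPs falling within D and tests the 2x2 table
#' (within/beyond x relevant/control) for an excess of relevant SNPs near
#' the CpG by a one-sided Fisher exact test (hypergeometric upper tail).
#' P-values are BH-adjusted across loci separately at each distance.
#'
#' @param cpgs Data.frame `cpg_id`, `chromosome`, `position` and
#'   optionally `gene`.
#' @param catalog SNP catalog.
#' @param relevant_group,control_group Group labels present in
#'   `catalog$group`.
#' @param distances Distance ladder in bp.
#' @return Data.frame with one row per CpG x distance: `cpg_id`, `gene`,
#'   `max_distance`, `relevant_within`, `control_within`, `p_value`,
#'   `fdr`.
#' @export
locus_enrichment <- function(cpgs, catalog, relevant_group, control_group,
                             distances = default_distances()) {
  stopifnot(relevant_group %in% catalog$group,
            control_group %in% catalog$group)
  sr <- success_ratios(cpgs, catalog[catalog$group %in%
                                       c(relevant_group, control_group), ],
                       distances)
  rel <- sr[sr$group == relevant_group, ]
  con <- sr[sr$group == control_group, ]
  key <- paste(rel$cpg_id, rel$max_distance)
  con <- con[match(key, paste(con$cpg_id, con$max_distance)), ]
  K_rel <- rel$group_total[1]
  K_con <- con$group_total[1]
  # one-sided Fisher on the 2x2 with fixed margins is the hypergeometric
  # upper tail: draws = total SNPs within D, successes = relevant SNPs
  p <- stats::phyper(rel$successes - 1, K_rel, K_con,
                     rel$successes + con$successes, lower.tail = FALSE)
  out <- data.frame(
    cpg_id = rel$cpg_id,
    gene = if ("gene" %in% names(cpgs)) {
      cpgs$gene[match(rel$cpg_id, cpgs$cpg_id)]
    } else NA_character_,
    max_distance = rel$max_distance,
    relevant_within = rel$successes,
    control_within = con$successes,
    p_value = p,
    stringsAsFactors = FALSE
  )
  out$fdr <- NA_real_
  for (D in unique(out$max_distance)) {
    i <- out$max_distance == D
    out$fdr[i] <- bh_fdr(out$p_value[i])
  }
  rownames(out) <- NULL
  out
}

#' Per-locus summary: largest significant distance
#'
#' Mirrors the published per-gene reporting: for each locus the largest
#' tested distance at which the enrichment FDR is below the threshold,
#' with that row's p-value and FDR.
#'
#' @param enrichment Output of [locus_enrichment()].
#' @param fdr_threshold Significance threshold on the FDR.
#' @return Data.frame `cpg_id`, `gene`, `max_distance`, `p_value`, `fdr`
#'   restricted to loci significant at some distance.
#' @export
locus_max_distance <- function(enrichment, fdr_threshold = 0.05) {
  sig <- enrichment[enrichment$fdr < fdr_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(sig[, c("cpg_id", "gene", "max_distance",
                                     "p_value", "fdr")])
  sig <- sig[order(sig$cpg_id, -sig$max_distance), ]
  best <- sig[!duplicated(sig$cpg_id), ]
  rownames(best) <- NULL
  best[, c("cpg_id", "gene", "max_distance", "p_value", "fdr")]
}

#' Histogram table of log2 success ratios
#'
#' Summarises, per group and distance, the distribution of log2 success
#' ratios across CpGs (zero ratios are dropped, as log2 is undefined).
#'
#' @param ratios Output of [success_ratios()].
#' @param binwidth Bin width on the log2 scale.
#' @return Data.frame `group`, `max_distance`, `bin_mid`, `count`.
#' @export
success_ratio_histogram <- function(ratios, binwidth = 1) {
  pos <- ratios[!is.na(ratios$success_ratio) & ratios$success_ratio > 0, ]
  if (nrow(pos) == 0) {
    return(data.frame(group = character(0), max_distance = integer(0),
                      bin_mid = numeric(0), count = integer(0)))
  }
  pos$bin <- floor(log2(pos$success_ratio) / binwidth)
  agg <- stats::aggregate(list(count = pos$bin),
                          by = list(group = pos$group,
                                    max_distance = pos$max_distance,
                                    bin = pos$bin),
                          FUN = length)
  agg$bin_mid <- (agg$bin + 0.5) * binwidth
  agg[order(agg$group, agg$max_distance, agg$bin),
      c("group", "max_distance", "bin_mid", "count")]
}
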