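# Probe-level QC and conversion between intensity, beta and M-value
# scales. The conventions follow standard Illumina array practice:
# beta = M/(M + U + 100), M-value = log2(beta/(1 - beta)), a detection
# p-value filter on "more than 5% of samples", removal of chrY and
# SNP-overlapping probes with retention of chrX (all-female cohorts).

#' Construct an intensity table
#'
#' Container for per-probe, per-sample methylated/unmethylated signals and
#' detection p-values, stored as three aligned matrices (probes x
#' samples).
#'
#' @param m_signal,u_signal Non-negative signal matrices with probe
#'   rownames and sample colnames.
#' @param detection_p Detection p-value matrix in \[0, 1\].
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(m_signal, u_signal, detection_p) {
  stopifnot(is.matrix(m_signal), is.matrix(u_signal), is.matrix(detection_p),
            identical(dim(m_signal), dim(u_signal)),
            identical(dim(m_signal), dim(detection_p)))
  if (any(m_signal < 0) || any(u_signal < 0)) {
    stop("negative intensity signal encountered")
  }
  if (any(detection_p < 0 | detection_p > 1)) {
    stop("detection p-values must lie in [0, 1]")
  }
  if (is.null(rownames(m_signal)) || is.null(colnames(m_signal))) {
    stop("m_signal must carry probe rownames and sample colnames")
  }
  structure(list(m_signal = m_signal, u_signal = u_signal,
                 detection_p = detection_p),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table:", nrow(x$m_signal), "probes x",
      ncol(x$m_signal), "samples\n")
  invisible(x)
}

#' Subset an intensity table by probe
#' @noRd
subset_intensities <- function(x, keep) {
  intensity_table(x$m_signal[keep, , drop = FALSE],
                  x$u_signal[keep, , drop = FALSE],
                  x$detection_p[keep, , drop = FALSE])
}

#' Tag a matrix with its methylation scale
#' @noRd
methylation_matrix <- function(values, scale = c("beta", "mvalue")) {
  scale <- match.arg(scale)
  attr(values, "scale") <- scale
  values
}

#' Scale tag of a methylation matrix
#'
#' @param x A matrix produced by [compute_beta()] or [beta_to_m()].
#' @return `"beta"` or `"mvalue"` (NULL for untagged matrices).
#' @export
methylation_scale <- function(x) attr(x, "scale")

#' Compute beta values from intensities
#'
#' Applies the Illumina formula beta = M/(M + U + 100) per probe and
#' sample. With non-negative signals the result lies in \[0, 1) and is
#' bounded by M/(M + 100).
#'
#' @param intensities An [intensity_table()].
#' @return A probes x samples matrix tagged with scale `"beta"`.
#' @export
compute_beta <- function(intensities) {
  stopifnot(inherits(intensities, "intensity_table"))
  m <- intensities$m_signal
  u <- intensities$u_signal
  if (any(m < 0) || any(u < 0)) stop("negative intensity signal encountered")
  methylation_matrix(m / (m + u + 100), "beta")
}

#' Convert beta values to M-values
#'
#' Base-2 logit transform M = log2(beta/(1 - beta)), preferred for linear
#' modelling because it is unbounded and closer to homoscedastic. Beta
#' values are first clipped to \[`clamp`, 1 - `clamp`\] so the transform is
#' finite at the boundary.
#'
#' @param beta A beta-scale matrix (values in \[0, 1\]).
#' @param clamp Clipping margin, default 1e-6.
#' @return A matrix tagged with scale `"mvalue"`.
#' @export
beta_to_m <- function(beta, clamp = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, clamp), 1 - clamp)
  out <- log2(b / (1 - b))
  attributes(out) <- attributes(beta)
  attr(out, "scale") <- "mvalue"
  out
}

#' Convert M-values back to beta values
#'
#' Exact inverse of [beta_to_m()] away from the clipping margin:
#' beta = 2^M / (1 + 2^M).
#'
#' @param mvalues An M-value-scale matrix.
#' @return A matrix tagged with scale `"beta"`.
#' @export
m_to_beta <- function(mvalues) {
  out <- 2^mvalues / (1 + 2^mvalues)
  attributes(out) <- attributes(mvalues)
  attr(out, "scale") <- "beta"
  out
}

#' Detection p-value probe filter
#'
#' Drops a probe when its detection p-value exceeds `p_threshold` in
#' strictly more than `sample_fraction` of the samples. With 34 samples
#' and the 5% default this means a probe failing in 2 or more samples is
#' removed (2 > 1.7) while a single failure is tolerated (1 > 1.7 is
#' false).
#'
#' @param intensities An [intensity_table()].
#' @param p_threshold Per-measurement detection p cut-off (default 0.01).
#' @param sample_fraction Tolerated failing-sample fraction (default
#'   0.05); the comparison is strict.
#' @return A list with `intensities` (filtered table) and `dropped`
#'   (data.frame `probe_id`, `n_failing`).
#' @export
filter_detection <- function(intensities, p_threshold = 0.01,
                             sample_fraction = 0.05) {
  stopifnot(inherits(intensities, "intensity_table"),
            p_threshold > 0, p_threshold < 1,
            sample_fraction > 0, sample_fraction < 1)
  if (nrow(intensities$detection_p) == 0) stop("empty intensity table")
  n <- ncol(intensities$detection_p)
  n_fail <- rowSums(intensities$detection_p > p_threshold)
  drop <- n_fail > sample_fraction * n
  list(
    intensities = subset_intensities(intensities, !drop),
    dropped = data.frame(probe_id = rownames(intensities$detection_p)[drop],
                         n_failing = unname(n_fail[drop]),
                         stringsAsFactors = FALSE)
  )
}

#' Chromosome and SNP-overlap probe filter
#'
#' Removes probes on the Y chromosome and probes physically overlapping a
#' SNP. X-linked probes are retained (appropriate for all-female
#' cohorts). When a probe matches both rules the recorded reason is
#' `"chrY"` (rule precedence).
#'
#' @param matrix A methylation matrix (beta or M-value scale) with probe
#'   rownames.
#' @param annotation Probe annotation data.frame with columns `probe_id`,
#'   `chromosome`, `position`, `gene`, `snp_overlap`.
#' @return A list with `matrix` (filtered), `dropped` (data.frame
#'   `probe_id`, `reason`) and `counts` (per-reason drop counts).
#' @export
filter_probes <- function(matrix, annotation) {
  probes <- rownames(matrix)
  if (is.null(probes)) stop("matrix must carry probe rownames")
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx)) {
    stop("probe(s) missing from annotation: ",
         paste(utils::head(probes[is.na(idx)], 3), collapse = ", "))
  }
  ann <- annotation[idx, ]
  chrom <- norm_chrom(ann$chromosome)
  is_y <- chrom == "Y"
  is_snp <- as.logical(ann$snp_overlap) & !is_y
  reason <- rep(NA_character_, length(probes))
  reason[is_y] <- "chrY"
  reason[is_snp] <- "snp_overlap"
  drop <- is_y | is_snp
  out <- matrix[!drop, , drop = FALSE]
  attr(out, "scale") <- attr(matrix, "scale")
  list(
    matrix = out,
    dropped = data.frame(probe_id = probes[drop], reason = reason[drop],
                         stringsAsFactors = FALSE),
    counts = c(chrY = sum(is_y), snp_overlap = sum(is_snp))
  )
}

#' Normalization hook
#'
#' Placeholder stage in the pipeline graph where array normalization
#' (e.g. functional normalization on raw control-probe data) would sit.
#' The identity default documents that no between-array normalization is
#' applied to synthetic intensities.
#'
#' @param intensities An [intensity_table()].
#' @param method Only `"none"` is implemented.
#' @return The input, unchanged.
#' @export
normalize_intensities <- function(intensities, method = c("none")) {
  method <- match.arg(method)
  intensities
}
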