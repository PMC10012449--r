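# Reference-free cell-composition adjustment. Whole blood mixes several
# cell types whose methylomes differ, so between-sample differences in
# composition confound association tests. Rather than estimating absolute
# cell counts against a reference panel, this module computes sample-level
# components correlated with the (unobserved) cell-type proportions:
# an unsupervised feature-selection step keeps the probes best explained
# by a low-rank structure of assumed dimension d, and PCA on those probes
# yields the component scores used as covariates downstream.

#' Reference-free cell-composition components
#'
#' Implements the feature-selection-plus-PCA scheme: (i) each probe is
#' standardized across samples; (ii) a rank-`d` approximation of the
#' standardized matrix is formed from its top `d` principal directions;
#' (iii) probes are ranked by the Euclidean distance between their
#' observed profile and the rank-`d` reconstruction; (iv) the `t`
#' lowest-distance probes are selected; (v) PCA on the selected
#' sub-matrix returns the first `k` sample-score components, which act as
#' linear transformations of the cell-type composition.
#'
#' Zero-variance probes cannot be standardized and are excluded with a
#' warning before selection. Component signs follow a fixed convention
#' (the first selected probe, in name order, with a dominant loading is
#' made positive), so the output is fully deterministic and stable under
#' sample reordering.
#'
#' @param mvalues M-value matrix, probes x samples, complete (no missing
#'   values).
#' @param d Assumed number of cell types (rank of the approximation),
#'   default 5.
#' @param t Number of probes to select, default 500.
#' @param k Number of components to return, default 3.
#' @return An object of class `composition_components`: list with
#'   `components` (samples x k score matrix, columns `PC1..PCk`),
#'   `selected_probes` (character), and `parameters`.
#' @export
refactor_components <- function(mvalues, d = 5L, t = 500L, k = 3L) {
  stopifnot(is.matrix(mvalues), d >= 1, k >= 1, k <= t)
  if (anyNA(mvalues)) stop("mvalues must be complete (no missing values)")
  n <- ncol(mvalues)
  sds <- apply(mvalues, 1L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance probe(s) excluded from ",
            "standardization")
  }
  x <- mvalues[keep, , drop = FALSE]
  if (t > nrow(x)) {
    stop("t (", t, ") exceeds the ", nrow(x), " usable probes")
  }
  d <- min(as.integer(d), n - 1L, nrow(x))
  # samples x probes, each probe standardized across samples
  z <- t((x - rowMeans(x)) / sds[keep])
  sv <- svd(z, nu = d, nv = d)
  zd <- sv$u %*% (sv$d[seq_len(d)] * t(sv$v))
  dist <- sqrt(colSums((z - zd)^2))
  sel <- order(dist)[seq_len(t)]
  selected <- colnames(z)[sel]
  # PCA on the selected probes in stable (name) order so the sign
  # convention references the same probe regardless of selection ranking
  sel <- sel[order(selected)]

  pc <- stats::prcomp(z[, sel, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(as.integer(k), ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: the first probe (name order) carrying a dominant
  # loading is made positive; stable even when many |loadings| tie
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    j0 <- min(which(abs(load) >= 0.5 * max(abs(load))))
    if (load[j0] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(mvalues)
  structure(
    list(components = scores, selected_probes = selected,
         parameters = list(d = d, t = as.integer(t), k = k)),
    class = "composition_components"
  )
}

#' @export
print.composition_components <- function(x, ...) {
  p <- x$parameters
  cat("composition_components: k =", p$k, "components from t =", p$t,
      "selected probes (assumed d =", p$d, "cell types)\n")
  invisible(x)
}

#' Write component scores as TSV
#'
#' @param components A `composition_components` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_components <- function(components, path) {
  df <- data.frame(sample_id = rownames(components$components),
                   components$components, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}
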