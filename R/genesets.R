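# CpG-to-gene mapping and hypergeometric over-representation analysis
# (ORA). A query gene list (genes linked to associated CpGs) is tested
# against each set of a GMT collection: with universe size N, K set
# members in the universe, a query of size n and overlap k, the one-sided
# upper-tail p-value is P(X >= k) for X ~ Hypergeometric(N, K, n).

#' Map CpGs to their annotated genes
#'
#' Splits ";"-separated gene fields, drops empty annotations, and
#' deduplicates while preserving first-seen order.
#'
#' @param cpgs Character vector of probe ids.
#' @param annotation Probe annotation with `probe_id` and `gene` columns.
#' @return Character vector of unique gene symbols.
#' @export
map_cpgs_to_genes <- function(cpgs, annotation) {
  idx <- match(cpgs, annotation$probe_id)
  if (anyNA(idx)) {
    stop("unknown probe id(s): ",
         paste(utils::head(cpgs[is.na(idx)], 3), collapse = ", "))
  }
  genes <- unlist(strsplit(annotation$gene[idx], ";", fixed = TRUE))
  genes <- genes[!is.na(genes) & nzchar(genes)]
  unique(genes)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query list within
#' the universe. Sets and query are first intersected with the universe;
#' duplicates are ignored. P-values are adjusted across sets by
#' Benjamini-Hochberg; the `q_value` column equals the BH-adjusted value
#' (a separate Storey-type estimator is deliberately not used, so the two
#' columns coincide by construction).
#'
#' @param query Character vector of query genes.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of background genes.
#' @return Data.frame with columns `set_id`, `description`, `bg_count`
#'   (K), `universe_size` (N), `query_size` (n), `overlap` (k),
#'   `p_value`, `p_adjust`, `q_value`, ordered by p-value.
#' @export
hypergeom_ora <- function(query, sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  query <- unique(intersect(query, universe))
  n <- length(query)
  if (n == 0) stop("empty query after intersection with the universe")
  descriptions <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  rows <- lapply(names(sets), function(id) {
    members <- unique(intersect(sets[[id]], universe))
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    desc <- if (id %in% names(descriptions)) unname(descriptions[[id]]) else ""
    data.frame(set_id = id,
               description = desc,
               bg_count = K, universe_size = N, query_size = n,
               overlap = k, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- bh_fdr(out$p_value)
  out$q_value <- out$p_adjust
  out[order(out$p_value), , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Uses
#' `fgsea::gmtPathways()` when available, with an equivalent built-in
#' parser otherwise.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with a `descriptions`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- ids
  }
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "", ""), ids)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to the
#'   `descriptions` attribute or empty strings).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]] %||% "", sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
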