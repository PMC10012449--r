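#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a fixed RNG seed, restoring the RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Normalize chromosome labels ("chr1" and "1" both map to "1")
#' @noRd
norm_chrom <- function(x) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  out[out %in% c("x")] <- "X"
  out[out %in% c("y")] <- "Y"
  out
}

#' Read a tab-separated table with a header
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by
#' all tables in this package (no factors, no quoting surprises).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' Write a table as TSV
#'
#' @param x A data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Published top interaction CpGs bundled with the package
#'
#' Returns the table of the 59 CpG sites reported genome-wide significant
#' for the smoking-dependent (interaction) association between whole-blood
#' DNA methylation and the zoledronic acid IC50 of donor-derived
#' osteoclasts: per CpG the regression coefficient (M-value units),
#' t-value, p-value, genomic location, FDR, linked gene symbol(s)
#' (";"-separated when a CpG maps to several genes) and whether a bone
#' mineral density association was reported within 5 kb.
#'
#' These published summary statistics are used as a worked example for the
#' Benjamini-Hochberg arithmetic (see [bh_fdr()]) and as a realistic input
#' for the replication and enrichment demos.
#'
#' @return A data.frame with columns `locus`, `cpg_id`, `coefficient`,
#'   `t_value`, `p_value`, `chromosome`, `position`, `fdr`, `gene`,
#'   `bmd_vicinity`.
#' @export
discovery_top59 <- function() {
  path <- system.file("extdata", "discovery_top59.tsv",
                      package = "interewas", mustWork = TRUE)
  out <- read_tsv_table(path)
  out$gene[is.na(out$gene)] <- ""
  out$chromosome <- as.character(out$chromosome)
  out
}
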