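# Vicinity-based replication. A discovery CpG counts as validated when
# some site of an external validation study lies on the same chromosome
# within a window (default +/- 5 kb, inclusive) and is significant there
# at q < 0.05 (strict). Matching is done against a sorted per-chromosome
# position index so each query is O(log n) in the validation table size.

#' Match discovery CpGs to nearby significant validation sites
#'
#' @param discovery Data.frame with `cpg_id`, `chromosome`, `position`.
#' @param validation Data.frame with `site_id`, `chromosome`, `position`,
#'   `q_value`.
#' @param window Matching window in bp (inclusive), default 5000.
#' @param q_threshold Significance threshold on the validation q-value
#'   (strict), default 0.05.
#' @return List with `results` (one row per discovery CpG: `cpg_id`,
#'   `chromosome`, `position`, `n_matches`, `nearest_site`,
#'   `nearest_distance`, `validated`) and `matches` (long form, nearest
#'   first per CpG: `cpg_id`, `site_id`, `distance`, `q_value`).
#' @export
vicinity_match <- function(discovery, validation, window = 5000,
                           q_threshold = 0.05) {
  stopifnot(window >= 0, q_threshold > 0)
  dchr <- norm_chrom(discovery$chromosome)
  vchr <- norm_chrom(validation$chromosome)
  if (!identical(as.character(discovery$chromosome), dchr) ||
      !identical(as.character(validation$chromosome), vchr)) {
    warning("chromosome labels normalized ('chrN' and 'N' treated alike)")
  }
  sig <- validation[validation$q_value < q_threshold, , drop = FALSE]
  schr <- vchr[validation$q_value < q_threshold]
  # sorted per-chromosome index
  index <- lapply(split(seq_len(nrow(sig)), schr), function(i) {
    i[order(sig$position[i])]
  })
  res <- data.frame(cpg_id = discovery$cpg_id,
                    chromosome = discovery$chromosome,
                    position = discovery$position,
                    n_matches = 0L,
                    nearest_site = NA_character_,
                    nearest_distance = NA_integer_,
                    validated = FALSE,
                    stringsAsFactors = FALSE)
  match_rows <- list()
  for (i in seq_len(nrow(discovery))) {
    idx <- index[[dchr[i]]]
    if (is.null(idx)) next
    pos <- sig$position[idx]
    lo <- findInterval(discovery$position[i] - window - 1, pos) + 1L
    hi <- findInterval(discovery$position[i] + window, pos)
    if (hi < lo) next
    hit <- idx[lo:hi]
    dist <- abs(sig$position[hit] - discovery$position[i])
    o <- order(dist)
    hit <- hit[o]; dist <- dist[o]
    res$n_matches[i] <- length(hit)
    res$nearest_site[i] <- sig$site_id[hit[1]]
    res$nearest_distance[i] <- dist[1]
    res$validated[i] <- TRUE
    match_rows[[length(match_rows) + 1L]] <- data.frame(
      cpg_id = discovery$cpg_id[i], site_id = sig$site_id[hit],
      distance = dist, q_value = sig$q_value[hit],
      stringsAsFactors = FALSE)
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(cpg_id = character(0), site_id = character(0),
               distance = integer(0), q_value = numeric(0),
               stringsAsFactors = FALSE)
  list(results = res, matches = matches)
}
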