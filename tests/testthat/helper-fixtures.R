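# Small in-code fixtures shared across tests.

toy_intensities <- function(m, u, p = NULL, probes = NULL, samples = NULL) {
  m <- as.matrix(m); u <- as.matrix(u)
  if (is.null(p)) p <- matrix(0, nrow(m), ncol(m))
  probes <- probes %||% sprintf("p%02d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- dimnames(u) <- dimnames(p) <- list(probes, samples)
  intensity_table(m, u, as.matrix(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small cohort for regression tests
toy_cohort <- function(n = 12, seed = 42) {
  generate_cohort(n, seed = seed)
}
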