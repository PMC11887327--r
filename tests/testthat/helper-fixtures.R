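# Shared fixture builders; everything is generated in code.

# A tiny counts matrix with named taxa/samples.
tiny_counts <- function(values, taxa, samples) {
  matrix(values, nrow = length(taxa), byrow = TRUE,
         dimnames = list(taxa, samples))
}

# A small complete study (counts + tree + taxonomy + metadata), cached per
# session for speed.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic(n_subjects = 30, n_visits = 3,
                                   genus_sizes = c(1L, 3L, 4L, 6L),
                                   sparsity = 0.6, seed = 42)
    }
    cache
  }
})

# Evaluate the log-CPM formula directly (closed-form oracle).
log_cpm_formula <- function(c, lib, cdot = 1) {
  log2((c + cdot / 2) / (lib + cdot) * 1e6 + 1)
}
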