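# Cached synthetic records so expensive fixtures are generated once per run.
.synth_cache <- new.env(parent = emptyenv())

cached_record <- function(seed, duration_s = 180, snr_db = Inf, ...) {
  key <- paste(seed, duration_s, snr_db, ..., sep = "_")
  if (is.null(.synth_cache[[key]])) {
    .synth_cache[[key]] <- generate_record(
      synthetic_spec(duration_s = duration_s, snr_db = snr_db, seed = seed, ...))
  }
  .synth_cache[[key]]
}

# AC detection accuracy of an annotation against generator truth, counting
# unannotated beats in the denominator (beats after the initialization block).
ac_accuracy <- function(ann, truth, n_it = 60L, tol_samples = 1L) {
  b <- ann$beats
  m <- vapply(b$r, function(ri) which.min(abs(truth$r - ri)), integer(1))
  idx <- which(seq_len(nrow(b)) > n_it)
  mean(!is.na(b$ac[idx]) & abs(b$ac[idx] - truth$ac[m[idx]]) <= tol_samples)
}

ao_accuracy <- function(ann, truth, tol_samples = 1L) {
  b <- ann$beats
  m <- vapply(b$r, function(ri) which.min(abs(truth$r - ri)), integer(1))
  mean(!is.na(b$ao) & abs(b$ao - truth$ao[m]) <= tol_samples)
}
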