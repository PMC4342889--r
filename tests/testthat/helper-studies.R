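# Full Monte-Carlo study runs are expensive, and several acceptance checks
# read different aspects of the same run, so results are computed once per
# session and cached.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(study, reps = 1000L) {
  key <- sprintf("s%d_r%d", study, reps)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- run_study(study_design(study, reps = reps))
  }
  .study_cache[[key]]
}
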