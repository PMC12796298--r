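# Shared fixtures, all generated in code.

# A hand-sized two-session stimulation table with known baselines.
tiny_table <- function() {
  data.frame(
    subject_id = rep(c("a", "b"), each = 4),
    session_id = rep(c("a_s1", "b_s1"), each = 4),
    group = rep(c("HC", "MDD"), each = 4),
    isi_ms = c(0, 0, 0, 4, 0, 0, 0, 10),
    amplitude_uv = c(1, 2, 3, 4, 5, 5, 5, 5),
    stringsAsFactors = FALSE
  )
}

small_config <- function(seed = 42L, n_mdd = 6L, n_hc = 5L) {
  cohort_config(n_mdd = n_mdd, n_hc = n_hc, seed = seed)
}

# Cleaned, annotated feature table from a small synthetic cohort.
small_features <- function(seed = 42L) {
  build_feature_table(generate_cohort(small_config(seed)))$features
}

# Random stimulation tables with arbitrary session structure, for
# property-style checks.
random_sessions <- function(n_sessions, n_singles, n_paired, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sessions), function(s) {
    data.frame(
      subject_id = sprintf("s%03d", s),
      session_id = sprintf("s%03d_1", s),
      group = sample(c("HC", "MDD"), 1),
      isi_ms = c(rep(0L, n_singles), sample(c(4L, 10L, 20L), n_paired, TRUE)),
      amplitude_uv = rlnorm(n_singles + n_paired, meanlog = 5, sdlog = 0.8),
      stringsAsFactors = FALSE
    )
  }))
}
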