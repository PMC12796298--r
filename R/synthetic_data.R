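#' Paired-pulse TMS session protocol
#'
#' Describes the stimulation protocol of one test session: a set of paired
#' pulses at each interstimulus interval (ISI) randomly intermixed with a
#' block of single pulses. ISI 0 encodes a single pulse throughout the
#' package. The defaults describe a conventional intracortical
#' facilitation/inhibition protocol: 8 paired pulses at each of ISIs
#' 4, 5, 8, 10, 15 and 20 ms plus 24 single pulses, i.e. 72 pulses per
#' session, with an 80% resting-motor-threshold (RMT) conditioning stimulus
#' and a 120% RMT test stimulus. The intensities are carried as metadata
#' only; amplitudes are modelled distributionally, not biophysically.
#'
#' @param isis_ms Strictly positive, unique interstimulus intervals (ms).
#' @param n_paired_per_isi Number of paired pulses recorded at each ISI.
#' @param n_single Number of single (test-pulse only) stimulations; must be
#'   at least 1 because single pulses form the within-session baseline.
#' @param conditioning_intensity_pct_rmt,test_intensity_pct_rmt Stimulus
#'   intensities as percent of RMT (metadata only).
#'
#' @return An object of class `tms_protocol`.
#' @examples
#' p <- protocol_spec()
#' p$n_single + p$n_paired_per_isi * length(p$isis_ms) # 72 pulses
#' @export
protocol_spec <- function(isis_ms = c(4L, 5L, 8L, 10L, 15L, 20L),
                          n_paired_per_isi = 8L,
                          n_single = 24L,
                          conditioning_intensity_pct_rmt = 80,
                          test_intensity_pct_rmt = 120) {
  if (!is.numeric(isis_ms) || length(isis_ms) < 1L || anyNA(isis_ms) ||
      any(isis_ms <= 0) || any(isis_ms != round(isis_ms))) {
    stop_param("`isis_ms` must be strictly positive integers")
  }
  if (anyDuplicated(isis_ms)) stop_param("`isis_ms` must be unique")
  n_single <- check_scalar_count(n_single, "n_single", min = 1L)
  n_paired_per_isi <- check_scalar_count(n_paired_per_isi, "n_paired_per_isi", min = 0L)
  structure(
    list(
      isis_ms = as.integer(isis_ms),
      n_paired_per_isi = n_paired_per_isi,
      n_single = n_single,
      conditioning_intensity_pct_rmt = conditioning_intensity_pct_rmt,
      test_intensity_pct_rmt = test_intensity_pct_rmt
    ),
    class = "tms_protocol"
  )
}

#' Total pulses per session implied by a protocol
#' @param protocol A [protocol_spec()] object.
#' @return Integer pulse count.
#' @export
pulses_per_session <- function(protocol) {
  stopifnot(inherits(protocol, "tms_protocol"))
  protocol$n_single + protocol$n_paired_per_isi * length(protocol$isis_ms)
}

#' Group-level generative model for MEP amplitudes
#'
#' MEP peak-to-peak amplitudes are modelled as Gamma distributed. A single
#' pulse for an average subject of the group draws from
#' Gamma(`base_shape`, `base_scale`). The effective scale of any draw is
#' `base_scale` multiplied by (i) a subject-level log-normal multiplier with
#' log-sd `subject_scale_sd` (between-subject amplitude heterogeneity),
#' (ii) `group_scale_factor` (overall excitability shift of the group), and
#' (iii) for paired pulses, `isi_modulation[isi]` — the
#' facilitation (>1) or inhibition (<1) induced by the conditioning pulse at
#' that interval.
#'
#' @param base_shape Gamma shape (dimensionless, > 0).
#' @param base_scale Gamma scale (microvolts, > 0).
#' @param group_scale_factor Multiplicative scale effect of the group (> 0).
#' @param isi_modulation Named numeric vector mapping each protocol ISI (ms,
#'   as character names) to a positive paired-pulse scale factor.
#' @param subject_scale_sd Log-sd of the subject-level log-normal scale
#'   multiplier (>= 0); 0 removes between-subject heterogeneity.
#'
#' @return An object of class `tms_group_effects`.
#' @seealso [hc_effects()], [mdd_effects()] for the packaged defaults.
#' @export
group_effects <- function(base_shape = 2,
                          base_scale = 150,
                          group_scale_factor = 1,
                          isi_modulation = default_isi_modulation("HC"),
                          subject_scale_sd = 0.5) {
  base_shape <- check_positive_scalar(base_shape, "base_shape")
  base_scale <- check_positive_scalar(base_scale, "base_scale")
  group_scale_factor <- check_positive_scalar(group_scale_factor, "group_scale_factor")
  if (!is.numeric(subject_scale_sd) || length(subject_scale_sd) != 1L ||
      is.na(subject_scale_sd) || subject_scale_sd < 0) {
    stop_param("`subject_scale_sd` must be a single non-negative number")
  }
  if (!is.numeric(isi_modulation) || is.null(names(isi_modulation)) ||
      any(!nzchar(names(isi_modulation))) || any(isi_modulation <= 0)) {
    stop_param("`isi_modulation` must be a named vector of strictly positive factors")
  }
  structure(
    list(
      base_shape = base_shape,
      base_scale = base_scale,
      group_scale_factor = group_scale_factor,
      isi_modulation = isi_modulation,
      subject_scale_sd = subject_scale_sd
    ),
    class = "tms_group_effects"
  )
}

#' Default paired-pulse modulation profiles
#'
#' Packaged ISI-to-scale-factor profiles for the default protocol. Healthy
#' controls show residual inhibition at short intervals (4-5 ms) and
#' facilitation peaking at 10-15 ms; the depressed-group profile shifts the
#' whole curve toward reduced inhibition and stronger facilitation. These are
#' synthetic effect sizes chosen to be physiologically plausible, not
#' estimates from any clinical dataset.
#'
#' @param group `"HC"` or `"MDD"`.
#' @return Named numeric vector keyed by ISI in ms.
#' @export
default_isi_modulation <- function(group = c("HC", "MDD")) {
  group <- match.arg(group)
  if (group == "HC") {
    c(`4` = 0.70, `5` = 0.75, `8` = 1.10, `10` = 1.30, `15` = 1.40, `20` = 1.20)
  } else {
    c(`4` = 1.00, `5` = 1.05, `8` = 1.45, `10` = 1.70, `15` = 1.80, `20` = 1.50)
  }
}

#' @rdname default_isi_modulation
#' @export
hc_effects <- function() {
  group_effects(
    base_shape = 2, base_scale = 150, group_scale_factor = 1,
    isi_modulation = default_isi_modulation("HC"), subject_scale_sd = 0.5
  )
}

#' @rdname default_isi_modulation
#' @export
mdd_effects <- function() {
  group_effects(
    base_shape = 2, base_scale = 150, group_scale_factor = 1.25,
    isi_modulation = default_isi_modulation("MDD"), subject_scale_sd = 0.5
  )
}

#' Synthetic cohort configuration
#'
#' Bundles everything needed to simulate a study cohort: group sizes (default
#' 26 MDD and 17 healthy controls, one session per subject), the session
#' protocol, per-group generative effects and the master seed.
#'
#' @param n_mdd,n_hc Number of subjects per group (each >= 1).
#' @param protocol A [protocol_spec()].
#' @param effects_hc,effects_mdd [group_effects()] objects for each group.
#' @param seed Integer master seed; the full table is a deterministic
#'   function of the config.
#'
#' @return An object of class `tms_cohort_config`.
#' @export
cohort_config <- function(n_mdd = 26L,
                          n_hc = 17L,
                          protocol = protocol_spec(),
                          effects_hc = hc_effects(),
                          effects_mdd = mdd_effects(),
                          seed = 1L) {
  n_mdd <- check_scalar_count(n_mdd, "n_mdd", min = 1L)
  n_hc <- check_scalar_count(n_hc, "n_hc", min = 1L)
  stopifnot(inherits(protocol, "tms_protocol"),
            inherits(effects_hc, "tms_group_effects"),
            inherits(effects_mdd, "tms_group_effects"))
  for (eff in list(effects_hc, effects_mdd)) {
    want <- as.character(protocol$isis_ms)
    if (protocol$n_paired_per_isi > 0L && !setequal(names(eff$isi_modulation), want)) {
      stop_param("`isi_modulation` must be keyed exactly by the protocol ISIs: ",
                 paste(want, collapse = ", "))
    }
  }
  seed <- check_scalar_count(seed, "seed", min = 0L)
  structure(
    list(n_mdd = n_mdd, n_hc = n_hc, protocol = protocol,
         effects_hc = effects_hc, effects_mdd = effects_mdd, seed = seed),
    class = "tms_cohort_config"
  )
}

#' Simulate one TMS session
#'
#' Draws every pulse of one session from the group's Gamma model: `n_single`
#' single pulses (ISI 0) and `n_paired_per_isi` paired pulses at each
#' protocol ISI, in randomised order (paired pulses are intermixed with the
#' singles). Amplitudes are Gamma(`base_shape`, effective scale) draws where
#' the effective scale is `base_scale` x subject multiplier x
#' `group_scale_factor` x `isi_modulation[isi]` (the last factor for paired
#' pulses only). Uses the current RNG stream; seed at the caller (or use
#' [generate_cohort()]).
#'
#' @param subject_id,session_id Identifiers copied into every row.
#' @param group `"HC"` or `"MDD"` label copied into every row.
#' @param effects A [group_effects()] object.
#' @param protocol A [protocol_spec()] object.
#'
#' @return A data.frame with columns `subject_id`, `session_id`, `group`,
#'   `isi_ms` (0 = single pulse) and `amplitude_uv`.
#' @examples
#' set.seed(7)
#' s <- generate_session("s01", "MDD", mdd_effects(), protocol_spec())
#' nrow(s)               # 72
#' sum(s$isi_ms == 0)    # 24
#' @export
generate_session <- function(subject_id, group, effects, protocol,
                             session_id = paste0(subject_id, "_s1")) {
  stopifnot(inherits(effects, "tms_group_effects"),
            inherits(protocol, "tms_protocol"))
  subject_mult <- if (effects$subject_scale_sd > 0) {
    rlnorm(1L, meanlog = 0, sdlog = effects$subject_scale_sd)
  } else {
    1
  }
  isi <- c(
    rep(0L, protocol$n_single),
    rep(protocol$isis_ms, each = protocol$n_paired_per_isi)
  )
  mod <- rep(1, length(isi))
  paired <- isi > 0L
  if (any(paired)) {
    mod[paired] <- effects$isi_modulation[as.character(isi[paired])]
  }
  scale_eff <- effects$base_scale * subject_mult * effects$group_scale_factor * mod
  amp <- rgamma(length(isi), shape = effects$base_shape, scale = scale_eff)
  ord <- sample.int(length(isi))
  data.frame(
    subject_id = as.character(subject_id),
    session_id = as.character(session_id),
    group = as.character(group),
    isi_ms = isi[ord],
    amplitude_uv = amp[ord],
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort stimulation table
#'
#' One session per subject. MDD subjects are drawn from `effects_mdd`,
#' healthy controls from `effects_hc`. The result is a deterministic
#' function of the config (including its seed); the caller's RNG state is
#' left untouched.
#'
#' @param config A [cohort_config()] object.
#' @return A stimulation table (data.frame) with one row per pulse; with the
#'   default protocol and group sizes, (26 + 17) x 72 = 3096 rows.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "tms_cohort_config"))
  with_preserved_seed(config$seed, {
    ids_mdd <- sprintf("mdd%02d", seq_len(config$n_mdd))
    ids_hc <- sprintf("hc%02d", seq_len(config$n_hc))
    sessions <- c(
      lapply(ids_mdd, generate_session, group = "MDD",
             effects = config$effects_mdd, protocol = config$protocol),
      lapply(ids_hc, generate_session, group = "HC",
             effects = config$effects_hc, protocol = config$protocol)
    )
    out <- do.call(rbind, sessions)
    rownames(out) <- NULL
    out
  })
}

#' Multiply a random subset of amplitudes to create artificial outliers
#'
#' Test harness for outlier cleaning: each row is independently selected
#' with probability `fraction` and its amplitude multiplied by `multiplier`.
#' Uses the current RNG stream.
#'
#' @param table A stimulation table.
#' @param fraction Selection probability in [0, 1).
#' @param multiplier Amplitude multiplier (> 0; values > 1 create outliers).
#' @return A list with `table` (modified copy) and `indices` (altered row
#'   indices, possibly empty).
#' @export
inject_outliers <- function(table, fraction, multiplier) {
  check_stim_table(table)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1) {
    stop_param("`fraction` must be in [0, 1)")
  }
  multiplier <- check_positive_scalar(multiplier, "multiplier")
  idx <- if (fraction > 0) which(rbinom(nrow(table), 1L, fraction) == 1L) else integer(0)
  table$amplitude_uv[idx] <- table$amplitude_uv[idx] * multiplier
  list(table = table, indices = idx)
}

#' Write / read the stimulation CSV schema
#'
#' Plain UTF-8 CSV with header `subject_id, session_id, group, isi_ms,
#' amplitude_uv` and `.` as decimal separator. Extra columns (e.g. `delta`,
#' `rho` on feature tables) are preserved.
#'
#' @param table A stimulation or feature table.
#' @param path File path.
#' @return `read_stim_csv` returns the table; `write_stim_csv` returns
#'   `path` invisibly.
#' @export
write_stim_csv <- function(table, path) {
  check_stim_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stim_csv
#' @export
read_stim_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_stim_table(out)
  out
}
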