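#' Simulate a labelled cohort of synthetic heart sounds
#'
#' Generates `n_normal` normal and `n_abnormal` abnormal records with heart
#' rates drawn uniformly from `bpm_range`, per-record variation of the
#' S1/S2 carriers and the systole fraction, and abnormal components cycled
#' through `abnormal_types` with murmur gains drawn from
#' `murmur_gain_range`. Fully deterministic given `seed`.
#'
#' @param n_normal,n_abnormal class sizes.
#' @param fs sampling rate, Hz.
#' @param n_cycles cycles per record.
#' @param bpm_range uniform heart-rate range, BPM.
#' @param abnormal_types types cycled over the abnormal records; each entry
#'   is a character vector of components (a single string is one component).
#' @param murmur_gain_range uniform range for the murmur gain.
#' @param seed master integer seed.
#' @return list with `records` (list of [heart_sound_record()]), `labels`
#'   (0/1 vector) and `types` (character; `"normal"` or the component set,
#'   `+`-joined).
#' @export
simulate_cohort <- function(n_normal = 60L, n_abnormal = 60L, fs = 4000,
                            n_cycles = 8L, bpm_range = c(55, 150),
                            abnormal_types = list("systolic_murmur",
                                                  "diastolic_murmur",
                                                  "S3", "S4"),
                            murmur_gain_range = c(0.4, 0.9), seed = 1L) {
  n <- n_normal + n_abnormal
  set.seed(.derive_seed(seed, 7L))
  bpm <- stats::runif(n, bpm_range[1], bpm_range[2])
  s1f <- stats::runif(n, 40, 70)
  s2f <- stats::runif(n, 60, 110)
  sysf <- stats::runif(n, 0.30, 0.40)
  gain <- stats::runif(n, murmur_gain_range[1], murmur_gain_range[2])
  records <- vector("list", n)
  types <- character(n)
  for (i in seq_len(n)) {
    comps <- if (i <= n_normal) character(0) else
      unlist(abnormal_types[[(i - n_normal - 1L) %% length(abnormal_types) + 1L]])
    cfg <- sim_config(bpm = bpm[i], fs = fs, n_cycles = n_cycles,
                      systole_fraction = sysf[i], s1_freq = s1f[i],
                      s2_freq = s2f[i], components = comps,
                      murmur_gain = gain[i], seed = .derive_seed(seed, 100L + i))
    records[[i]] <- generate_heart_sound(cfg)
    types[i] <- if (length(comps)) paste(comps, collapse = "+") else "normal"
  }
  list(records = records, labels = c(rep(0L, n_normal), rep(1L, n_abnormal)),
       types = types)
}
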