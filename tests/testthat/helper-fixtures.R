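# Shared lightweight fixtures. The coarse geometry and reduced filter bank
# keep per-test encodes fast; full-resolution defaults are exercised in the
# acceptance suite.

g_default <- stim_geometry()
g_coarse <- stim_geometry(pixels_per_degree = 1)

spec_small <- filterbank_spec(
  orientations = seq(0, 180, length.out = 9)[-9],
  spatial_frequencies = c(0.2, 0.5),
  filter_size = 15,
  pixels_per_degree = 1
)

base_images <- function(geometry = g_default) {
  lapply(make_base_set(), render_stimulus, geometry = geometry)
}

# A deterministic synthetic trial log: one subject, given per-trial correct
# flags, one session per `session_size` trials.
make_log <- function(correct, session_size = length(correct),
                     pair_id = "p1", correction = FALSE, subject = "s1") {
  n <- length(correct)
  data.frame(
    subject = subject,
    session = ((seq_len(n) - 1) %/% session_size) + 1L,
    trial = seq_len(n),
    pair_id = pair_id,
    target_side = "left",
    chosen_side = ifelse(correct, "left", "right"),
    correct = correct,
    correction_trial = rep(correction, length.out = n),
    stage = "mixed",
    stringsAsFactors = FALSE
  )
}
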