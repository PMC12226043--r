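# CAP and cardiac waveform templates. CAPs are biphasic
# (negative-then-positive) deflections of ~1.5 ms total span, parameterized
# by an amplitude, a width factor and the relative size of the positive
# rebound. Cardiac deflections are wider and appear on both channels.

# Biphasic CAP template sampled at fs. Returns the waveform (uV) and the
# index of its alignment point (the dominant negative peak).
make_cap_template <- function(fs, width_factor = 1, amplitude_uV = 60,
                              amp_ratio = 0.6, pre_ratio = 0) {
  wf <- width_factor
  t_ms <- seq(-0.85 * wf, 0.85 * wf, by = 1000 / fs)
  w <- pre_ratio * exp(-(t_ms + 0.52 * wf)^2 / (2 * (0.16 * wf)^2)) -
    exp(-(t_ms + 0.16 * wf)^2 / (2 * (0.14 * wf)^2)) +
    amp_ratio * exp(-(t_ms - 0.26 * wf)^2 / (2 * (0.20 * wf)^2))
  w <- w / max(abs(w)) * amplitude_uV
  list(wave = w, align = which.max(abs(w)))
}

# Cardiac artifact as seen on the vagus cuff channel: a broad biphasic wave,
# clearly wider than any CAP, shared in time with the ECG channel.
make_cardiac_vagus_template <- function(fs, amplitude_uV = 100) {
  t_ms <- seq(-1.5, 3.0, by = 1000 / fs)
  w <- exp(-t_ms^2 / (2 * 0.28^2)) -
    0.25 * exp(-(t_ms - 0.8)^2 / (2 * 0.5^2))
  w <- w / max(abs(w)) * amplitude_uV
  list(wave = w, align = which.max(abs(w)))
}

# R-wave deflection on the ECG channel.
make_ecg_template <- function(fs, amplitude_uV = 200) {
  t_ms <- seq(-2, 3, by = 1000 / fs)
  w <- exp(-t_ms^2 / (2 * 0.5^2)) -
    0.25 * exp(-(t_ms - 1.4)^2 / (2 * 0.8^2)) -
    0.12 * exp(-(t_ms + 1.2)^2 / (2 * 0.6^2))
  w <- w / max(abs(w)) * amplitude_uV
  list(wave = w, align = which.max(abs(w)))
}
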