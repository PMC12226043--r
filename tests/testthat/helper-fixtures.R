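# Small in-code fixtures shared across tests.

# A minimal cohort configuration with hand-picked units; cheap enough for
# signal-level tests at full 32 kHz on short excerpts.
toy_config <- function(n_mice = 1, rates = c(3, 5, 8), burst_gain = 2.3,
                       responses = cbind(c(0.5, 0.6, -0.4),
                                         c(0.6, -0.5, -0.5)),
                       cardiac_rate = 10, noise_sd = 2.5, seed = 7L,
                       fs = 32000) {
  responses <- responses[rep_len(seq_len(nrow(responses)),
                                 length(rates)), , drop = FALSE]
  n_units <- length(rates) * n_mice
  category <- vapply(seq_len(length(rates)), function(i) {
    s1 <- sign(responses[i, 1]); s2 <- sign(responses[i, 2])
    if (s1 > 0 && s2 > 0) "increasing"
    else if (s1 < 0 && s2 < 0) "decreasing" else "mixed"
  }, character(1))
  units <- tibble::tibble(
    unit_id = sprintf("toy-u%02d", seq_len(n_units)),
    mouse_id = rep(seq_len(n_mice), each = length(rates)),
    category = rep(category, n_mice),
    overall_rate = rep(rates, n_mice),
    baseline_rate = rep(rates, n_mice) / 1.26,
    burst_gain = burst_gain,
    response_c1 = rep(responses[, 1], n_mice),
    response_c2 = rep(responses[, 2], n_mice),
    template_id = rep(seq_along(rates), n_mice),
    width_factor = rep(c(0.6, 1.05, 1.6, 2.1), 4)[seq_along(rates)],
    amp_ratio = rep(c(0.45, 0.75, 0.5, 0.8), 4)[seq_along(rates)],
    amplitude_uV = rep(c(55, 85, 70, 95), 4)[seq_along(rates)]
  )
  sim_config(
    group_label = "CON", units = units,
    resp_burst_duration = c(133.73, 12), resp_burst_period = c(649.75, 60),
    cardiac_rate = cardiac_rate, noise_sd_base = noise_sd, fs = fs,
    plans = replicate(n_mice, session_plan(), simplify = FALSE),
    seed = seed
  )
}

# Gaussian-class decoder features with a chosen class separation (in SDs).
gaussian_features <- function(n_per_class = 200, separation = 5, sd = 1,
                              n_features = 3, seed = 11) {
  withr::with_seed(seed, {
    classes <- factor(rep(c("BL", "TNF", "IL1B"), each = n_per_class),
                      levels = c("BL", "TNF", "IL1B"))
    means <- matrix(separation * sd * (0:2), nrow = 3, ncol = n_features)
    x <- do.call(rbind, lapply(1:3, function(ci) {
      matrix(rnorm(n_per_class * n_features, means[ci, 1], sd),
             ncol = n_features)
    }))
    colnames(x) <- paste0("rate_u", seq_len(n_features))
    out <- tibble::tibble(t_s = seq_len(3 * n_per_class) - 1,
                          class = classes, tibble::as_tibble(x))
    class(out) <- c("cap_features", class(out))
    out
  })
}
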