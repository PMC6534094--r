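# straightforward generator for pre/post recovery studies, written with
# plain rnorm arithmetic so it stays independent of the package's own
# simulators
gen_prepost <- function(n_patients, level, delta, post_times = c(0.3, 0.6, 1),
                        b0_sd = 0.9, b1_sd = 0.2, b2_sd = 0.05,
                        resid_sd = 0.15, seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    b0 <- rnorm(1, 0, b0_sd); b1 <- rnorm(1, 0, b1_sd)
    b2 <- rnorm(1, 0, b2_sd)
    z_pre <- level + b0 + rnorm(1, 0, resid_sd)
    z_post <- level + delta + b0 + b1 * post_times + b2 * post_times^2 +
      rnorm(length(post_times), 0, resid_sd)
    rows[[i]] <- tibble::tibble(
      patient_id = sprintf("R%05d", i),
      time_years = c(0, post_times),
      z = c(z_pre, z_post),
      post = c(FALSE, rep(TRUE, length(post_times))))
  }
  dplyr::bind_rows(rows)
}
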