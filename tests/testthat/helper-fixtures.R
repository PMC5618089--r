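# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except in the I/O tests, which write to tempdir() first.

cornicabra_only_config <- function(seed, noise_cv = 0.10, n = 9) {
  generator_config(
    varieties = list(variety_params("cornicabra", precursor_mean = 7740,
                                    humidity = 0.35, crushing_slope = 175,
                                    malax_slope_htyr = 1.20)),
    n_batches_per_variety = n, noise_cv = noise_cv, seed = seed
  )
}

arbequina_only_config <- function(seed, noise_cv = 0.10, n = 9) {
  generator_config(
    varieties = list(variety_params("arbequina", precursor_mean = 2050,
                                    humidity = 0.50, crushing_slope = 97,
                                    malax_slope_htyr = 0.30)),
    n_batches_per_variety = n, noise_cv = noise_cv, seed = seed
  )
}

# A tiny hand-built batch table: 2 cornicabra batches measured at all
# stages, lying exactly on a known model chain so fits are predictable.
exact_chain_table <- function(slope = 175, malax_htyr = 1.2,
                              malax_tyr = 0.98, K_htyr = 0.047,
                              K_tyr = 0.064, humidity = 0.35,
                              mi = c(12, 25), ole_fruit = 7740) {
  rows <- purrr::map(seq_along(mi), function(i) {
    m <- mi[i]
    crushed_htyr <- slope * m
    crushed_tyr <- m / 100 * ole_fruit
    kneaded_htyr <- malax_htyr * crushed_htyr
    kneaded_tyr <- malax_tyr * crushed_tyr
    oil_htyr <- K_htyr * kneaded_htyr / humidity
    oil_tyr <- K_tyr * kneaded_tyr / humidity
    tibble::tibble(
      batch_id = sprintf("b%d", i), variety = "cornicabra",
      stage = c("fruit", "crushed", "kneaded", "oil"),
      humidity = humidity, added_water = 0,
      mill_type = NA_character_, rpm = NA_real_, grid_mm = NA_real_,
      milling_intensity = m,
      conc_ole_glu = c(ole_fruit, ole_fruit * (1 - 3 * m / 100), NA, 0),
      conc_htyr_sec = c(0, crushed_htyr, kneaded_htyr, oil_htyr),
      conc_tyr_sec = c(0, crushed_tyr, kneaded_tyr, oil_tyr)
    )
  })
  dplyr::bind_rows(rows)
}
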