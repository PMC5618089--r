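test_that("the default configuration carries the reference cultivar parameters", {
  cfg <- default_generator_config()
  corn <- cfg$varieties$cornicabra
  arb <- cfg$varieties$arbequina
  expect_equal(corn$precursor_mean, 7740)
  expect_equal(arb$precursor_mean, 2050)
  expect_equal(corn$humidity, 0.35)
  expect_equal(arb$humidity, 0.50)
  expect_equal(corn$crushing_slope, 175)
  expect_equal(arb$crushing_slope, 97)
  expect_equal(corn$malax_slope_htyr, 1.20)
  expect_equal(arb$malax_slope_htyr, 0.30)
  expect_equal(corn$malax_slope_tyr, 0.98)
  expect_equal(corn$K_htyr, 0.047)
  expect_equal(corn$K_tyr, 0.064)
  expect_equal(cfg$n_batches_per_variety, 9L)
  expect_equal(cfg$mi_range, c(10, 30))
  expect_equal(cfg$noise_cv, 0.10)
  expect_equal(cfg$seed, 42L)
})

test_that("generation is deterministic under a seed and distinct across seeds", {
  a <- generate_dataset(default_generator_config(seed = 7L))
  b <- generate_dataset(default_generator_config(seed = 7L))
  c <- generate_dataset(default_generator_config(seed = 8L))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$conc_htyr_sec, c$conc_htyr_sec)))
  # the generator must not disturb the caller's RNG stream
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(generate_dataset(default_generator_config()))
  expect_identical(runif(1), before)
})

test_that("zero-noise datasets satisfy the stage equations exactly", {
  cfg <- default_generator_config(noise_cv = 0)
  dat <- generate_dataset(cfg)
  wide <- tidyr::pivot_wider(
    dat[, c("batch_id", "variety", "stage", "humidity", "milling_intensity",
            "conc_ole_glu", "conc_htyr_sec", "conc_tyr_sec")],
    names_from = "stage",
    values_from = dplyr::starts_with("conc_")
  )
  for (v in names(cfg$varieties)) {
    vp <- cfg$varieties[[v]]
    d <- wide[wide$variety == v, ]
    mi <- d$milling_intensity
    expect_equal(d$conc_tyr_sec_crushed, mi / 100 * d$conc_ole_glu_fruit)
    expect_equal(d$conc_htyr_sec_crushed, vp$crushing_slope * mi)
    expect_equal(d$conc_ole_glu_crushed,
                 d$conc_ole_glu_fruit * pmax(0, 1 - 3 * mi / 100))
    expect_equal(d$conc_htyr_sec_kneaded,
                 vp$malax_slope_htyr * d$conc_htyr_sec_crushed)
    expect_equal(d$conc_tyr_sec_kneaded,
                 vp$malax_slope_tyr * d$conc_tyr_sec_crushed)
    expect_equal(d$conc_htyr_sec_oil,
                 vp$K_htyr * d$conc_htyr_sec_kneaded / vp$humidity)
    expect_equal(d$conc_tyr_sec_oil,
                 vp$K_tyr * d$conc_tyr_sec_kneaded / vp$humidity)
    expect_equal(d$conc_ole_glu_oil, rep(0, nrow(d)))
  }
})

test_that("generated concentrations stay non-negative and finite under heavy noise", {
  dat <- generate_dataset(default_generator_config(noise_cv = 0.5,
                                                   seed = 123L))
  conc <- c(dat$conc_ole_glu, dat$conc_htyr_sec, dat$conc_tyr_sec)
  expect_true(all(is.finite(conc)))
  expect_true(all(conc >= 0))
  expect_equal(nrow(dat), 2 * 9 * 4)
})

test_that("single noisy replicates land within 25% of the generating values", {
  dat <- dplyr::bind_rows(
    generate_dataset(cornicabra_only_config(7)),
    generate_dataset(arbequina_only_config(7))
  )
  expect_equal(fit_crushing(dat, "cornicabra")$slope, 175, tolerance = 0.25)
  expect_equal(fit_crushing(dat, "arbequina")$slope, 97, tolerance = 0.25)
  expect_equal(fit_malaxation(dat, "cornicabra", "htyr_sec")$slope, 1.20,
               tolerance = 0.25)
  expect_equal(fit_malaxation(dat, "arbequina", "htyr_sec")$slope, 0.30,
               tolerance = 0.25)
  expect_equal(fit_malaxation(dat, NULL, "tyr_sec")$slope, 0.98,
               tolerance = 0.25)
  expect_equal(estimate_partition(dat, "htyr_sec")$K, 0.047,
               tolerance = 0.25)
  expect_equal(estimate_partition(dat, "tyr_sec")$K, 0.064,
               tolerance = 0.25)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(list()), class = "secofate_config_error")
  expect_error(default_generator_config(n_batches_per_variety = 0),
               class = "secofate_domain_error")
  expect_error(default_generator_config(mi_range = c(30, 10)),
               class = "secofate_config_error")
  expect_error(default_generator_config(noise_cv = -0.1),
               class = "secofate_domain_error")
  expect_error(generate_dataset(list(seed = 1)),
               class = "secofate_config_error")
})
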