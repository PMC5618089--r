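test_that("water fraction adds humidity and added water within (0, 1)", {
  expect_equal(water_fraction(0.35), 0.35)
  expect_equal(water_fraction(0.50), 0.50)
  expect_equal(water_fraction(0.4, 0.1), 0.5)
  rec <- batch_record("b", "cornicabra", humidity = 0.35, added_water = 0.05)
  expect_equal(water_fraction(rec), 0.40)
  expect_error(water_fraction(0), class = "secofate_domain_error")
  expect_error(water_fraction(0.7, 0.3), class = "secofate_domain_error")
})

test_that("per-sample partition coefficients invert the transfer model", {
  tbl <- tibble::tibble(
    batch_id = "p1", variety = "cornicabra",
    stage = c("kneaded", "oil"), humidity = 0.35, added_water = 0,
    mill_type = NA_character_, rpm = NA_real_, grid_mm = NA_real_,
    conc_ole_glu = NA_real_, conc_htyr_sec = c(4000, 537.1),
    conc_tyr_sec = NA_real_
  )
  m <- estimate_partition(tbl, "htyr_sec")
  expect_equal(m$K, 537.1 * 0.35 / 4000, tolerance = 1e-12)
  expect_equal(m$K, 0.047, tolerance = 1e-3)
  expect_equal(m$n, 1L)
  expect_named(m$per_sample_K, "p1")

  # C_oil = C_kneaded with w = 1 - eps gives K ~ 1; C_oil = 0 gives K = 0
  tbl$humidity <- 0.999999
  tbl$conc_htyr_sec <- c(4000, 4000)
  expect_equal(estimate_partition(tbl, "htyr_sec")$K, 1, tolerance = 1e-5)
  tbl$conc_htyr_sec <- c(4000, 0)
  expect_equal(estimate_partition(tbl, "htyr_sec")$K, 0)
})

test_that("zero-kneaded pairs are skipped with a warning, not errors", {
  tbl <- dplyr::bind_rows(
    tibble::tibble(batch_id = "a", variety = "v", stage = c("kneaded", "oil"),
                   humidity = 0.35, added_water = 0,
                   mill_type = NA_character_, rpm = NA_real_,
                   grid_mm = NA_real_, conc_ole_glu = NA_real_,
                   conc_htyr_sec = c(0, 10), conc_tyr_sec = NA_real_),
    tibble::tibble(batch_id = "b", variety = "v", stage = c("kneaded", "oil"),
                   humidity = 0.35, added_water = 0,
                   mill_type = NA_character_, rpm = NA_real_,
                   grid_mm = NA_real_, conc_ole_glu = NA_real_,
                   conc_htyr_sec = c(2000, 268.6), conc_tyr_sec = NA_real_)
  )
  expect_warning(m <- estimate_partition(tbl, "htyr_sec"), "zero kneaded")
  expect_equal(m$n, 1L)
  expect_equal(m$K, 268.6 * 0.35 / 2000, tolerance = 1e-12)

  only_zero <- tbl[tbl$batch_id == "a", ]
  expect_warning(
    expect_error(estimate_partition(only_zero, "htyr_sec"),
                 class = "secofate_insufficient_data_error"),
    "zero kneaded"
  )
})

test_that("K of the noise-free generator is recovered exactly, pooled over humidities", {
  both <- dplyr::bind_rows(
    generate_dataset(cornicabra_only_config(21, noise_cv = 0)),
    generate_dataset(arbequina_only_config(21, noise_cv = 0))
  )
  expect_equal(estimate_partition(both, "htyr_sec")$K, 0.047,
               tolerance = 1e-9)
  expect_equal(estimate_partition(both, "tyr_sec")$K, 0.064,
               tolerance = 1e-9)
})

test_that("predict_oil follows K * C / w and its monotonicity", {
  expect_equal(predict_oil(0.047, 3500, 0.35), 470)
  expect_equal(predict_oil(0.35, 1234, 0.35), 1234)  # K = w cancels
  expect_equal(predict_oil(0.047, 0, 0.35), 0)
  expect_error(predict_oil(0.047, 100, 0), class = "secofate_domain_error")
  expect_error(predict_oil(0.047, 100, 1), class = "secofate_domain_error")
  expect_error(predict_oil(0.047, -1, 0.5),
               class = "secofate_precondition_error")
  expect_error(predict_oil(-0.1, 100, 0.5), class = "secofate_domain_error")

  # strictly increasing in concentration, strictly decreasing in w
  conc <- seq(0, 5000, length.out = 25)
  expect_true(all(diff(predict_oil(0.047, conc, 0.35)) > 0))
  ws <- seq(0.05, 0.95, length.out = 25)
  expect_true(all(diff(predict_oil(0.047, 3500, ws)) < 0))
})

test_that("round trip: estimating K from predict_oil output returns the same K", {
  set.seed(33)
  K <- 0.047
  kneaded <- runif(12, 500, 6000)
  humidity <- rep(c(0.35, 0.50), 6)
  oil <- predict_oil(K, kneaded, humidity)
  tbl <- dplyr::bind_rows(purrr::map(1:12, function(i) tibble::tibble(
    batch_id = sprintf("b%02d", i), variety = "v",
    stage = c("kneaded", "oil"), humidity = humidity[i], added_water = 0,
    mill_type = NA_character_, rpm = NA_real_, grid_mm = NA_real_,
    conc_ole_glu = NA_real_, conc_htyr_sec = c(kneaded[i], oil[i]),
    conc_tyr_sec = NA_real_
  )))
  expect_equal(estimate_partition(tbl, "htyr_sec")$K, K, tolerance = 1e-9)
})

test_that("validate_prediction reports through-origin adequacy", {
  p <- c(100, 200, 400)
  expect_equal(validate_prediction(p, p)$slope, 1)
  expect_equal(validate_prediction(p, p)$r2, 1)
  expect_equal(validate_prediction(p, 2 * p)$slope, 2)
  expect_error(validate_prediction(p, c(1, 2)),
               class = "secofate_input_error")
  set.seed(9)
  m <- p * 1.1 * exp(rnorm(3, sd = 0.05))
  fit <- validate_prediction(p, m)
  oracle <- grid_search_origin(p, m)
  expect_equal(fit$slope, oracle$slope,
               tolerance = 2 * oracle$slope_resolution)
})
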