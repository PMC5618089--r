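test_that("internal-standard arithmetic gives the textbook concentration", {
  pt <- peak_table("s1", "paste_or_fruit", sample_mass = 4.0, is_mass = 2.0,
                   is_area = 1e5, analyte_areas = c(dhpea_eda = 1e5),
                   response_factors = c(dhpea_eda = 1))
  prof <- quantify(pt)
  # area ratio 1, RF 1: 2.0 mg in 4.0 g = 0.004 kg -> 500 mg/kg
  expect_equal(prof$concentrations[["htyr_sec"]], 500)
  expect_identical(prof$stage, "crushed")

  zero <- peak_table("s2", "paste_or_fruit", 4.0, 2.0, 1e5,
                     analyte_areas = c(dhpea_eda = 0),
                     response_factors = c(dhpea_eda = 1))
  expect_equal(quantify(zero)$concentrations[["htyr_sec"]], 0)
})

test_that("quantification is linear in area and inverse in IS area and mass", {
  base <- function(is_area = 1e5, area = 5e4, mass = 4.0) {
    pt <- peak_table("s", "paste_or_fruit", mass, 2.0, is_area,
                     analyte_areas = c(p_hpea_eda = area),
                     response_factors = c(p_hpea_eda = 1.5))
    quantify(pt)$concentrations[["tyr_sec"]]
  }
  expect_equal(base(area = 1e5), 2 * base(area = 5e4))
  expect_equal(base(is_area = 2e5), base(is_area = 1e5) / 2)
  expect_equal(base(mass = 8.0), base(mass = 4.0) / 2)
})

test_that("compounds sum into families and missing RFs are config errors", {
  pt <- peak_table("s", "paste_or_fruit", 4.0, 2.0, 1e5,
                   analyte_areas = c(dhpea_eda = 2e4, dhpea_ea = 3e4,
                                     oleuropein = 1e4),
                   response_factors = c(dhpea_eda = 1, dhpea_ea = 1,
                                        oleuropein = 2))
  prof <- quantify(pt)
  expect_equal(prof$concentrations[["htyr_sec"]],
               (2e4 + 3e4) / 1e5 * 2.0 / 0.004)
  expect_equal(prof$concentrations[["ole_glu"]],
               1e4 / 1e5 * 2.0 * 2 / 0.004)

  incomplete <- peak_table("s", "paste_or_fruit", 4.0, 2.0, 1e5,
                           analyte_areas = c(dhpea_eda = 2e4, p_hpea_ea = 1e3),
                           response_factors = c(dhpea_eda = 1))
  expect_error(quantify(incomplete), class = "secofate_config_error")
  expect_error(
    peak_table("s", "paste_or_fruit", 4.0, 2.0, 1e5,
               analyte_areas = c(quercetin = 10)),
    class = "secofate_config_error"
  )
  expect_warning(
    peak_table("s", "paste_or_fruit", 4.0, 2.0, 1e5,
               analyte_areas = c(dhpea_eda = 10)),
    "RF = 1"
  )
})

test_that("default protocols carry the published sample and IS masses", {
  paste_proto <- default_protocol("paste_or_fruit")
  expect_equal(paste_proto$sample_mass, 4.0)
  expect_equal(paste_proto$is_mass, 2.0)

  oil_mass <- default_protocol("oil")  # 0.250 mL * 0.792 g/mL * 15 mg/kg
  expect_equal(oil_mass$sample_mass, 2.5)
  expect_equal(oil_mass$is_mass, 0.250 * 0.792 * 15 / 1000)
  expect_equal(oil_mass$is_mass, 2.97e-3, tolerance = 1e-3)

  oil_vol <- default_protocol("oil", is_units = "mg_per_L")
  expect_equal(oil_vol$is_mass, 3.75e-3)
})

test_that("profile -> synthetic peak table -> quantify is an exact round trip", {
  profs <- list(
    phenolic_profile("crushed", ole_glu = 300, htyr_sec = 3500,
                     tyr_sec = 908),
    phenolic_profile("kneaded", htyr_sec = 4200, tyr_sec = 890),
    phenolic_profile("oil", ole_glu = 0, htyr_sec = 470, tyr_sec = 160)
  )
  for (p in profs) {
    pt <- synthetic_peak_table(p)
    back <- quantify(pt, stage = p$stage)
    for (fam in phenolic_families()) {
      want <- p$concentrations[[fam]]
      if (is.na(want)) want <- 0
      expect_equal(back$concentrations[[fam]], want, tolerance = 1e-12)
    }
  }
  # non-unit response factors must round-trip too
  rf <- c(dhpea_eda = 1.3, dhpea_ea = 0.8, p_hpea_eda = 2.1, p_hpea_ea = 0.5,
          oleuropein = 1.7, demethyl_oleuropein = 0.9)
  pt <- synthetic_peak_table(profs[[1]], response_factors = rf)
  back <- quantify(pt)
  expect_equal(back$concentrations[["htyr_sec"]], 3500, tolerance = 1e-12)
  expect_equal(back$concentrations[["tyr_sec"]], 908, tolerance = 1e-12)
})
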