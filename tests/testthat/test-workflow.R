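test_that("simulate -> fit -> predict -> validate runs end to end on disk", {
  dir <- withr::local_tempdir()
  sim <- run_simulate(default_generator_config(n_batches_per_variety = 5),
                      out_dir = file.path(dir, "sim"), seed = 202)
  expect_true(file.exists(sim$dataset_csv))
  expect_equal(sim$report$run$seed, 202L)
  expect_equal(length(unique(sim$dataset$batch_id)), 10)

  fit <- run_fit(sim$dataset_csv, out_dir = file.path(dir, "fit"))
  expect_true(file.exists(fit$models_yaml))
  report <- jsonlite::read_json(fit$report_paths$json)
  expect_true(all(c("crushing", "malaxation", "partition") %in% names(report)))
  expect_match(report$run$config_hash, "^[0-9a-f]+$")

  pred <- run_predict(fit$models_yaml, sim$dataset_csv,
                      out_dir = file.path(dir, "pred"))
  expect_true(file.exists(pred$predicted_csv))
  expect_equal(sort(unique(pred$predicted$stage)),
               c("crushed", "kneaded", "oil"))
  expect_equal(length(unique(pred$predicted$batch_id)), 10)

  val <- run_validate(fit$models_yaml, sim$dataset_csv,
                      out_dir = file.path(dir, "val"))
  expect_true(all(c("stage", "family", "variety", "n", "slope", "r2") %in%
                    names(val$validation)))
  oil_pooled <- val$validation[val$validation$stage == "oil" &
                                 val$validation$variety == "pooled", ]
  expect_equal(nrow(oil_pooled), 2)
  # self-validation: models fitted on these data should track them closely
  expect_true(all(abs(oil_pooled$slope - 1) < 0.15))
})

test_that("self-validation on zero-noise data gives slope 1 and r2 1", {
  dir <- withr::local_tempdir()
  sim <- run_simulate(default_generator_config(noise_cv = 0), out_dir = dir)
  fit <- run_fit(sim$dataset, out_dir = dir)
  val <- run_validate(fit$models, sim$dataset, out_dir = dir)
  expect_equal(val$validation$slope, rep(1, nrow(val$validation)),
               tolerance = 1e-9)
  expect_equal(val$validation$r2, rep(1, nrow(val$validation)),
               tolerance = 1e-9)
})

test_that("simulation is byte-identical under one seed and reports it", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  run_simulate(NULL, out_dir = dir1, seed = 55)
  run_simulate(NULL, out_dir = dir2, seed = 55)
  expect_identical(readLines(file.path(dir1, "dataset.csv")),
                   readLines(file.path(dir2, "dataset.csv")))
  rep1 <- jsonlite::read_json(file.path(dir1, "simulate_report.json"))
  expect_equal(rep1$run$seed, 55L)
  expect_true(nzchar(rep1$run$config_hash))
})

test_that("a dataset without an oil stage skips the partition fit with a warning", {
  dat <- generate_dataset(default_generator_config(n_batches_per_variety = 3))
  no_oil <- dat[dat$stage != "oil", ]
  ws <- capture_warnings(fit <- run_fit(no_oil,
                                        out_dir = withr::local_tempdir()))
  expect_true(any(grepl("Partition fit skipped", ws)))
  expect_length(fit$models$partition, 0)
  expect_length(fit$models$crushing, 2)
})

test_that("run_quantify converts a peak CSV to family concentrations", {
  dir <- withr::local_tempdir()
  peaks <- file.path(dir, "peaks.csv")
  writeLines(c(
    "sample_id,matrix,sample_mass_g,is_mass_mg,is_area,dhpea_eda,p_hpea_eda",
    "s1,paste_or_fruit,4.0,2.0,100000,100000,",
    "s2,oil,2.5,0.00297,200000,50000,25000"
  ), peaks)
  rfs <- file.path(dir, "rf.csv")
  writeLines(c("compound,rf", "dhpea_eda,1.0", "p_hpea_eda,1.0"), rfs)
  out <- run_quantify(peaks, rf_csv = rfs, out_dir = dir)
  expect_equal(nrow(out$quantified), 2)
  expect_equal(out$quantified$conc_htyr_sec[1], 500)
  expect_equal(out$quantified$stage, c("crushed", "oil"))
  expect_true(file.exists(out$quantified_csv))
})

cli_path <- function() {
  path <- system.file("scripts", "secofate", package = "secofate")
  if (!nzchar(path)) skip("CLI script not found in installation")
  path
}

test_that("the CLI wraps the workflows with proper exit codes", {
  dir <- withr::local_tempdir()
  script <- cli_path()
  # make the current library stack visible to the subprocess
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2("Rscript", c(script, "simulate", "--seed", "5",
                                 "--out", shQuote(dir)),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(dir, "dataset.csv")))

  status_fit <- system2("Rscript", c(script, "fit", "--data",
                                     shQuote(file.path(dir, "dataset.csv")),
                                     "--out", shQuote(dir)),
                        stdout = FALSE, stderr = FALSE)
  expect_equal(status_fit, 0L)
  expect_true(file.exists(file.path(dir, "models.yaml")))

  # missing required input -> exit 2
  status_bad <- system2("Rscript", c(script, "fit"),
                        stdout = FALSE, stderr = FALSE)
  expect_equal(status_bad, 2L)
  status_cmd <- system2("Rscript", c(script, "squeeze"),
                        stdout = FALSE, stderr = FALSE)
  expect_equal(status_cmd, 2L)
})
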