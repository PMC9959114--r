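# Dilution bookkeeping, condition series, and the command-line dispatcher.

test_that("aliquot dilution reproduces the worked concentration", {
  # one 50 uL aliquot of 200 mM into 2 mM in a 1.0 mL chamber -> 11.43 mM
  c1 <- concentration_after_additions(1, chamber_volume = 1e-3)
  expect_equal(c1, (2 * 1000 + 200 * 50) / 1050, tolerance = 1e-12)
  expect_equal(c1, 11.43, tolerance = 1e-3)
  expect_equal(concentration_after_additions(0, 1e-3), 2)
})

test_that("dilution is monotone in additions and bounded by the stock", {
  n <- 0:100
  conc <- concentration_after_additions(n, chamber_volume = 1e-3)
  expect_true(all(diff(conc) > 0))
  expect_true(all(conc <= 200))
  expect_equal(concentration_after_additions(1e6, 1e-3), 200,
               tolerance = 1e-3)
})

test_that("asymmetry factor is the top/bottom concentration ratio", {
  expect_equal(asymmetry_factor(2, 2), 1)
  expect_equal(asymmetry_factor(11.43, 2), 5.71, tolerance = 1e-3)
  expect_equal(asymmetry_factor(3 * 1.7, 1.7), 3)
  expect_error(asymmetry_factor(0, 2), class = "electrobend_domain_error")
})

test_that("schedule tabulates top concentration and x per addition", {
  sched <- asymmetry_schedule(2, chamber_volume = 1e-3)
  expect_equal(nrow(sched), 3L)
  expect_equal(sched$top_concentration_mM[1], 2)
  expect_equal(sched$x_factor[1], 1)
  expect_equal(sched$top_concentration_mM[2], 11.43, tolerance = 1e-3)
  expect_equal(sched$x_factor,
               sched$top_concentration_mM / sched$bottom_concentration_mM)
})

write_series_fixture <- function(dir, specs, sample_rate = 100) {
  proto <- fast_protocol(sample_rate = sample_rate)
  vapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    params <- do.call(simulation_params, sp)
    path <- file.path(dir, paste0("trace", i, ".csv"))
    write_trace(simulate_trace(params, proto), path)
    path
  }, character(1L))
}

test_that("a two-condition DOPG series shows the 50% rigidity increase", {
  dir <- withr::local_tempdir()
  paths <- write_series_fixture(dir, list(
    list(zero_field_thickness = 2.84e-9, young_modulus = 6.29e6,
         lipid = "DOPG", x_factor = 1),
    list(zero_field_thickness = 2.84e-9, young_modulus = 9.43e6,
         lipid = "DOPG", x_factor = 5.71)
  ))
  manifest <- tibble::tibble(trace_path = paths)
  series <- run_series(manifest, config = no_boot)
  expect_equal(nrow(series), 2L)
  expect_equal(series$x_factor, c(1, 5.71))
  expect_equal(series$bending_rigidity_pct_change[1], 0)
  expect_equal(series$bending_rigidity_pct_change[2], 50, tolerance = 0.02)
  # with thickness held fixed, percent change in k_c equals that in E
  expect_equal(
    series$bending_rigidity_pct_change[2],
    100 * (series$young_modulus_Pa[2] / series$young_modulus_Pa[1] - 1),
    tolerance = 1e-3
  )
})

test_that("series output is invariant to manifest row order", {
  dir <- withr::local_tempdir()
  paths <- write_series_fixture(dir, list(
    list(x_factor = 1),
    list(young_modulus = 1.4e7, x_factor = 3)
  ))
  s1 <- run_series(tibble::tibble(trace_path = paths), config = no_boot)
  s2 <- run_series(tibble::tibble(trace_path = rev(paths)), config = no_boot)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("degenerate series cases behave as documented", {
  dir <- withr::local_tempdir()
  paths <- write_series_fixture(dir, list(list(x_factor = 1)))
  single <- run_series(tibble::tibble(trace_path = paths), config = no_boot)
  expect_equal(nrow(single), 1L)
  expect_false("bending_rigidity_pct_change" %in% names(single))

  twin <- run_series(tibble::tibble(trace_path = paths[c(1, 1)]),
                     config = no_boot)
  expect_equal(twin$bending_rigidity_pct_change, c(0, 0), tolerance = 1e-12)

  mixed_paths <- write_series_fixture(dir, list(
    list(lipid = "DOPC", x_factor = 1),
    list(lipid = "DOPG", zero_field_thickness = 2.84e-9,
         young_modulus = 6.29e6, x_factor = 1)
  ))
  expect_error(
    run_series(tibble::tibble(trace_path = mixed_paths), config = no_boot),
    class = "electrobend_config_error"
  )
  grouped <- run_series(tibble::tibble(trace_path = mixed_paths),
                        config = no_boot, by_lipid = TRUE)
  expect_equal(sort(grouped$lipid), c("DOPC", "DOPG"))
  expect_s3_class(autoplot(grouped), "ggplot")
})

test_that("the CLI covers simulate/analyze/series/protocol with exit codes", {
  dir <- withr::local_tempdir()
  proto_csv <- file.path(dir, "protocol.csv")
  expect_equal(
    suppressMessages(cli_main(c("protocol", "--output", proto_csv))), 0L
  )
  proto <- read.csv(proto_csv)
  expect_equal(nrow(proto), 18L)

  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(
    list(
      params = list(capacitance_noise = 0.001),
      protocol = list(sample_rate = 50),
      analysis = list(bootstrap_replicates = 100)
    ),
    cfg_path,
    auto_unbox = TRUE
  )
  trace_csv <- file.path(dir, "trace.csv")
  expect_equal(
    suppressMessages(cli_main(c(
      "simulate", "--config", cfg_path, "--seed", "3",
      "--output", trace_csv
    ))),
    0L
  )
  expect_true(file.exists(trace_csv))

  report_json <- file.path(dir, "report.json")
  expect_equal(
    suppressMessages(cli_main(c(
      "analyze", trace_csv, "--config", cfg_path, "--output", report_json
    ))),
    0L
  )
  report <- jsonlite::read_json(report_json, simplifyVector = TRUE)
  expect_equal(report$moduli$young_modulus_constant_volume_Pa, 1.757e7,
               tolerance = 0.05)

  manifest_csv <- file.path(dir, "manifest.csv")
  write.csv(
    data.frame(trace_path = trace_csv, lipid = "DOPC", x_factor = 1),
    manifest_csv,
    row.names = FALSE
  )
  table_csv <- file.path(dir, "series.csv")
  expect_equal(
    suppressMessages(cli_main(c(
      "series", manifest_csv, "--config", cfg_path, "--output", table_csv
    ))),
    0L
  )
  expect_equal(nrow(read.csv(table_csv)), 1L)

  # exit codes: 1 for data errors, 2 for configuration errors
  expect_equal(
    suppressMessages(cli_main(c("analyze", file.path(dir, "nope.csv")))), 1L
  )
  expect_equal(suppressMessages(cli_main("simulate")), 2L)
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(cli_main(c("analyze", "--seed", "x"))), 2L)
})
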