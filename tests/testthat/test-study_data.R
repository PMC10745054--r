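test_that("domain constructors enforce their physical invariants", {
  expect_error(franz_cell(sample_volume_ml = 3), "Vs < Vc")
  expect_error(franz_cell(sample_volume_ml = 3.5), "Vs < Vc")
  expect_error(franz_cell(times_h = c(0, 1, 1, 2)), "strictly increasing")
  expect_error(franz_cell(times_h = c(-1, 1)), "strictly increasing")
  expect_error(franz_cell(area_cm2 = 0), "area")
  expect_error(analyte_spec("x", lod = 3, loq = 1), "lod")
  expect_error(analyte_spec("x", mw = -1), "mw")
  expect_error(conc_series("c", c(0, 1), c(1, -2)), "non-negative")
  expect_error(conc_series("c", c(1, 0), c(1, 2)), "strictly increasing")

  d <- dose_spec(0.3, 10000)
  expect_equal(d$applied_mass_ug, d$applied_volume_ml * d$c0_ug_ml,
               tolerance = 1e-9)
  expect_equal(d$applied_mass_ug, 3000)
})

test_that("time-course writer/reader round trip is lossless and sorted", {
  cell <- franz_cell()
  s1 <- conc_series("cellA", cell$times_h, c(0, 11.5, 23.25, 47.125, 96.0625),
                    membrane = "nuclepore", formulation = "F03",
                    analyte = "caffeine")
  s2 <- conc_series("cellB", cell$times_h, c(0, 5, 9, 21, 40),
                    membrane = "sublingual_mucosa", analyte = "caffeine")
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_table(list(s1, s2), path)
  back <- read_timecourse_table(path, cell)

  expect_length(back, 2)
  expect_equal(lengths(lapply(back, `[[`, "times_h")),
               c(cellA = 5L, cellB = 5L))
  expect_equal(back$cellA$conc_ug_ml, s1$conc_ug_ml, tolerance = 1e-12)
  expect_equal(back$cellB$membrane, "sublingual_mucosa")

  # out-of-order rows come back sorted ascending in time
  df <- utils::read.csv(path)
  utils::write.csv(df[rev(seq_len(nrow(df))), ], path, row.names = FALSE)
  resorted <- read_timecourse_table(path, cell)
  expect_equal(resorted$cellA$times_h, cell$times_h)
  expect_equal(resorted$cellA$conc_ug_ml, s1$conc_ug_ml)
})

test_that("time-course reader rejects malformed tables with precise errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,membrane,formulation,analyte,time_h",
               "c1,m,f,a,0"), path)
  expect_error(read_timecourse_table(path), "conc_ug_ml")

  writeLines(c("cell_id,membrane,formulation,analyte,time_h,conc_ug_ml",
               "c1,m,f,a,0,1.0",
               "c1,m,f,a,oops,2.0"), path)
  expect_error(read_timecourse_table(path), "row 2")

  writeLines(c("cell_id,membrane,formulation,analyte,time_h,conc_ug_ml",
               "c1,m,f,a,0,1.0",
               "c1,m,f,a,1,-4.0"), path)
  expect_error(read_timecourse_table(path), "negative concentration")
})

test_that("TMWL reader handles the reference panel, replicates and edge cases", {
  panel <- tmwl_reference_panel()
  expect_s3_class(panel, "tmwl_panel")
  expect_equal(nrow(panel), 34)                       # 16 x 2 + 2 controls
  expect_equal(sum(panel$is_control), 2)
  expect_setequal(unique(panel$membrane),
                  c("nuclepore", "sublingual_mucosa"))

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("membrane,formulation,tmwl", path)
  expect_equal(nrow(read_tmwl_table(path)), 0)        # empty, no error

  writeLines(c("membrane,formulation,tmwl",
               "m1,control,80",
               "m1,F1,40",
               "m1,F1,42"), path)
  dup <- read_tmwl_table(path)
  expect_equal(nrow(dup), 3)                          # replicates kept
  expect_equal(sum(dup$formulation == "F1"), 2)

  writeLines(c("membrane,formulation,tmwl",
               "m1,F1,40"), path)
  expect_error(read_tmwl_table(path), "control")
})

test_that("parameters table writes a fixed layout and round-trips numerics", {
  empty <- withr::local_tempfile(fileext = ".csv")
  write_parameters_table(list(), empty)
  hdr <- utils::read.csv(empty)
  expect_equal(nrow(hdr), 0)
  expect_equal(names(hdr)[1:5],
               c("cell_id", "membrane", "formulation", "analyte", "model"))

  cell <- franz_cell()
  s <- conc_series("c1", cell$times_h, c(0, 61.3, 122.7, 240.1, 455.9),
                   membrane = "nuclepore", analyte = "caffeine")
  p <- fit_permeation(s, cell, dose_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameters_table(list(p), path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 1)
  for (col in c("flux_j_ug_cm2_h", "kp_cm_h", "lag_tl_h", "auc_ug_h_cm2")) {
    expect_equal(back[[col]], parameters_table(list(p))[[col]],
                 tolerance = 1e-12)
  }
})

test_that("study configuration parses YAML and falls back to defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cell:",
               "  vc_ml: 5",
               "  vs_ml: 0.5",
               "  area_cm2: 2.0",
               "  times_h: [0, 1, 2]",
               "dose:",
               "  volume_ml: 0.2",
               "  c0_ug_ml: 5000",
               "analytes:",
               "  - name: caffeine",
               "    log_kow: -0.1",
               "    mw: 194.2",
               "    lod: 0.82",
               "    loq: 2.49"), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$cell$receptor_volume_ml, 5)
  expect_equal(cfg$cell$times_h, c(0, 1, 2))
  expect_equal(cfg$dose$applied_mass_ug, 1000)
  expect_equal(cfg$analytes$caffeine$loq, 2.49)

  writeLines("{}", path)
  cfg <- read_study_config(path)
  expect_equal(cfg$cell$area_cm2, 1.86)
  expect_equal(cfg$dose$applied_mass_ug, 3000)
})
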