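small_cfg <- function(...) {
  panel_config(n_compounds = 2, n_cells_per_condition = 80,
               time_points_min = c(0, 30), n_replicates = 2, rng_seed = 3, ...)
}

test_that("panel configuration enforces its invariants", {
  expect_error(panel_config(time_points_min = numeric(0)), "empty")
  expect_error(panel_config(time_points_min = c(0, 30, 30)), "increasing")
  expect_error(panel_config(time_points_min = c(5, 30)), "include 0")
  expect_error(panel_config(n_cells_per_condition = 20), ">= 50")
  bad <- mechanism_archetype("x", shifts = c(not_a_descriptor = 1))
  expect_error(panel_config(mechanism_groups = list(mechanism_archetype("null"), bad)),
               "not_a_descriptor")
  expect_error(mechanism_archetype("null", shifts = c(PM_pAkt_mean = 1)),
               "null archetype")
})

test_that("panel layout counts batches and cells per condition", {
  cfg <- panel_config(n_compounds = 14, n_cells_per_condition = 50,
                      rng_seed = 1)
  panel <- generate_panel(cfg)
  pm <- panel$plate_map
  expect_equal(nrow(pm), (14 + 1) * 5 * 2)
  expect_equal(sum(pm$compound != "DMSO"), 14 * 5 * 2)
  expect_equal(sum(pm$compound == "DMSO"), 5 * 2)
  expect_equal(nrow(panel$features), nrow(pm) * 50)
  expect_true(all(table(panel$features$batch_id) == 50))
  # every compound maps to exactly one mechanism group; control to null
  expect_equal(anyDuplicated(panel$truth$compound), 0)
  expect_equal(panel$truth$group[panel$truth$compound == "DMSO"], "null")
})

test_that("generation is a pure function of config and seed", {
  a <- generate_panel(small_cfg())
  b <- generate_panel(small_cfg())
  expect_identical(a$features, b$features)
  c2 <- generate_panel(panel_config(n_compounds = 2,
                                    n_cells_per_condition = 80,
                                    time_points_min = c(0, 30),
                                    n_replicates = 2, rng_seed = 4))
  expect_false(identical(a$features, c2$features))
})

test_that("a +3 SD shift moves the empirical mean by 3 control SD", {
  d <- "Cytoplasm_pERK_mean"
  arch <- list(mechanism_archetype("null"),
               mechanism_archetype("shifted",
                                   shifts = stats::setNames(3, d)))
  cfg <- panel_config(n_compounds = 1, n_cells_per_condition = 600,
                      time_points_min = c(0, 30), n_replicates = 1,
                      mechanism_groups = arch[2:1], rng_seed = 8,
                      potency_levels = 1)
  # single compound assigned to the shifted archetype, control to null
  cfg$group_of <- "shifted"
  panel <- generate_panel(cfg)
  at30 <- panel$features[panel$features$time_min == 30, ]
  trt <- at30[[d]][at30$compound == "cmpd01"]
  ctl <- at30[[d]][at30$compound == "DMSO"]
  shift_sd_units <- (mean(trt) - mean(ctl)) / sd(ctl)
  expect_lt(abs(shift_sd_units - 3), 0.2)
})

test_that("null compounds are distributed like the control", {
  cfg <- panel_config(n_compounds = 2, n_cells_per_condition = 500,
                      time_points_min = c(0, 30), n_replicates = 1,
                      mechanism_groups = list(mechanism_archetype("null")),
                      rng_seed = 5)
  panel <- generate_panel(cfg)
  at30 <- panel$features[panel$features$time_min == 30, ]
  for (d in c("PM_EGFR_mean", "Nucleus_pERK_mean")) {
    d_ks <- signed_ks(at30[[d]][at30$compound == "cmpd01"],
                      at30[[d]][at30$compound == "DMSO"])
    expect_lt(abs(d_ks$signed_d), 0.12)   # ~ 2-sample null scale at n = 500
  }
})

test_that("expected |Z| grows monotonically with the descriptor shift", {
  d <- "PM_pAkt_mean"
  expected_abs_z <- vapply(c(0, 0.5, 1, 2), function(s) {
    zs <- vapply(1:8, function(run) {
      arch <- list(mechanism_archetype("null"),
                   mechanism_archetype("g", shifts = stats::setNames(s, d)))
      cfg <- panel_config(n_compounds = 1, n_cells_per_condition = 200,
                          time_points_min = c(0, 30), n_replicates = 1,
                          mechanism_groups = arch, rng_seed = 100 + run,
                          potency_levels = 1)
      cfg$group_of <- "g"
      at30 <- generate_panel(cfg)$features
      at30 <- at30[at30$time_min == 30, ]
      ctl <- at30[[d]][at30$compound == "DMSO"]
      std <- bootstrap_null_std(ctl, 300, seed = 9)$std
      abs(signed_ks(at30[[d]][at30$compound == "cmpd01"], ctl)$signed_d / std)
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(expected_abs_z) >= 0))
})
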