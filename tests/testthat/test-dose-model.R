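test_that("plan simulation is deterministic in its seed", {
  ph <- small_phantom()
  s <- plan_sim_spec(seed = 7, noise_sd_Gy = 0.8)
  d1 <- simulate_plan(ph$structs, s)
  d2 <- simulate_plan(ph$structs, s)
  expect_identical(d1$values, d2$values)
  # noiseless plans are deterministic too, and differ from noisy ones
  s0 <- plan_sim_spec(seed = 7, noise_sd_Gy = 0)
  expect_identical(simulate_plan(ph$structs, s0)$values,
                   simulate_plan(ph$structs, s0)$values)
  expect_false(identical(d1$values, simulate_plan(ph$structs, s0)$values))
  # different seeds give different noise
  expect_false(identical(
    d1$values, simulate_plan(ph$structs, plan_sim_spec(seed = 8, noise_sd_Gy = 0.8))$values))
})

test_that("PTV mean dose lands within 2% of prescription", {
  ph <- small_phantom()
  d <- small_plan(seed = 11)
  ptv_mean <- mean(d$values[ph$structs$rois$PTV$mask])
  expect_lt(abs(ptv_mean - 66) / 66, 0.02)
})

test_that("techniques with different fall-off scales change the RING dose", {
  ph <- small_phantom()
  a <- simulate_plan(ph$structs, plan_sim_spec(technique_id = "impt_mc", seed = 3))
  b <- simulate_plan(ph$structs, plan_sim_spec(technique_id = "tomo_cc", seed = 3))
  ring <- ph$structs$rois$RING$mask
  expect_gt(abs(mean(a$values[ring]) - mean(b$values[ring])), 1)
})

test_that("cohort sizes are exactly 4 / 8 / 22 and nested as designed", {
  ph <- small_phantom()
  repro <- generate_cohort(ph$structs, "reproducibility", base_seed = 2)
  stab <- generate_cohort(ph$structs, "stability", base_seed = 2)
  sens <- generate_cohort(ph$structs, "sensitivity", base_seed = 2)
  expect_length(repro, 4)
  expect_length(stab, 8)
  expect_length(sens, 22)
  # reproducibility plans are the first four stability plans, bitwise
  for (i in 1:4)
    expect_identical(repro[[i]]$dose$values, stab[[i]]$dose$values)
  # sensitivity: 11 labels x 2 resolutions, >= 4 distinct techniques
  expect_length(unique(vapply(sens, `[[`, character(1), "label")), 11)
  expect_setequal(unique(vapply(sens, `[[`, character(1), "resolution")),
                  c("fine", "coarse"))
  expect_gte(length(unique(vapply(sens, `[[`, character(1), "technique_id"))), 4)
  expect_error(generate_cohort(ph$structs, "nope", 1), "unknown design")
})

test_that("DVH constraint checks follow closed-form expectations", {
  ph <- small_phantom()
  st <- ph$structs
  g <- st$grid
  # uniform 66 Gy inside the PTV, zero elsewhere
  v <- array(0, g$dim)
  v[st$rois$PTV$mask] <- 66
  qa <- check_constraints(dose_grid(v, g$spacing_mm, g$origin_mm), st, 66)
  get <- function(roi, metric) qa[qa$roi == roi & qa$metric == metric, ]
  expect_equal(get("PTV", "D98%")$value, 66)
  expect_true(get("PTV", "D98%")$pass)
  expect_equal(get("PTV", "V105%")$value, 0)
  expect_true(get("PTV", "V105%")$pass)
  # all-zero dose: PTV coverage fails, OAR limits trivially pass
  qa0 <- check_constraints(dose_grid(array(0, g$dim), g$spacing_mm, g$origin_mm), st, 66)
  expect_false(qa0[qa0$roi == "PTV" & qa0$metric == "D98%", "pass"])
  expect_true(all(qa0[qa0$metric %in% c("Dmax", "Dmean"), "pass"]))
  # spinal canal max just under / just over the 45 Gy limit
  for (mx in c(44.9, 45.1)) {
    v2 <- array(0, g$dim)
    v2[st$rois$spinal_canal$mask] <- mx
    v2[st$rois$PTV$mask] <- 66
    qa2 <- check_constraints(dose_grid(v2, g$spacing_mm, g$origin_mm), st, 66)
    expect_identical(qa2[qa2$roi == "spinal_canal", "pass"], mx < 45)
  }
})

test_that("an empty ROI yields an explicit error record, not a silent pass", {
  ph <- small_phantom()
  st <- ph$structs
  st$rois$trachea$mask[] <- FALSE
  qa <- check_constraints(small_plan(), st, 66)
  row <- qa[qa$roi == "trachea", ]
  expect_true(is.na(row$pass))
  expect_match(row$note, "empty")
})

test_that("generated plans pass the planning-constraint QA", {
  ph <- small_phantom()
  coh <- generate_cohort(ph$structs, "stability", base_seed = 41)
  for (pl in coh) {
    qa <- check_constraints(pl$dose, ph$structs, 66)
    expect_true(all(qa$pass), label = paste("plan", pl$label, "passes QA"))
  }
})
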