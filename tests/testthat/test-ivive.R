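test_that("PS clearance converts units correctly and is linear in Fub", {
  phys <- physiology_config()  # 20 m2 = 2e5 cm2
  expect_equal(ps_clearance(1, 3e-6, phys), 36)         # 0.6 cm3/s
  expect_equal(ps_clearance(0.5, 3e-6, phys), 18)       # halved exactly
  expect_equal(ps_clearance(1, 0, phys), 0)
  expect_error(ps_clearance(0, 3e-6, phys), "fub")
  expect_error(ps_clearance(1.2, 3e-6, phys), "fub")
  # explicit area conversion audit: 20 m2 -> 2e5 cm2
  expect_equal(physiology_config(A_BBB_m2 = 20)$A_BBB_m2 * 1e4, 2e5)
})

test_that("rate constant and half-life compose as the hand-worked chain", {
  phys <- physiology_config()   # V_ref 5 L
  k <- uptake_rate_constant(36, phys)
  expect_equal(k, 1.2e-4)                    # 0.0072 / min
  expect_equal(uptake_rate_constant(0, phys), 0)
  # halving V_ref doubles k
  expect_equal(uptake_rate_constant(36, physiology_config(V_ref_L = 2.5)),
               2.4e-4)
  th <- uptake_half_life(k)
  expect_equal(th, log(2) / 1.2e-4)          # ~5776 s
  expect_equal(th / 60, 96.27, tolerance = 1e-4)
  expect_equal(uptake_half_life(log(2)), 1)
  expect_identical(uptake_half_life(0), Inf)
  expect_error(uptake_half_life(-1), ">= 0")
})

test_that("half-life scales inversely with Papp and Fub", {
  phys <- physiology_config()
  th <- function(fub, papp)
    uptake_half_life(uptake_rate_constant(ps_clearance(fub, papp, phys), phys))
  expect_equal(th(0.5, 2e-6), th(1, 2e-6) * 2)
  expect_equal(th(0.5, 4e-6), th(0.5, 2e-6) / 2)
})

test_that("steady-state brain concentration follows the efflux ratio", {
  expect_equal(css_brain(7, 1), 7)                  # ER 1: brain = serum
  expect_equal(css_brain(1, 2.5), 0.4)              # efflux cut: 40% of serum
  # belinostat: ER from the printed panel, > 100-fold accumulation
  expect_equal(css_brain(1, 0.07 / 18.8), 18.8 / 0.07)
  expect_gt(css_brain(1, 0.07 / 18.8), 100)
  expect_error(css_brain(-1, 1), ">= 0")
  expect_error(css_brain(1, 0), "> 0")
  # strictly decreasing in ER
  ers <- 10^seq(-2, 1, length.out = 20)
  expect_true(all(diff(vapply(ers, css_brain, numeric(1),
                              css_serum = 5)) < 0))
})

test_that("bounds survive the whole extrapolation chain", {
  phys <- physiology_config()
  ps <- ps_clearance(1, bound(500e-6, "lower"), phys)
  expect_equal(bound_type(ps), "lower")
  k <- uptake_rate_constant(ps, phys)
  expect_equal(bound_type(k), "lower")
  th <- uptake_half_life(k)
  expect_equal(bound_type(th), "upper")     # faster than the bound says
  cb <- css_brain(10, bound(0.24, "upper"))
  expect_equal(bound_type(cb), "lower")     # at least 10/0.24
  expect_equal(bound_value(cb), 10 / 0.24)
  cb2 <- css_brain(10, bound(50, "lower"))
  expect_equal(bound_type(cb2), "upper")
})

test_that("dose scaling is linear with an updated reference", {
  tk <- make_toxkinetic_table(c("a", "b"), seed = 2)
  expect_equal(scale_dose(tk, 1), tk)
  tk2 <- scale_dose(tk, 2)
  expect_equal(tk2$css_serum_uM, tk$css_serum_uM * 2)
  expect_equal(tk2$reference_dose_mg_kg_day, c(2, 2))
  expect_equal(scale_dose(tk, 0)$css_serum_uM, c(0, 0))
  tk$reference_dose_mg_kg_day <- 0
  expect_error(scale_dose(tk, 1), "> 0")
})

test_that("panel prediction joins, flags gaps, and preserves order logic", {
  fx <- load_reference_panel()
  res <- bidirectional_results(fx)
  tk <- make_toxkinetic_table(res$compound_id, seed = 9)
  exp <- predict_panel(res, tk)
  expect_equal(nrow(exp), nrow(res))
  # brain:serum ranking is the ranking of 1/ER (uncensored rows)
  unc <- !is.na(exp$css_brain_uM) & exp$css_brain_bound_type == "point" &
    !is.na(res$er) & res$er_bound_type == "point"
  ratio <- exp$css_brain_uM[unc] / exp$css_serum_uM[unc]
  expect_equal(order(ratio), order(1 / res$er[unc]))

  # missing toxicokinetics: row kept with explicit notes
  tk2 <- tk[tk$compound_id != "Verapamil", ]
  exp2 <- predict_panel(res, tk2)
  expect_equal(nrow(exp2), nrow(res))
  vrow <- exp2[exp2$compound_id == "Verapamil", ]
  expect_match(vrow$notes, "acute-incomplete")
  expect_match(vrow$notes, "chronic-incomplete")
  expect_true(is.na(vrow$k_per_s))

  # censored AB: bounded kinetics and bounded brain concentration
  vp <- exp[exp$compound_id == "Valproic acid", ]
  expect_equal(vp$k_bound_type, "lower")
  expect_equal(vp$t_half_bound_type, "upper")
  expect_equal(vp$css_brain_bound_type, "lower")

  # empty join errors with the unmatched identifiers
  tk3 <- make_toxkinetic_table(c("nope1", "nope2"), seed = 1)
  expect_error(predict_panel(res, tk3), "no compound identifiers match")
})

test_that("single-compound composition matches the unit operations", {
  res <- data.frame(compound_id = "x", papp_ab = 2e-6, sd_ab = 0.1e-6,
                    n_ab = 3L, r2_ab = 0.99, ab_censored = FALSE,
                    flags_ab = "", papp_ba = 2e-6, sd_ba = 0.1e-6,
                    n_ba = 3L, r2_ba = 0.99, ba_censored = FALSE,
                    flags_ba = "", er = 1, er_bound_type = "point",
                    er_sd = 0.05, rate_class = "Moderate",
                    transport_call = "NoBias",
                    transport_indeterminate = FALSE,
                    stringsAsFactors = FALSE)
  tk <- data.frame(compound_id = "x", casrn = NA, fub = 1, css_serum_uM = 3,
                   reference_dose_mg_kg_day = 1, stringsAsFactors = FALSE)
  phys <- physiology_config()
  exp <- predict_panel(res, tk, phys)
  expect_equal(exp$css_brain_uM, 3)          # ER 1, Fub excluded at steady state
  expect_equal(exp$k_per_s,
               uptake_rate_constant(ps_clearance(1, 2e-6, phys), phys))
})
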