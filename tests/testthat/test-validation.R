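# Observation fixtures built against the mini mechano network; directions
# were chosen to agree (or deliberately disagree) with its known behavior.
obs_correct <- function() {
  observation_table(
    measured = c("BNP", "ERK12", "Ca", "Akt", "cGMP",
                 "BNP", "Akt", "ERK12", "Ca", "BNP"),
    category = c("input-output", rep("input-intermediate", 4),
                 rep("inhibition", 5)),
    direction = c("increase", "increase", "increase", "increase", "no-change",
                  "decrease", "decrease", "decrease", "decrease", "decrease"),
    inhibit = c(rep(NA, 5), "AT1R", "PI3K", "Raf1", "LTCC", "Raf1"))
}

test_that("classify_change applies strict thresholds symmetrically", {
  cfg <- validation_config(threshold = 0.05)
  expect_equal(classify_change(0.06, cfg), "increase")
  expect_equal(classify_change(-0.03, cfg), "no-change")
  expect_equal(classify_change(c(0.05, -0.05), cfg),
               c("no-change", "no-change"))  # exact ties are no-change
  # antisymmetry
  d <- c(-0.2, -0.05, -0.01, 0, 0.01, 0.05, 0.2)
  flip <- c(increase = "decrease", decrease = "increase",
            `no-change` = "no-change")
  expect_equal(unname(flip[classify_change(d, cfg)]),
               classify_change(-d, cfg))
})

test_that("relative mode divides by the reference, falling back at zero", {
  cfg <- validation_config(threshold = 0.05, threshold_mode = "relative")
  # 0.03 absolute on a reference of 0.4 is 7.5% relative
  expect_equal(classify_change(0.03, cfg, reference = 0.4), "increase")
  expect_equal(classify_change(0.03, validation_config(0.05), 0.4),
               "no-change")
  out <- classify_change(c(0.03, 0.06), cfg, reference = c(0.5, 0))
  expect_equal(out[1:2], c("increase", "increase"))
  expect_equal(attr(out, "absolute_fallback"), 2L)
})

test_that("inhibition deltas are relative to steady-state stretch", {
  m <- mini_mechano_network()
  cfg <- validation_config()
  pred <- predict_observation(m, list(measured = "ERK12",
                                      category = "inhibition",
                                      inhibit = "Raf1"), cfg)
  st <- perturbation(set_input = c(Stretch = 0.7))
  ss1 <- steady_state(apply_perturbation(m, st))
  ssI <- steady_state(apply_perturbation(m, merge_perturbations(
    st, perturbation(scale_ymax = c(Raf1 = 0)))))
  expect_equal(pred$delta, unname(ssI["ERK12"] - ss1["ERK12"]),
               tolerance = 1e-8)
  expect_equal(pred$direction, "decrease")
  # a node unreachable from stretch predicts no change
  pred0 <- predict_observation(m, list(measured = "cGMP",
                                       category = "input-intermediate"), cfg)
  expect_equal(pred0$delta, 0, tolerance = 1e-8)
  expect_equal(pred0$direction, "no-change")
})

test_that("a fixture built to match validates at accuracy 1", {
  rep <- validate_observations(mini_mechano_network(), obs_correct())
  expect_equal(rep$overall$accuracy, 1)
  expect_equal(rep$overall$matches, 10)
  expect_equal(sum(rep$by_category$matches), rep$overall$matches)
  expect_true(all(rep$records$evaluable))
  expect_equal(sum(rep$disagreements), 0)
})

test_that("disagreements fall into the four taxonomy classes", {
  obs <- observation_table(
    measured = rep("BNP", 4),
    category = rep("inhibition", 4),
    direction = c("decrease", "decrease", "no-change", "increase"),
    inhibit = c("LTCC", "FoxO", "AT1R", "AT1R"))
  rep <- validate_observations(mini_mechano_network(), obs)
  expect_equal(rep$overall$accuracy, 0)
  expect_equal(unname(rep$disagreements["below_threshold"]), 1)      # LTCC
  expect_equal(unname(rep$disagreements["missing_connection"]), 1)   # FoxO
  expect_equal(unname(rep$disagreements["spurious_prediction"]), 1)
  expect_equal(unname(rep$disagreements["sign_flip"]), 1)
})

test_that("duplicating a record changes counts but not predictions", {
  obs <- obs_correct()
  rep1 <- validate_observations(mini_mechano_network(), obs)
  rep2 <- validate_observations(mini_mechano_network(),
                                rbind(obs, obs[1, ]))
  expect_equal(rep2$overall$total, rep1$overall$total + 1)
  expect_equal(rep2$records$delta[nrow(obs) + 1], rep1$records$delta[1])
})

test_that("inhibition depth modulates inhibition deltas continuously", {
  m <- mini_mechano_network()
  d_full <- predict_observation(m, list(measured = "BNP",
                                        category = "inhibition",
                                        inhibit = "AT1R"),
                                validation_config(inhibition_depth = 0))$delta
  d_half <- predict_observation(m, list(measured = "BNP",
                                        category = "inhibition",
                                        inhibit = "AT1R"),
                                validation_config(inhibition_depth = 0.5))$delta
  expect_lt(d_full, d_half)  # full block suppresses more
  expect_lt(d_half, 0)
})

test_that("strip_and_gates splits activating ANDs and spares inhibitors", {
  m <- suppressWarnings(network_model(
    data.frame(id = c("A", "B", "C", "D")),
    data.frame(id = c("r1", "r2", "r3"),
               rule = c("A & B => C", "A & !B => D", "=> A"),
               weight = c(0.8, 0.9, 0.7))))
  s <- strip_and_gates(m)
  expect_equal(nrow(s$species), nrow(m$species))
  expect_equal(sort(s$reactions$rule),
               sort(c("A => C", "B => C", "A & !B => D", "=> A")))
  # split reactions inherit the AND reaction's parameters
  expect_equal(s$reactions$weight[s$reactions$rule == "A => C"], 0.8)
})

test_that("AND-to-OR never lowers steady states of activating networks", {
  for (seed in 1:5) {
    m <- random_network(10, 14, seed = seed, p_inhibitor = 0, p_and = 0.5)
    ss_and <- steady_state(m)
    ss_or <- steady_state(strip_and_gates(m))
    expect_true(all(ss_or >= ss_and - 1e-8), label = paste("seed", seed))
  }
})

test_that("AND-to-OR conversion degrades validation of the gated fixture", {
  acc_orig <- validate_observations(mini_mechano_network(),
                                    obs_correct())$overall$accuracy
  acc_or <- validate_observations(strip_and_gates(mini_mechano_network()),
                                  obs_correct())$overall$accuracy
  expect_lt(acc_or, acc_orig)
})

test_that("robustness scan: degenerate width, tau/y_init invariance, seeding", {
  m <- mini_mechano_network()
  obs <- obs_correct()
  cfg <- validation_config()
  acc0 <- validate_observations(m, obs, cfg)$overall$accuracy
  r0 <- robustness_scan(m, obs, cfg, "y_max", half_widths = 0,
                        n_sets = 3, seed = 42)
  expect_true(all(r0$accuracy == acc0))
  for (par in c("tau", "y_init")) {
    r <- robustness_scan(m, obs, cfg, par, half_widths = 0.3,
                         n_sets = 3, seed = 42)
    expect_true(all(r$accuracy == acc0), label = par)
  }
  r1 <- robustness_scan(m, obs, cfg, "ec50", half_widths = c(0.1, 0.2),
                        n_sets = 3, seed = 7)
  r2 <- robustness_scan(m, obs, cfg, "ec50", half_widths = c(0.1, 0.2),
                        n_sets = 3, seed = 7)
  expect_identical(r1, r2)  # bit-reproducible under a fixed seed
})

test_that("activation band counts non-input nodes inside the interval", {
  m <- mini_mechano_network()
  expect_equal(activation_band(m, 0, band = c(0.5, 0.95)), 0)
  expect_equal(activation_band(m, 0.7, band = c(0, 1)), 1)
  frac <- activation_band(m, 0.7, band = c(0.5, 0.95))
  expect_gt(frac, 0.5)  # the 0.7 calibration activates most of the cascade
  expect_lt(frac, 1)    # but not the pharmacological sGC/cGMP/PKG1 branch
})

test_that("observation tables validate their fields on construction", {
  expect_error(observation_table("BNP", "bogus", "increase"), "category")
  expect_error(observation_table("BNP", "input-output", "up"), "direction")
  expect_error(observation_table("BNP", "inhibition", "decrease"),
               "inhibited species")
  expect_error(validate_observations(
    mini_mechano_network(),
    observation_table("NotANode", "input-output", "increase")),
    "unknown species")
})

test_that("observation tables round-trip through CSV", {
  obs <- obs_correct()
  path <- file.path(tempdir(), "obs.csv")
  write.csv(as.data.frame(obs), path, row.names = FALSE)
  obs2 <- read_observations(path)
  expect_equal(obs2$measured, obs$measured)
  expect_equal(obs2$direction, obs$direction)
  expect_equal(obs2$inhibit, obs$inhibit)
})
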