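p_def <- gf_params()

test_that("closed-form constants and fold changes", {
  expect_equal(smcp_from_baseline(1.73, 1.60e-10), 2.768e-10, tolerance = 1e-12)
  expect_equal(rate_from_halflife(80), log(2) / 80, tolerance = 1e-15)
  expect_error(rate_from_halflife(0), "positive")
  expect_equal(fold_change(c(2, 4, 8), 2), c(1, 2, 4))
  expect_error(fold_change(1:3, 0), "positive")
})

test_that("single-study exclusion applies only to the collagen stage", {
  d <- generate_timeseries(p_def, "COL")
  # the 10-week point carries a lone study tag and is dropped for this stage
  expect_true(10 %in% d$abscissa)
  kept <- exclusion_rule(d, "mmp_timp_col")
  expect_false(10 %in% kept$abscissa)
  expect_equal(nrow(kept), nrow(d) - sum(d$abscissa == 10))
  expect_equal(attr(kept, "baseline"), attr(d, "baseline"))
  # multiply-sourced points survive untouched
  expect_setequal(kept$abscissa, setdiff(d$abscissa, 10))
  # any other stage passes everything through
  expect_identical(exclusion_rule(d, "tgf"), d)
  # an empty dataset is returned unchanged
  e <- d[0, , drop = FALSE]
  expect_equal(nrow(exclusion_rule(e, "mmp_timp_col")), 0)
})

test_that("stage data kinds and malformed inputs are rejected", {
  ts <- generate_timeseries(p_def, "MAC")
  dr <- generate_dose_response(p_def, "mcp_vs_age")
  expect_error(fit_subsystem("mcp", ts, p_def), "dose-response")
  expect_error(fit_subsystem("mac", dr, p_def), "fold-change")
  expect_error(fit_subsystem("amc", ts, p_def), "vitro")
  expect_error(fit_subsystem("amc", list(vitro = ts, vivo = dr), p_def),
               "reversed")
  expect_error(fit_subsystem("mac", ts, p_def,
                             initial_guess = c(lambda_TGF = 1)), "among")
  expect_error(fit_subsystem("tgf", ts[0, ], p_def), "non-empty")
})

## ---- noiseless recovery, stage by stage ------------------------------------
## Data generated with the default parameters; fits start from displaced
## guesses and must come back to the generating values.

test_that("noiseless recovery: AGE formation kinetics", {
  d <- generate_timeseries(p_def, "AGE", sample_weeks = seq(0, 24, by = 4))
  fit <- fit_subsystem("age", d, p_def,
                       initial_guess = c(lambda_AGE = 3 * p_def$lambda_AGE,
                                         K_GLU = 0.4 * p_def$K_GLU,
                                         n_GLU = 2))
  expect_true(fit$converged)
  for (nm in gf_stage_params$age)
    expect_lt(rel_err(fit$estimates[[nm]], p_def[[nm]]), 0.01)
})

test_that("noiseless recovery: MCP dose-response", {
  d <- generate_dose_response(p_def, "mcp_vs_age")
  fit <- fit_subsystem("mcp", d, p_def,
                       initial_guess = c(S_MCP = 5 * p_def$S_MCP,
                                         lambda_MCP = 0.2 * p_def$lambda_MCP,
                                         K_AGE = 4 * p_def$K_AGE))
  expect_true(fit$converged)
  for (nm in gf_stage_params$mcp)
    expect_lt(rel_err(fit$estimates[[nm]], p_def[[nm]]), 0.01)
})

test_that("noiseless recovery: macrophage recruitment", {
  d <- generate_timeseries(p_def, "MAC")
  fit <- fit_subsystem("mac", d, p_def,
                       initial_guess = c(lambda_MAC = 0.3 * p_def$lambda_MAC,
                                         n_MCP = 2, mu_MAC = 3 * p_def$mu_MAC))
  expect_true(fit$converged)
  for (nm in gf_stage_params$mac)
    expect_lt(rel_err(fit$estimates[[nm]], p_def[[nm]]), 0.01)
})

test_that("noiseless recovery: TGF-beta production", {
  d <- generate_timeseries(p_def, "TGF")
  fit <- fit_subsystem("tgf", d, p_def,
                       initial_guess = c(S_TGF = 0.1 * p_def$S_TGF,
                                         lambda_TGF = 10 * p_def$lambda_TGF))
  expect_true(fit$converged)
  for (nm in gf_stage_params$tgf)
    expect_lt(rel_err(fit$estimates[[nm]], p_def[[nm]]), 0.01)
})

test_that("noiseless recovery: mesangial activation (two sub-fits)", {
  d <- list(vitro = generate_dose_response(p_def, "asma_vs_tgf"),
            vivo = generate_timeseries(p_def, "AMC",
                                       sample_weeks = seq(0, 24, by = 6)))
  fit <- fit_subsystem("amc", d, p_def,
                       initial_guess = c(lambda_AMC = 4 * p_def$lambda_AMC,
                                         K_TGF = 0.3 * p_def$K_TGF,
                                         S_AMC = 5 * p_def$S_AMC,
                                         n_TGF = 3))
  expect_true(fit$converged)
  for (nm in gf_stage_params$amc)
    expect_lt(rel_err(fit$estimates[[nm]], p_def[[nm]]), 0.01)
})

test_that("noiseless recovery: collagen stage, with lambda_MMP solved from the
           healthy MMP target", {
  mmp_target <- steady_state(p_def)[["MMP"]]
  d <- generate_timeseries(p_def, "COL")
  fit <- fit_subsystem("mmp_timp_col", d, p_def,
                       initial_guess = c(lambda_COLA = 0.2 * p_def$lambda_COLA,
                                         gamma_COL = 5 * p_def$gamma_COL),
                       mmp_ss_target = mmp_target)
  expect_true(fit$converged)
  # the solved production rate reproduces the generating value
  expect_lt(rel_err(fit$estimates$lambda_MMP, p_def$lambda_MMP), 1e-6)
  expect_equal(fit$estimates$lambda_TIMP, fit$estimates$lambda_MMP / 5)
  for (nm in gf_stage_params$mmp_timp_col)
    expect_lt(rel_err(fit$estimates[[nm]], p_def[[nm]]), 0.01)
})

## ---- recovery under noise ---------------------------------------------------

test_that("replicated noisy data still pin the macrophage death rate", {
  d <- generate_timeseries(p_def, "MAC",
                           noise = noise_model("multiplicative_lognormal",
                                               cv = 0.05, seed = 42L,
                                               replicates = 20L))
  fit <- fit_subsystem("mac", d, p_def,
                       initial_guess = c(mu_MAC = 3 * p_def$mu_MAC))
  expect_true(fit$converged)
  expect_lt(rel_err(fit$estimates$mu_MAC, p_def$mu_MAC), 0.20)
})

## (the 100-replicate median-bias study for the linear rates lives in the
## acceptance suite)

## ---- pipeline ---------------------------------------------------------------

test_that("the staged pipeline runs in order without touching upstream
           estimates", {
  guesses <- list(
    age = c(lambda_AGE = 2 * p_def$lambda_AGE),
    mcp = c(K_AGE = 3 * p_def$K_AGE),
    mac = c(mu_MAC = 0.5 * p_def$mu_MAC),
    tgf = c(lambda_TGF = 2 * p_def$lambda_TGF))
  data <- list(
    age = generate_timeseries(p_def, "AGE", sample_weeks = seq(0, 24, by = 4)),
    mcp = generate_dose_response(p_def, "mcp_vs_age"),
    mac = generate_timeseries(p_def, "MAC"),
    tgf = generate_timeseries(p_def, "TGF"))
  p <- p_def
  for (st in names(data)) {
    fit <- fit_subsystem(st, data[[st]], p, initial_guess = guesses[[st]])
    # only the stage's own parameters may change
    frozen <- setdiff(names(unclass(p)), gf_stage_params[[st]])
    expect_equal(unclass(fit$params)[frozen], unclass(p)[frozen])
    p <- fit$params
  }
  # after four noiseless stages the carried parameter set is the generator's
  for (nm in unlist(gf_stage_params[names(data)]))
    expect_lt(rel_err(p[[nm]], p_def[[nm]]), 0.01)
})

test_that("fit objects print, coerce and serialise coherently", {
  d <- generate_dose_response(p_def, "mcp_vs_age")
  fit <- fit_subsystem("mcp", d, p_def, multistart = FALSE)
  expect_s3_class(fit, "gf_fit")
  expect_named(coef(fit), gf_stage_params$mcp)
  expect_output(print(fit), "stage 'mcp'")
  f <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$stage, "mcp")
  expect_equal(back$estimates$K_AGE, fit$estimates$K_AGE, tolerance = 1e-12)
})
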