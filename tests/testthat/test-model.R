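p_def <- gf_params()

test_that("derivatives reproduce each balance term-for-term", {
  p <- p_def
  ss <- oracle_steady_state(p, p$G1, age_anchor = 1.5e-7)

  # near the healthy state every derivative is small relative to the largest
  # term in its own balance
  d <- derivatives(0, ss, p, modifiers = list(production_divisor = 1,
                                              degradation_multiplier = 1,
                                              glucose_override = p$G1))
  biggest <- c(AGE = p$mu_AGE * ss["AGE"], MCP = p$mu_MCP * ss["MCP"],
               MAC = p$mu_MAC * ss["MAC"], TGF = p$mu_TGF * ss["TGF"],
               AMC = p$mu_AMC * ss["AMC"], MMP = p$mu_MMP * ss["MMP"],
               TIMP = p$mu_TIMP * ss["TIMP"], COL = p$mu_COL * ss["COL"])
  # AGE is excluded: it is anchored at a measured value ~11% above the
  # model's own glucose fixed point, so its balance is not closed by design
  expect_true(all(abs(d[-1]) < 1e-2 * biggest[-1]))
  expect_lt(abs(d[1]), 0.15 * biggest[1])

  # term dropout: no macrophages leaves only baseline TGF-beta turnover
  st <- ss; st["MAC"] <- 0; st["TGF"] <- 3e-9
  d2 <- derivatives(0, st, p)
  expect_equal(unname(d2["TGF"]), p$S_TGF - p$mu_TGF * 3e-9)

  # AGE formation alone at the diabetic plateau (frozen direct evaluation)
  st2 <- ss; st2["AGE"] <- 0
  d3 <- derivatives(200, st2, p)   # day 200 is past the ramp
  expect_equal(unname(d3["AGE"]), 8.864046667e-08, tolerance = 1e-8)

  # collagen lysis carries no collagen factor: dCOL is linear in COL with
  # slope -mu_COL at fixed MMP/AMC
  stA <- ss; stB <- ss
  stA["COL"] <- 1; stB["COL"] <- 2
  dA <- derivatives(0, stA, p); dB <- derivatives(0, stB, p)
  expect_equal(unname(dB["COL"] - dA["COL"]), -p$mu_COL)

  expect_error(derivatives(0, ss[1:5], p), "8 components")
})

test_that("anchored steady state matches the sequential algebraic oracle and
           the reported healthy concentrations", {
  p <- p_def
  ss <- steady_state(p)
  orc <- oracle_steady_state(p, p$G1, age_anchor = 1.5e-7)
  expect_equal(unname(ss[names(orc)]), unname(orc), tolerance = 1e-8)
  # reported healthy values: the solved MCP, MAC, TGF, AMC agree within 2%
  for (sp in c("MCP", "MAC", "TGF", "AMC"))
    expect_lt(rel_err(ss[sp], reported_initial_values[sp]), 0.02)
  # residuals below the convergence tolerance
  res <- attr(ss, "residual")
  expect_true(all(abs(res) <= pmax(1e-18, 1e-9 * abs(ss))))
})

test_that("unanchored steady state relaxes AGE to its own glucose fixed point", {
  p <- p_def
  ss <- steady_state(p, glucose = p$G1, age_anchor = NULL)
  age_fp <- p$lambda_AGE * hill_activation(p$G1, p$K_GLU, p$n_GLU) / p$mu_AGE
  expect_equal(unname(ss["AGE"]), age_fp, tolerance = 1e-9)
  orc <- oracle_steady_state(p, p$G1, age_anchor = NULL)
  expect_equal(as.numeric(ss), unname(orc), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("removing macrophage recruitment empties the macrophage pool", {
  p <- gf_params(lambda_MAC = 1e-30)  # effectively zero, within positivity rules
  ss <- steady_state(p)
  expect_lt(ss["MAC"], 1e-30)
  # and the simulated pool decays exponentially at mu_MAC
  init <- steady_state(p_def)
  tr <- simulate_model(p, horizon_weeks = 4, init = init)
  mac <- tr$MAC
  expected <- init["MAC"] * exp(-p$mu_MAC * tr$time_days)
  expect_equal(mac, unname(expected), tolerance = 1e-5)
})

test_that("simulated AGE matches the closed-form relaxation when glucose is
           held constant", {
  p <- p_def
  init <- steady_state(p)
  init["AGE"] <- 5e-6   # displaced, as after a diabetic episode
  tr <- simulate_model(p, horizon_weeks = 40, init = init,
                       scenario = gf_scenario("glucose_control", t_treat = 0))
  expect_equal(tr$AGE, oracle_age_decay(p, p$G1, 5e-6, tr$time_days),
               tolerance = 1e-7)
})

test_that("base case over 24 weeks: fibrotic switch, AGE still rising", {
  p <- p_def
  tr <- simulate_model(p, horizon_weeks = 24)
  # AGE turns around at the glucose ramp and rises monotonically thereafter
  # (the anchored initial AGE sits slightly above the model's own baseline
  # fixed point, so there is a small residual decline up to ~week 6)
  expect_lt(abs(tr$time_weeks[which.min(tr$AGE)] - 6), 0.5)
  age <- tr$AGE[tr$time_weeks >= 6.5]
  expect_true(all(diff(age) > 0))
  flags <- attr(tr, "at_steady_state")
  expect_false(flags[["AGE"]])
  d_end <- derivatives(24 * 7, unlist(tr[nrow(tr), gf_species()]), p)
  expect_gt(abs(d_end["AGE"]) / tr$AGE[nrow(tr)], 1e-3)
  # collagen accumulates well above the healthy state
  expect_gt(tr$COL[nrow(tr)] / tr$COL[1], 1)
  # every species stays non-negative
  for (sp in gf_species()) expect_true(all(tr[[sp]] >= 0))
  # every Hill activation factor stays in [0, 1] along the trajectory
  for (act in list(hill_activation(tr$glucose, p$K_GLU, p$n_GLU),
                   hill_activation(tr$MCP, p$K_MCP, p$n_MCP),
                   hill_activation(tr$TGF, p$K_TGF, p$n_TGF)))
    expect_true(all(act >= 0 & act <= 1))
})

test_that("24-week collagen responds monotonically to the diabetic glucose
           level", {
  init <- steady_state(p_def)
  col24 <- vapply(c(3e-3, 5e-3, 8e-3), function(g2) {
    p <- gf_params(G2 = g2)
    tr <- simulate_model(p, horizon_weeks = 24, init = init, grid_days = 1)
    tr$COL[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(col24) > 0))
})

test_that("day/week time bases are self-consistent under rate rescaling", {
  # scaling every per-day rate by 7 and the clock by 1/7 must leave the
  # trajectory unchanged: a silent unit mix would break this exactly
  p <- p_def
  rates <- c("lambda_AGE", "mu_AGE", "S_MCP", "lambda_MCP", "mu_MCP",
             "lambda_MAC", "mu_MAC", "S_TGF", "lambda_TGF", "mu_TGF",
             "S_AMC", "lambda_AMC", "mu_AMC", "mu_AMC_vitro", "lambda_MMP",
             "gamma_MMP", "mu_MMP", "lambda_TIMP", "gamma_TIMP", "mu_TIMP",
             "lambda_COL", "lambda_COLA", "mu_COL", "gamma_COL")
  q <- unclass(p)
  for (r in rates) q[[r]] <- q[[r]] * 7
  q$t1 <- q$t1 / 7; q$t2 <- q$t2 / 7
  q$t_half_COL_mature <- q$t_half_COL_mature / 7
  q <- do.call(gf_params, q)
  init <- steady_state(p)
  tr_days <- simulate_model(p, horizon_weeks = 24, init = init, grid_days = 7)
  tr_scaled <- simulate_model(q, horizon_weeks = 24 / 7, init = init,
                              grid_days = 1)
  for (sp in gf_species())
    expect_equal(tr_scaled[[sp]], tr_days[[sp]], tolerance = 1e-6)
})

test_that("trajectories round-trip through the fixed CSV layout", {
  tr <- simulate_model(p_def, horizon_weeks = 2, grid_days = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  hdr <- readLines(f, n = 1)
  expect_identical(hdr, "time_weeks,glucose,AGE,MCP,MAC,TGF,AMC,MMP,TIMP,COL")
  back <- read_trajectory(f)
  for (sp in gf_species())
    expect_equal(back[[sp]], tr[[sp]], tolerance = 1e-14)
  # two identical runs produce byte-identical files
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(simulate_model(p_def, horizon_weeks = 2, grid_days = 1), f2)
  expect_identical(readLines(f), readLines(f2))
})
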