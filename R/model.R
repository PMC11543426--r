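#' Right-hand side of the fibrosis network ODEs
#'
#' Time derivatives, in g/mL/day, of the eight dynamic species in the fixed
#' order AGE, MCP, MAC, TGF, AMC, MMP, TIMP, COL. Glucose is a prescribed
#' input ([glucose_input()]); the mesangial-cell density `MC` is constant.
#' The collagen lysis term is `gamma_COL * MMP` exactly as the model defines
#' it (no collagen factor), so collagen positivity is a property to be
#' verified, not enforced.
#'
#' Interventions enter through `modifiers`: the AGE production term is divided
#' by `production_divisor`, the AGE degradation term multiplied by
#' `degradation_multiplier`, and `glucose_override` (if non-`NULL`) replaces
#' the glucose input. [build_modifiers()] produces these from a scenario.
#'
#' @param t time in days.
#' @param state named numeric vector of the 8 species concentrations, g/mL.
#' @param params a [gf_params()] object.
#' @param modifiers list with elements `production_divisor`,
#'   `degradation_multiplier` (both >= 1) and `glucose_override` (g/mL or
#'   `NULL`); defaults to the identity (base case).
#' @return named numeric vector of derivatives in the species order.
#' @export
derivatives <- function(t, state, params, modifiers = identity_modifiers()) {
  if (length(state) != length(GF_SPECIES))
    stop("state must have exactly ", length(GF_SPECIES), " components (",
         paste(GF_SPECIES, collapse = ", "), ")", call. = FALSE)
  if (is.null(names(state))) names(state) <- GF_SPECIES
  p <- params
  glu <- if (!is.null(modifiers$glucose_override)) modifiers$glucose_override
         else glucose_input(t, p)
  s <- as.list(state)
  dAGE <- p$lambda_AGE * hill_activation(glu, p$K_GLU, p$n_GLU) /
            modifiers$production_divisor -
          p$mu_AGE * s$AGE * modifiers$degradation_multiplier
  dMCP <- p$S_MCP + p$lambda_MCP * s$AGE / (p$K_AGE + s$AGE) * p$MC -
          p$mu_MCP * s$MCP
  dMAC <- p$lambda_MAC * hill_activation(s$MCP, p$K_MCP, p$n_MCP) * p$MAC0 -
          p$mu_MAC * s$MAC
  dTGF <- p$S_TGF + p$lambda_TGF * s$MAC - p$mu_TGF * s$TGF
  dAMC <- p$S_AMC + p$lambda_AMC * hill_activation(s$TGF, p$K_TGF, p$n_TGF) * p$MC -
          p$mu_AMC * s$AMC
  dMMP <- p$lambda_MMP * s$MAC - p$gamma_MMP * s$MMP * s$TIMP - p$mu_MMP * s$MMP
  dTIMP <- p$lambda_TIMP * s$MAC - p$gamma_TIMP * s$MMP * s$TIMP - p$mu_TIMP * s$TIMP
  dCOL <- p$lambda_COL * p$MC + p$lambda_COLA * s$AMC - p$mu_COL * s$COL -
          p$gamma_COL * s$MMP
  setNames(c(dAGE, dMCP, dMAC, dTGF, dAMC, dMMP, dTIMP, dCOL), GF_SPECIES)
}

identity_modifiers <- function() {
  list(production_divisor = 1, degradation_multiplier = 1, glucose_override = NULL)
}

## deSolve-facing wrapper; `anchor_age` freezes AGE (used for anchored
## steady-state initialisation where AGE is a literature value, not a model
## fixed point).
gf_ode_func <- function(t, y, parms) {
  d <- derivatives(t, y, parms$params, parms$modifiers)
  if (isTRUE(parms$anchor_age)) d["AGE"] <- 0
  list(d)
}

#' Integrate the fibrosis model
#'
#' Runs the stiff implicit integrator (`deSolve::lsoda`) over a caller-chosen
#' grid and returns a `gf_trajectory`: a data frame with time (weeks and
#' days), the prescribed glucose input and the eight species concentrations,
#' plus solver metadata and a per-species steady-state diagnostic (relative
#' derivative below 1e-3/day at the final time).
#'
#' Default tolerances are tight (`rtol = 1e-8`, `atol = 1e-15` g/mL) because
#' the state spans roughly 1e-13 to 1 g/mL; a uniform coarse absolute
#' tolerance would drown the macrophage dynamics.
#'
#' @param params a [gf_params()] object.
#' @param horizon_weeks simulation horizon in weeks (> 0).
#' @param init named initial state (g/mL) in the species order; default is the
#'   healthy steady state from [steady_state()] with AGE anchored at the
#'   literature baseline 1.5e-7 g/mL.
#' @param scenario a [gf_scenario()]; default is the untreated base case.
#' @param grid_days output grid spacing in days.
#' @param rtol,atol solver tolerances.
#' @param t_start_weeks start of the integration window (used internally when
#'   restarting at a treatment time).
#' @return a `gf_trajectory` data frame.
#' @examples
#' traj <- simulate_model(gf_params(), horizon_weeks = 24)
#' summary(traj)
#' @export
simulate_model <- function(params, horizon_weeks = 24, init = NULL,
                           scenario = gf_scenario("base"), grid_days = 0.5,
                           rtol = 1e-8, atol = 1e-15, t_start_weeks = 0) {
  stopifnot(horizon_weeks > t_start_weeks, grid_days > 0, rtol > 0, atol > 0)
  if (is.null(init)) init <- steady_state(params)
  init <- init[GF_SPECIES]
  if (any(is.na(init)) || any(init < 0))
    stop("initial state must be non-negative and cover all species", call. = FALSE)
  t0 <- t_start_weeks * GF_DAYS_PER_WEEK
  tend <- horizon_weeks * GF_DAYS_PER_WEEK
  times <- unique(sort(c(seq(t0, tend, by = grid_days), tend,
                         ## glucose ramp breakpoints, if inside the window
                         intersect_pts(c(params$t1, params$t2) * GF_DAYS_PER_WEEK,
                                       t0, tend))))
  mods <- scenario_phase_modifiers(scenario, params, t0)
  out <- run_lsoda(init, times, params, mods, rtol, atol)
  make_trajectory(out, params, scenario, rtol, atol)
}

intersect_pts <- function(x, lo, hi) x[x > lo & x < hi]

run_lsoda <- function(init, times, params, modifiers, rtol, atol) {
  out <- deSolve::lsoda(y = init, times = times, func = gf_ode_func,
                        parms = list(params = params, modifiers = modifiers,
                                     anchor_age = FALSE),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  di <- attr(out, "istate")
  if (is.null(di) || di[1] < 0)
    stop("ODE integration failed near t = ", max(out[, "time"]),
         " days (solver status ", if (!is.null(di)) di[1] else NA, ")",
         call. = FALSE)
  out
}

make_trajectory <- function(out, params, scenario, rtol, atol) {
  tdays <- out[, "time"]
  mods_end <- scenario_phase_modifiers(scenario, params, max(tdays))
  glu <- vapply(tdays, function(tt) {
    m <- scenario_phase_modifiers(scenario, params, tt)
    if (!is.null(m$glucose_override)) m$glucose_override else glucose_input(tt, params)
  }, numeric(1))
  traj <- data.frame(time_weeks = tdays / GF_DAYS_PER_WEEK,
                     time_days = tdays, glucose = glu)
  for (sp in GF_SPECIES) traj[[sp]] <- out[, sp]
  ## steady-state diagnostic at the final time
  yend <- setNames(as.numeric(out[nrow(out), GF_SPECIES]), GF_SPECIES)
  dend <- derivatives(max(tdays), yend, params, mods_end)
  at_ss <- abs(dend) < pmax(atol, 1e-3 * abs(yend))
  structure(traj, class = c("gf_trajectory", "data.frame"),
            params = params, scenario = scenario,
            solver = list(rtol = rtol, atol = atol, n_steps = nrow(out)),
            at_steady_state = at_ss)
}

#' Healthy or fixed-glucose steady state
#'
#' Solves the model's fixed point at a constant glucose concentration by
#' long-horizon integration followed by a damped Newton polish on the
#' algebraic balance. When `age_anchor` is supplied (the default: the
#' literature serum baseline of the long-lived AGE), AGE is held at that value
#' and the remaining seven species are solved; this is how the model's initial
#' values are produced, since the baseline AGE concentration comes from
#' measurements rather than from the model's own glucose fixed point.
#'
#' @param params a [gf_params()] object.
#' @param glucose constant glucose concentration, g/mL; default `params$G1`.
#' @param age_anchor AGE concentration to hold fixed (g/mL), or `NULL` to let
#'   AGE relax to its own fixed point `lambda_AGE * Pi(glucose) / mu_AGE`.
#' @param horizon_days integration horizon used before polishing.
#' @param tol relative residual tolerance for convergence
#'   (`|dX/dt| < max(atol, tol * |X|)` per day for every solved species).
#' @param rtol,atol integrator tolerances.
#' @return named numeric vector of the 8 species concentrations (class
#'   retains the fixed ordering), with attribute `residual` holding the final
#'   derivative vector.
#' @examples
#' ss <- steady_state(gf_params())
#' ss["MAC"]   # healthy glomerular macrophage concentration
#' @export
steady_state <- function(params, glucose = params$G1, age_anchor = 1.5e-7,
                         horizon_days = 6000, tol = 1e-9,
                         rtol = 1e-10, atol = 1e-18) {
  stopifnot(glucose > 0)
  anchored <- !is.null(age_anchor)
  age0 <- if (anchored) age_anchor else params$lambda_AGE *
    hill_activation(glucose, params$K_GLU, params$n_GLU) / params$mu_AGE
  init <- setNames(c(age0, 1e-10, 1e-13, 1e-10, 1e-4, 1e-6, 1e-9, 1), GF_SPECIES)
  mods <- identity_modifiers()
  mods$glucose_override <- glucose
  out <- deSolve::lsoda(init, c(0, horizon_days / 4, horizon_days), gf_ode_func,
                        parms = list(params = params, modifiers = mods,
                                     anchor_age = anchored),
                        rtol = rtol, atol = atol, maxsteps = 100000)
  y <- setNames(as.numeric(out[nrow(out), GF_SPECIES]), GF_SPECIES)
  y <- newton_polish(y, params, mods, anchored, atol_state = atol)
  res <- derivatives(0, y, params, mods)
  if (anchored) res["AGE"] <- 0
  solved <- if (anchored) setdiff(GF_SPECIES, "AGE") else GF_SPECIES
  ok <- abs(res[solved]) < pmax(atol, tol * abs(y[solved]))
  if (!all(ok))
    stop("steady state did not converge; residuals (g/mL/day): ",
         paste(sprintf("%s=%.3e", solved[!ok], res[solved][!ok]), collapse = ", "),
         call. = FALSE)
  attr(y, "residual") <- res
  y
}

## Damped Newton on the solved components with a scaled finite-difference
## Jacobian; states span ~1e-13..1 g/mL so steps are relative.
newton_polish <- function(y, params, mods, anchored, atol_state,
                          max_iter = 50) {
  solved <- if (anchored) setdiff(GF_SPECIES, "AGE") else GF_SPECIES
  f <- function(v) {
    yy <- y; yy[solved] <- v
    derivatives(0, yy, params, mods)[solved]
  }
  v <- y[solved]
  for (it in seq_len(max_iter)) {
    r <- f(v)
    if (all(abs(r) < pmax(atol_state, 1e-13 * abs(v)))) break
    J <- matrix(0, length(v), length(v))
    for (j in seq_along(v)) {
      h <- max(1e-7 * abs(v[j]), 1e-30)
      vp <- v; vp[j] <- vp[j] + h
      J[, j] <- (f(vp) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      vn <- v + lam * step
      if (all(vn > 0) && sum(f(vn)^2) < sum(r^2)) { v <- vn; break }
      lam <- lam / 2
      if (lam < 1e-6) { vn <- NULL; break }
    }
    if (is.null(vn)) break
  }
  y[solved] <- v
  y
}
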