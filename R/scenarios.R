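#' Treatment scenarios
#'
#' A scenario names the intervention applied to the model, the week at which
#' it starts, and its dimensionless strength `K_I`:
#'
#' * `"base"` — untreated disease course (prescribed glucose ramp only);
#' * `"glucose_control"` — blood glucose stepped back to the healthy baseline
#'   `G1` at `t_treat` (idealised immediate glycaemic control);
#' * `"age_production_inhibition"` — the AGE formation term divided by
#'   `1 + K_I` from `t_treat` on (idealised aminoguanidine-like inhibitor);
#' * `"age_degradation_enhanced"` — the AGE degradation term multiplied by
#'   `1 + K_I` from `t_treat` on (idealised cross-link breaker).
#'
#' @param kind one of the four scenario kinds above.
#' @param t_treat treatment start, weeks (default 24, the conventional end of
#'   the disease-development window).
#' @param K_I inhibition strength, > 0; ignored for `base`/`glucose_control`.
#' @return an object of class `gf_scenario`.
#' @examples
#' gf_scenario("glucose_control")
#' gf_scenario("age_degradation_enhanced", K_I = 1e3)
#' @export
gf_scenario <- function(kind = c("base", "glucose_control",
                                 "age_production_inhibition",
                                 "age_degradation_enhanced"),
                        t_treat = 24, K_I = 1e5) {
  kind <- match.arg(kind)
  if (t_treat < 0) stop("t_treat must be >= 0 (weeks)", call. = FALSE)
  if (kind %in% c("age_production_inhibition", "age_degradation_enhanced") &&
      (!is.numeric(K_I) || K_I <= 0))
    stop("K_I must be > 0 for the AGE interventions", call. = FALSE)
  structure(list(kind = kind, t_treat = t_treat, K_I = K_I),
            class = "gf_scenario")
}

format_scenario <- function(sc) {
  if (sc$kind == "base") return("base case (untreated)")
  extra <- if (sc$kind %in% c("age_production_inhibition",
                              "age_degradation_enhanced"))
    sprintf(", K_I = %g", sc$K_I) else ""
  sprintf("%s at %g weeks%s", gsub("_", " ", sc$kind), sc$t_treat, extra)
}

#' @export
print.gf_scenario <- function(x, ...) {
  cat("Scenario:", format_scenario(x), "\n")
  invisible(x)
}

#' Rate-law modifiers implied by a scenario at a time point
#'
#' Uniform mechanism for expressing the interventions: before `t_treat` every
#' scenario is the identity; from `t_treat` on, glucose control overrides the
#' glucose input with `G1`, AGE-production inhibition sets the production
#' divisor to `1 + K_I`, and enhanced AGE degradation sets the degradation
#' multiplier to `1 + K_I`.
#'
#' @param scenario a [gf_scenario()].
#' @param t time in days.
#' @param params a [gf_params()] object (supplies `G1`).
#' @return list with `production_divisor`, `degradation_multiplier`,
#'   `glucose_override` (or `NULL`).
#' @export
build_modifiers <- function(scenario, t, params) {
  stopifnot(inherits(scenario, "gf_scenario"))
  mods <- identity_modifiers()
  if (scenario$kind == "base" || t < scenario$t_treat * GF_DAYS_PER_WEEK)
    return(mods)
  switch(scenario$kind,
    glucose_control = { mods$glucose_override <- params$G1 },
    age_production_inhibition = { mods$production_divisor <- 1 + scenario$K_I },
    age_degradation_enhanced = { mods$degradation_multiplier <- 1 + scenario$K_I },
    stop("unknown scenario kind: ", scenario$kind, call. = FALSE))
  mods
}

## Modifiers for the integration phase starting at t0 (days). Within a phase
## the modifiers are constant; run_scenario() restarts the solver at t_treat.
scenario_phase_modifiers <- function(scenario, params, t0) {
  if (is.null(scenario)) return(identity_modifiers())
  build_modifiers(scenario, t0, params)
}

#' Run a treatment scenario
#'
#' Integrates the base case up to the treatment time and the modified system
#' afterwards, restarting the solver at the (rate-law) discontinuity so the
#' state itself is continuous at `t_treat`.
#'
#' @param params a [gf_params()] object.
#' @param scenario a [gf_scenario()].
#' @param horizon_weeks total horizon, `>= t_treat`.
#' @param init initial state; default healthy steady state.
#' @param grid_days output grid spacing, days.
#' @param rtol,atol solver tolerances.
#' @return a `gf_trajectory` covering `[0, horizon_weeks]`.
#' @examples
#' \donttest{
#' p <- gf_params()
#' traj <- run_scenario(p, gf_scenario("glucose_control"), horizon_weeks = 120)
#' reversal_time(traj, baseline_col = steady_state(p)["COL"])
#' }
#' @export
run_scenario <- function(params, scenario, horizon_weeks = 120, init = NULL,
                         grid_days = 0.5, rtol = 1e-8, atol = 1e-15) {
  stopifnot(inherits(scenario, "gf_scenario"))
  if (horizon_weeks < scenario$t_treat && scenario$kind != "base")
    stop("horizon must reach the treatment time", call. = FALSE)
  if (is.null(init)) init <- steady_state(params)
  if (scenario$kind == "base" || scenario$t_treat == 0 ||
      horizon_weeks <= scenario$t_treat)
    return(simulate_model(params, horizon_weeks, init, scenario, grid_days,
                          rtol, atol))
  pre <- simulate_model(params, scenario$t_treat, init, gf_scenario("base"),
                        grid_days, rtol, atol)
  y_treat <- setNames(as.numeric(pre[nrow(pre), GF_SPECIES]), GF_SPECIES)
  post <- simulate_model(params, horizon_weeks, y_treat, scenario, grid_days,
                         rtol, atol, t_start_weeks = scenario$t_treat)
  df <- rbind(as.data.frame(pre), as.data.frame(post)[-1, ])
  rownames(df) <- NULL
  structure(df, class = c("gf_trajectory", "data.frame"),
            params = params, scenario = scenario,
            solver = attr(post, "solver"),
            at_steady_state = attr(post, "at_steady_state"))
}

#' Time to complete reversal of fibrosis
#'
#' "Complete reversal" is defined as collagen entering, and remaining within
#' (through the end of the trajectory), a relative band of `rel_tol` around
#' the healthy steady-state collagen concentration. The entry time is refined
#' by linear interpolation between grid points. Both the simulation-clock time
#' and the time elapsed since treatment are reported, since published
#' recovery times mix the two conventions.
#'
#' @param traj a `gf_trajectory` (or data frame with `time_weeks` and `COL`).
#' @param baseline_col healthy steady-state collagen, g/mL.
#' @param rel_tol relative half-width of the reversal band (default 0.05).
#' @return list with `reversed` (logical), `clock_weeks`,
#'   `post_treatment_weeks` (`NA` when no treatment time is attached), and —
#'   when not reversed — `closing_gap`, the final relative distance from
#'   baseline.
#' @export
reversal_time <- function(traj, baseline_col, rel_tol = 0.05) {
  stopifnot(baseline_col > 0, rel_tol > 0)
  tw <- traj$time_weeks
  rel <- abs(traj$COL - baseline_col) / baseline_col
  in_band <- rel <= rel_tol
  stays <- rev(cumprod(rev(in_band))) == 1
  sc <- attr(traj, "scenario")
  t_treat <- if (!is.null(sc) && sc$kind != "base") sc$t_treat else NA_real_
  if (!any(stays))
    return(list(reversed = FALSE, clock_weeks = NA_real_,
                post_treatment_weeks = NA_real_,
                closing_gap = rel[length(rel)]))
  i <- which(stays)[1]
  t_entry <- tw[i]
  if (i > 1) {
    ## refine: linear interpolation of |COL - baseline|/baseline crossing rel_tol
    r0 <- rel[i - 1]; r1 <- rel[i]
    if (r0 > rel_tol && r1 < r0)
      t_entry <- tw[i - 1] + (r0 - rel_tol) / (r0 - r1) * (tw[i] - tw[i - 1])
  }
  list(reversed = TRUE, clock_weeks = t_entry,
       post_treatment_weeks = if (is.na(t_treat)) NA_real_ else t_entry - t_treat)
}

#' Percent reduction of a species between two times
#'
#' `100 * (X(t_ref) - X(t_eval)) / X(t_ref)`; positive values mean the
#' concentration fell. Values are linearly interpolated on the trajectory
#' grid.
#'
#' @param traj a `gf_trajectory`.
#' @param species one of the 8 species names.
#' @param t_ref_weeks,t_eval_weeks reference and evaluation times in weeks,
#'   `t_ref_weeks < t_eval_weeks` within the trajectory window.
#' @return percent reduction (scalar).
#' @export
percent_reduction <- function(traj, species, t_ref_weeks, t_eval_weeks) {
  species <- match.arg(species, GF_SPECIES)
  if (t_ref_weeks > t_eval_weeks)
    stop("t_ref_weeks must not exceed t_eval_weeks", call. = FALSE)
  if (t_eval_weeks > max(traj$time_weeks) + 1e-9)
    stop("t_eval_weeks lies beyond the trajectory horizon", call. = FALSE)
  x0 <- traj_at(traj, species, t_ref_weeks)
  x1 <- traj_at(traj, species, t_eval_weeks)
  if (x0 == 0) stop("reference concentration is zero; reduction undefined",
                    call. = FALSE)
  100 * (x0 - x1) / x0
}
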