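#' Closed-form calibration constants
#'
#' Two parameters have closed forms rather than fitted values. The baseline
#' MCP production rate balances baseline production against degradation in
#' unstimulated culture, `S_MCP = mu_MCP * MCP_vitro`. The AGE removal rate is
#' tied to the half-life of mature cross-linked collagen (the scaffold the
#' long-lived AGE adducts ride on), `mu_AGE = ln(2) / t_half`.
#'
#' @param mu_MCP MCP degradation rate, 1/day.
#' @param MCP_vitro baseline MCP concentration in unstimulated culture, g/mL.
#' @return `smcp_from_baseline()`: production rate in (g/mL)/day.
#' @examples
#' smcp_from_baseline(1.73, 1.60e-10)   # 2.77e-10
#' rate_from_halflife(80)               # 8.7e-3 per day
#' @export
smcp_from_baseline <- function(mu_MCP, MCP_vitro) {
  stopifnot(mu_MCP > 0, MCP_vitro >= 0)
  mu_MCP * MCP_vitro
}

#' @rdname smcp_from_baseline
#' @param t_half half-life in days, > 0.
#' @return `rate_from_halflife()`: first-order rate in 1/day.
#' @export
rate_from_halflife <- function(t_half) {
  if (!is.numeric(t_half) || any(t_half <= 0))
    stop("half-life must be positive", call. = FALSE)
  log(2) / t_half
}

#' Fold change relative to a baseline
#'
#' @param series numeric concentrations.
#' @param baseline positive baseline concentration; maps to fold change 1.
#' @return dimensionless series `series / baseline`.
#' @export
fold_change <- function(series, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1 || baseline <= 0)
    stop("baseline must be a positive scalar", call. = FALSE)
  series / baseline
}

#' Calibration datasets
#'
#' A calibration dataset is a data frame with the fixed column layout
#' `kind, readout, abscissa, value, n_replicates, source` plus a recorded
#' baseline concentration (attribute `baseline`, g/mL) for fold-change data.
#' `kind` is `"timeseries_foldchange"` (abscissa in weeks, values
#' dimensionless fold changes) or `"dose_response"` (abscissa a dose in g/mL,
#' values concentrations in g/mL). Replicates at a design point occupy one row
#' each; `source` carries semicolon-separated study tags so single-study
#' points can be recognised by [exclusion_rule()].
#'
#' @param kind dataset kind.
#' @param readout species or assay name.
#' @param abscissa weeks or doses (one per row).
#' @param value observations (one per row).
#' @param n_replicates replicate count per design point (recycled).
#' @param source study tag(s) per row, `";"`-separated when pooled.
#' @param baseline baseline concentration for fold-change data, g/mL.
#' @return object of class `gf_dataset` (a data frame).
#' @export
gf_dataset <- function(kind = c("timeseries_foldchange", "dose_response"),
                       readout, abscissa, value, n_replicates = 1L,
                       source = "synthetic", baseline = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(length(abscissa) == length(value), all(value > 0))
  pts <- unique(abscissa)
  if (is.unsorted(pts)) stop("abscissa must be increasing", call. = FALSE)
  df <- data.frame(kind = kind, readout = readout, abscissa = abscissa,
                   value = value, n_replicates = as.integer(n_replicates),
                   source = source, stringsAsFactors = FALSE)
  structure(df, class = c("gf_dataset", "data.frame"), baseline = baseline)
}

#' @rdname gf_dataset
#' @param data a `gf_dataset`.
#' @param path CSV path.
#' @export
write_dataset <- function(data, path) {
  df <- as.data.frame(data)[, c("kind", "readout", "abscissa", "value",
                                "n_replicates", "source")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname gf_dataset
#' @export
read_dataset <- function(path, baseline = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gf_dataset(kind = df$kind[1], readout = df$readout, abscissa = df$abscissa,
             value = df$value, n_replicates = df$n_replicates,
             source = df$source, baseline = baseline)
}

#' Single-study exclusion rule
#'
#' For the collagen (MMP/TIMP/collagen) fitting stage, time points supported
#' by only one source study are excluded: a point that no second laboratory
#' corroborates should not constrain the fit. All other stages pass data
#' through unchanged. A point is single-study when its `source` field holds
#' exactly one `";"`-separated study tag.
#'
#' @param data a `gf_dataset`.
#' @param stage calibration stage name.
#' @return the (possibly filtered) dataset.
#' @export
exclusion_rule <- function(data, stage) {
  if (!identical(stage, "mmp_timp_col") || nrow(data) == 0) return(data)
  n_studies <- vapply(strsplit(as.character(data$source), ";", fixed = TRUE),
                      function(s) length(s[nzchar(trimws(s))]), integer(1))
  keep <- n_studies != 1
  out <- data[keep, , drop = FALSE]
  structure(out, class = class(data), baseline = attr(data, "baseline"))
}

## ---- subsystem fitting -----------------------------------------------------

## Which parameters each stage estimates. The network is feed-forward, so a
## stage's readout depends on upstream species but never the reverse; upstream
## trajectories are precomputed once per fit and held fixed.
gf_stage_params <- list(
  age          = c("lambda_AGE", "K_GLU", "n_GLU"),
  mcp          = c("S_MCP", "lambda_MCP", "K_AGE"),
  mac          = c("lambda_MAC", "n_MCP", "mu_MAC"),
  tgf          = c("S_TGF", "lambda_TGF"),
  amc          = c("lambda_AMC", "K_TGF", "S_AMC", "n_TGF"),
  mmp_timp_col = c("lambda_COLA", "gamma_COL")
)

#' Sequential subsystem parameter estimation
#'
#' Implements the staged calibration workflow: parameters are estimated three
#' to four at a time, one species group per stage, with all upstream
#' parameters held fixed, by bounded Levenberg-Marquardt nonlinear least
#' squares (unweighted SSE). Time-series stages fit on the fold-change scale
#' against the dataset's recorded baseline concentration; dose-response
#' stages fit on the concentration scale — matching what each kind of
#' experiment reports. Optimisation is done on log10-transformed parameters
#' (all are positive and span orders of magnitude) from a fixed deterministic
#' set of five multi-starts, keeping the fit reproducible without RNG.
#'
#' Stages and their data:
#' * `age`: `lambda_AGE`, `K_GLU`, `n_GLU` from an AGE fold-change time
#'   series under the glucose ramp.
#' * `mcp`: `S_MCP`, `lambda_MCP`, `K_AGE` from the in vitro MCP
#'   dose-response to AGE.
#' * `mac`: `lambda_MAC`, `n_MCP`, `mu_MAC` from a macrophage fold-change
#'   time series (upstream MCP trajectory fixed).
#' * `tgf`: `S_TGF`, `lambda_TGF` from a TGF-beta fold-change time series.
#' * `amc`: two sub-fits — `lambda_AMC`, `K_TGF` from the in vitro alpha-sma
#'   dose-response to TGF-beta (in vitro death rate `mu_AMC_vitro`), then
#'   `S_AMC`, `n_TGF` from the in vivo activated-cell fold-change series.
#'   Supply a list of two datasets `list(vitro = ..., vivo = ...)`.
#' * `mmp_timp_col`: optionally solves `lambda_MMP` so the healthy MMP steady
#'   state matches `mmp_ss_target` (with `lambda_TIMP` constrained to
#'   `lambda_MMP / 5`), then fits `lambda_COLA`, `gamma_COL` to a collagen
#'   fold-change series after the single-study [exclusion_rule()].
#'
#' @param stage one of `"age"`, `"mcp"`, `"mac"`, `"tgf"`, `"amc"`,
#'   `"mmp_timp_col"`.
#' @param data a `gf_dataset`, or for stage `"amc"` a list
#'   `list(vitro = , vivo = )`.
#' @param params current parameter set; upstream values are taken from here
#'   and are not altered.
#' @param initial_guess named vector of starting values for the stage's free
#'   parameters; defaults to the values in `params`.
#' @param bounds list with named vectors `lower`/`upper`; default is
#'   `[1e-3, 1e3]` times the default parameter value, with Hill exponents
#'   floored at 1.
#' @param mmp_ss_target for stage `"mmp_timp_col"`: healthy steady-state MMP
#'   concentration (g/mL) used to solve `lambda_MMP`, or `NULL` to leave
#'   `lambda_MMP` untouched.
#' @param multistart logical; use the fixed 5-start schedule (default) or the
#'   single supplied start.
#' @return an object of class `gf_fit`: estimates, residual sum of squares,
#'   convergence flag, bounds, and the updated full parameter set
#'   (`$params`).
#' @export
fit_subsystem <- function(stage, data, params, initial_guess = NULL,
                          bounds = NULL, mmp_ss_target = NULL,
                          multistart = TRUE) {
  stage <- match.arg(stage, names(gf_stage_params))
  free <- gf_stage_params[[stage]]
  check_stage_data(stage, data)
  p <- params
  extra <- list()
  if (stage == "mmp_timp_col" && !is.null(mmp_ss_target)) {
    p$lambda_MMP <- solve_lambda_mmp(p, mmp_ss_target)
    p$lambda_TIMP <- p$lambda_MMP / 5
    extra <- list(lambda_MMP = p$lambda_MMP, lambda_TIMP = p$lambda_TIMP)
  }
  if (stage == "amc") return(fit_amc(data, p, initial_guess, bounds, multistart,
                                     extra))
  if (stage == "mmp_timp_col") data <- exclusion_rule(data, stage)
  resid_fn <- stage_residual_fn(stage, data, p)
  run_stage_fit(stage, free, resid_fn, p, initial_guess, bounds, multistart,
                data, extra)
}

check_stage_data <- function(stage, data) {
  want_dr <- stage %in% c("mcp")
  if (stage == "amc") {
    if (!is.list(data) || !all(c("vitro", "vivo") %in% names(data)))
      stop("stage 'amc' needs data = list(vitro = <dose_response>, ",
           "vivo = <timeseries_foldchange>)", call. = FALSE)
    if (data$vitro$kind[1] != "dose_response" ||
        data$vivo$kind[1] != "timeseries_foldchange")
      stop("stage 'amc' data kinds are reversed", call. = FALSE)
    return(invisible(TRUE))
  }
  if (!inherits(data, "gf_dataset") || nrow(data) == 0)
    stop("calibration data must be a non-empty gf_dataset", call. = FALSE)
  kind <- data$kind[1]
  if (want_dr && kind != "dose_response")
    stop("stage '", stage, "' expects dose-response data", call. = FALSE)
  if (!want_dr && kind != "timeseries_foldchange")
    stop("stage '", stage, "' expects fold-change time-series data", call. = FALSE)
  invisible(TRUE)
}

## default box bounds: 1e±3 times the default value; Hill exponents >= 1
stage_bounds <- function(free, bounds) {
  def <- unlist(gf_default_parameters()[free])
  lower <- def * 1e-3
  upper <- def * 1e3
  hill <- intersect(free, c("n_GLU", "n_MCP", "n_TGF"))
  lower[hill] <- pmax(lower[hill], 1)
  upper[hill] <- pmin(upper[hill], 20)  # exponents beyond ~20 are numerically moot
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  list(lower = lower, upper = upper)
}

run_stage_fit <- function(stage, free, resid_fn, params, initial_guess, bounds,
                          multistart, data, extra = list()) {
  b <- stage_bounds(free, bounds)
  start <- unlist(params[free])
  if (!is.null(initial_guess)) {
    if (!all(names(initial_guess) %in% free))
      stop("initial_guess names must be among: ", paste(free, collapse = ", "),
           call. = FALSE)
    start[names(initial_guess)] <- initial_guess
  }
  start <- pmin(pmax(start, b$lower), b$upper)
  ## fixed multi-start schedule (scale factors applied to every free parameter)
  factors <- if (multistart) c(1, 0.2, 5, 0.04, 25) else 1
  best <- NULL
  for (f in factors) {
    s <- pmin(pmax(start * f, b$lower), b$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log10(s),
                         lower = log10(b$lower), upper = log10(b$upper),
                         fn = function(lp) resid_fn(setNames(10^lp, free)),
                         control = minpack.lm::nls.lm.control(maxiter = 200,
                                                              ftol = 1e-12,
                                                              ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(new_gf_fit(stage, setNames(start, free), NA_real_, FALSE, b, params,
                      data, "all starts failed", extra))
  est <- setNames(10^best$fit$par, free)
  conv <- best$fit$info %in% 1:4
  p_new <- params
  p_new[free] <- as.list(est)
  new_gf_fit(stage, est, best$rss, conv, b, p_new, data, best$fit$message, extra)
}

new_gf_fit <- function(stage, estimates, rss, converged, bounds, params, data,
                       message = "", extra = list()) {
  structure(list(stage = stage, estimates = c(extra, as.list(estimates)),
                 rss = rss, converged = converged, bounds = bounds,
                 params = params, data = data, message = message),
            class = "gf_fit")
}

#' @export
print.gf_fit <- function(x, ...) {
  cat("Subsystem fit, stage '", x$stage, "'",
      if (!isTRUE(x$converged)) " (NOT converged)", "\n", sep = "")
  est <- unlist(x$estimates)
  print(data.frame(estimate = signif(est, 4)))
  cat("residual sum of squares:", format(x$rss, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.gf_fit <- function(object, ...) unlist(object$estimates)

#' @export
summary.gf_fit <- function(object, ...) {
  cat("stage:", object$stage, "\n")
  cat("converged:", object$converged, "| RSS:", format(object$rss, digits = 6),
      "\n")
  est <- unlist(object$estimates)
  fitted_names <- intersect(names(est), names(object$bounds$lower))
  df <- data.frame(estimate = est[fitted_names],
                   lower = object$bounds$lower[fitted_names],
                   upper = object$bounds$upper[fitted_names])
  print(df)
  invisible(object)
}

## fit result -> JSON (flat, machine-readable)
#' @rdname fit_subsystem
#' @param fit a `gf_fit`.
#' @param path output JSON path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(list(stage = fit$stage, estimates = fit$estimates,
                            rss = fit$rss, converged = fit$converged,
                            bounds = lapply(fit$bounds, as.list)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- stage prediction machinery -------------------------------------------

## Upstream drive for a stage: simulate the base case once with the current
## parameters and return interpolators. Downstream species never feed back,
## so these are exact inputs for any candidate stage parameters.
upstream_drive <- function(params, horizon_weeks) {
  traj <- simulate_model(params, horizon_weeks = horizon_weeks, grid_days = 0.25)
  lapply(setNames(GF_SPECIES, GF_SPECIES), function(sp)
    stats::approxfun(traj$time_days, traj[[sp]], rule = 2))
}

## Integrate a single linear species balance dy/dt = f(t) - mu * y.
## Every stage fits one species whose own equation is linear with a fixed
## upstream forcing, so an exponential integrator that is exact for
## piecewise-linear f (the resolution at which upstream trajectories are
## interpolated anyway) replaces a stiff ODE call inside the optimiser.
integrate_one <- function(forcing_fn, mu, y0, t_days, dt = 0.25) {
  tmax <- max(t_days, dt)
  n <- ceiling(tmax / dt) + 1L
  grid <- seq(0, tmax, length.out = n)
  f <- forcing_fn(grid)
  h <- grid[2]
  e <- exp(-mu * h)
  A <- -expm1(-mu * h) / mu          # int_0^h exp(-mu (h - s)) ds
  C <- (1 - e * (1 + mu * h)) / mu^2 # int_0^h u exp(-mu u) du
  g <- f[-n] * (C / h) + f[-1] * (A - C / h)
  y <- c(y0, stats::filter(g, e, method = "recursive", init = y0))
  stats::approx(grid, as.numeric(y), xout = t_days, rule = 2)$y
}

stage_residual_fn <- function(stage, data, params) {
  baseline <- attr(data, "baseline")
  t_days <- data$abscissa * GF_DAYS_PER_WEEK
  horizon <- max(data$abscissa, 24)
  if (stage == "age") {
    if (is.na(baseline)) stop("AGE fold-change data needs a recorded baseline",
                              call. = FALSE)
    function(th) {
      p <- modifyList(params, as.list(th))
      pred <- integrate_one(function(t)
        p$lambda_AGE * hill_activation(glucose_input(t, p), p$K_GLU, p$n_GLU),
        p$mu_AGE, baseline, t_days)
      pred / baseline - data$value
    }
  } else if (stage == "mcp") {
    function(th) {
      p <- modifyList(params, as.list(th))
      pred <- (p$S_MCP + p$lambda_MCP * data$abscissa /
                 (p$K_AGE + data$abscissa) * p$MC) / p$mu_MCP
      pred - data$value
    }
  } else if (stage == "mac") {
    drive <- upstream_drive(params, horizon)
    mcp_ss <- drive$MCP(0)
    function(th) {
      p <- modifyList(params, as.list(th))
      y0 <- p$lambda_MAC * hill_activation(mcp_ss, p$K_MCP, p$n_MCP) * p$MAC0 /
        p$mu_MAC
      pred <- integrate_one(function(t)
        p$lambda_MAC * hill_activation(drive$MCP(t), p$K_MCP, p$n_MCP) * p$MAC0,
        p$mu_MAC, y0, t_days)
      pred / baseline - data$value
    }
  } else if (stage == "tgf") {
    drive <- upstream_drive(params, horizon)
    mac_ss <- drive$MAC(0)
    function(th) {
      p <- modifyList(params, as.list(th))
      y0 <- (p$S_TGF + p$lambda_TGF * mac_ss) / p$mu_TGF
      pred <- integrate_one(function(t) p$S_TGF + p$lambda_TGF * drive$MAC(t),
                            p$mu_TGF, y0, t_days)
      pred / baseline - data$value
    }
  } else if (stage == "mmp_timp_col") {
    drive <- upstream_drive(params, horizon)
    amc_ss <- drive$AMC(0); mmp_ss <- drive$MMP(0)
    function(th) {
      p <- modifyList(params, as.list(th))
      y0 <- (p$lambda_COL * p$MC + p$lambda_COLA * amc_ss -
               p$gamma_COL * mmp_ss) / p$mu_COL
      pred <- integrate_one(function(t)
        p$lambda_COL * p$MC + p$lambda_COLA * drive$AMC(t) -
          p$gamma_COL * drive$MMP(t),
        p$mu_COL, y0, t_days)
      pred / baseline - data$value
    }
  } else stop("no residual function for stage ", stage, call. = FALSE)
}

## In vitro alpha-sma steady state as a function of TGF-beta dose (uses the
## slower in vitro death rate).
amc_dose_response <- function(dose, p) {
  (p$S_AMC + p$lambda_AMC * hill_activation(dose, p$K_TGF, p$n_TGF) * p$MC) /
    p$mu_AMC_vitro
}

fit_amc <- function(data, params, initial_guess, bounds, multistart, extra) {
  ## sub-fit 1: lambda_AMC, K_TGF on the in vitro dose-response
  dr <- data$vitro
  res1 <- function(th) {
    p <- modifyList(params, as.list(th))
    amc_dose_response(dr$abscissa, p) - dr$value
  }
  f1 <- run_stage_fit("amc", c("lambda_AMC", "K_TGF"), res1, params,
                      initial_guess[intersect(names(initial_guess),
                                              c("lambda_AMC", "K_TGF"))],
                      bounds, multistart, dr)
  ## sub-fit 2: S_AMC, n_TGF on the in vivo fold-change series
  p_mid <- f1$params
  ts <- data$vivo
  baseline <- attr(ts, "baseline")
  t_days <- ts$abscissa * GF_DAYS_PER_WEEK
  drive <- upstream_drive(p_mid, max(ts$abscissa, 24))
  tgf_ss <- drive$TGF(0)
  res2 <- function(th) {
    p <- modifyList(p_mid, as.list(th))
    y0 <- (p$S_AMC + p$lambda_AMC *
             hill_activation(tgf_ss, p$K_TGF, p$n_TGF) * p$MC) / p$mu_AMC
    pred <- integrate_one(function(t)
      p$S_AMC + p$lambda_AMC *
        hill_activation(drive$TGF(t), p$K_TGF, p$n_TGF) * p$MC,
      p$mu_AMC, y0, t_days)
    pred / baseline - ts$value
  }
  f2 <- run_stage_fit("amc", c("S_AMC", "n_TGF"), res2, p_mid,
                      initial_guess[intersect(names(initial_guess),
                                              c("S_AMC", "n_TGF"))],
                      bounds, multistart, ts)
  est <- c(f1$estimates[c("lambda_AMC", "K_TGF")],
           f2$estimates[c("S_AMC", "n_TGF")])
  b <- stage_bounds(gf_stage_params$amc, bounds)
  new_gf_fit("amc", unlist(est), f1$rss + f2$rss,
             isTRUE(f1$converged) && isTRUE(f2$converged), b, f2$params,
             data, paste(f1$message, f2$message, sep = " / "), extra)
}

## lambda_MMP such that the healthy-steady-state MMP equals `target`
## (lambda_TIMP tied to lambda_MMP/5). At the fixed point,
## MMP (gamma_MMP TIMP + mu_MMP) = lambda_MMP MAC and
## TIMP (gamma_TIMP MMP + mu_TIMP) = (lambda_MMP/5) MAC; eliminating TIMP
## leaves a monotone scalar equation in lambda_MMP.
solve_lambda_mmp <- function(params, target) {
  stopifnot(target > 0)
  ss <- steady_state(params)
  mac <- ss[["MAC"]]
  g <- function(lam) {
    timp <- (lam / 5) * mac / (params$gamma_TIMP * target + params$mu_TIMP)
    lam * mac / (params$gamma_MMP * timp + params$mu_MMP) - target
  }
  stats::uniroot(g, lower = params$lambda_MMP * 1e-6,
                 upper = params$lambda_MMP * 1e6, tol = 1e-12)$root
}
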