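#' Noise model for synthetic calibration data
#'
#' Pooled inter-study fold-change data are positive and right-skewed, so the
#' generator uses multiplicative log-normal noise calibrated to mean 1: a
#' noiseless expectation is unbiased at every coefficient of variation. With
#' `kind = "none"` the CV is forced to zero and the data are exact.
#'
#' @param kind `"none"` or `"multiplicative_lognormal"`.
#' @param cv coefficient of variation of the multiplicative factor (>= 0).
#' @param seed integer RNG seed; identical seeds reproduce identical datasets.
#' @param replicates replicates per design point (>= 1).
#' @return object of class `gf_noise`.
#' @export
noise_model <- function(kind = c("none", "multiplicative_lognormal"),
                        cv = 0, seed = 1L, replicates = 1L) {
  kind <- match.arg(kind)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (kind == "none") cv <- 0
  if (kind == "multiplicative_lognormal" && cv == 0)
    stop("multiplicative noise needs cv > 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(kind = kind, cv = cv, seed = as.integer(seed),
                 replicates = as.integer(replicates)), class = "gf_noise")
}

## mean-1 log-normal factors: sigma^2 = log(1 + cv^2), mu = -sigma^2/2
noise_factors <- function(noise, n) {
  if (noise$kind == "none" || noise$cv == 0) return(rep(1, n))
  sigma2 <- log(1 + noise$cv^2)
  exp(stats::rnorm(n, mean = -sigma2 / 2, sd = sqrt(sigma2)))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

## default in vivo sampling designs: sparse for AGE and the activated-cell
## surrogate (two time points, mirroring the scarcity of those measurements),
## denser for the well-replicated readouts. The 10-week collagen point is
## tagged as single-study so the exclusion rule has a realistic target.
gf_default_design <- list(
  AGE = c(8, 24),
  MAC = c(0, 4, 8, 12, 16, 20, 24),
  TGF = c(0, 6, 12, 18, 24),
  AMC = c(12, 24),
  COL = c(0, 4, 8, 10, 12, 16, 20, 24)
)

#' Generate a synthetic fold-change time series
#'
#' Simulates the untreated disease course, reads the chosen species at the
#' sampling weeks, converts to fold change relative to the healthy steady
#' state, and applies the noise model independently per replicate. For the
#' activated mesangial cells the readout plays the role of the alpha-sma
#' surrogate marker used in vivo.
#'
#' @param params a [gf_params()] object.
#' @param readout one of `"AGE"`, `"MAC"`, `"TGF"`, `"AMC"`, `"COL"`.
#' @param sample_weeks sampling times in `[0, 24]` weeks; default is the
#'   readout-specific design in `gf_default_design`.
#' @param noise a [noise_model()].
#' @return a [gf_dataset()] of kind `"timeseries_foldchange"` with the
#'   healthy steady-state concentration recorded as its baseline.
#' @export
generate_timeseries <- function(params, readout = c("AGE", "MAC", "TGF",
                                                    "AMC", "COL"),
                                sample_weeks = NULL,
                                noise = noise_model("none")) {
  readout <- match.arg(readout)
  if (is.null(sample_weeks)) sample_weeks <- gf_default_design[[readout]]
  if (any(sample_weeks < 0 | sample_weeks > 24))
    stop("sample weeks must lie within [0, 24]", call. = FALSE)
  sample_weeks <- sort(sample_weeks)
  traj <- simulate_model(params, horizon_weeks = 24, grid_days = 0.25)
  baseline <- traj[[readout]][1]
  fc <- fold_change(traj_at(traj, readout, sample_weeks), baseline)
  nrep <- noise$replicates
  vals <- with_seed(noise$seed,
                    rep(fc, each = nrep) * noise_factors(noise,
                                                         length(fc) * nrep))
  src <- if (readout == "COL")
    ifelse(rep(sample_weeks, each = nrep) == 10, "s9", "s1;s2;s3")
  else "s1;s2"
  gf_dataset(kind = "timeseries_foldchange", readout = readout,
             abscissa = rep(sample_weeks, each = nrep), value = vals,
             n_replicates = nrep, source = src, baseline = baseline)
}

#' Generate a synthetic in vitro dose-response curve
#'
#' Analytic steady-state responses of the two culture assays used for
#' calibration: MCP released by mesangial cells as a function of the AGE dose
#' (Michaelis-Menten in AGE), and alpha-sma (activated-cell marker) as a
#' function of the TGF-beta dose (Hill in TGF-beta, with the in vitro death
#' rate). Both saturate at high dose; noise is applied per replicate.
#'
#' @param params a [gf_params()] object.
#' @param assay `"mcp_vs_age"` or `"asma_vs_tgf"`.
#' @param doses positive dose grid in g/mL; default spans 0.1-10 times the
#'   assay's saturation constant plus a zero-dose control.
#' @param noise a [noise_model()].
#' @return a [gf_dataset()] of kind `"dose_response"` (values in g/mL).
#' @export
generate_dose_response <- function(params, assay = c("mcp_vs_age",
                                                     "asma_vs_tgf"),
                                   doses = NULL, noise = noise_model("none")) {
  assay <- match.arg(assay)
  if (is.null(doses)) {
    K <- if (assay == "mcp_vs_age") params$K_AGE else params$K_TGF
    doses <- c(0, K * 10^seq(-1, 1, length.out = 7))
  }
  if (length(doses) == 0) stop("dose list must be non-empty", call. = FALSE)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  doses <- sort(doses)
  resp <- if (assay == "mcp_vs_age") {
    (params$S_MCP + params$lambda_MCP * doses / (params$K_AGE + doses) *
       params$MC) / params$mu_MCP
  } else {
    amc_dose_response(doses, params)
  }
  nrep <- noise$replicates
  vals <- with_seed(noise$seed,
                    rep(resp, each = nrep) * noise_factors(noise,
                                                           length(resp) * nrep))
  gf_dataset(kind = "dose_response", readout = assay,
             abscissa = rep(doses, each = nrep), value = vals,
             n_replicates = nrep, source = "s1;s2")
}
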