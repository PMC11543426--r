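# Independent oracles used to cross-check the package's solvers. These are
# deliberately written from the algebraic structure of the network (plain
# arithmetic, no calls into the package's steady-state or ODE machinery).

# Sequential fixed-point solve exploiting the feed-forward topology:
# AGE -> MCP -> MAC -> TGF -> AMC -> (MMP, TIMP) -> COL. The MMP/TIMP pair is
# mutually coupled and solved by damped fixed-point iteration.
oracle_steady_state <- function(p, glucose, age_anchor = NULL) {
  hillf <- function(X, K, n) { r <- (X / K)^n; r / (1 + r) }
  AGE <- if (is.null(age_anchor))
    p$lambda_AGE * hillf(glucose, p$K_GLU, p$n_GLU) / p$mu_AGE else age_anchor
  MCP <- (p$S_MCP + p$lambda_MCP * AGE / (p$K_AGE + AGE) * p$MC) / p$mu_MCP
  MAC <- p$lambda_MAC * hillf(MCP, p$K_MCP, p$n_MCP) * p$MAC0 / p$mu_MAC
  TGF <- (p$S_TGF + p$lambda_TGF * MAC) / p$mu_TGF
  AMC <- (p$S_AMC + p$lambda_AMC * hillf(TGF, p$K_TGF, p$n_TGF) * p$MC) / p$mu_AMC
  MMP <- 1e-6; TIMP <- 1e-9
  for (i in 1:500) {
    MMP <- p$lambda_MMP * MAC / (p$gamma_MMP * TIMP + p$mu_MMP)
    TIMP <- p$lambda_TIMP * MAC / (p$gamma_TIMP * MMP + p$mu_TIMP)
  }
  COL <- (p$lambda_COL * p$MC + p$lambda_COLA * AMC - p$gamma_COL * MMP) / p$mu_COL
  c(AGE = AGE, MCP = MCP, MAC = MAC, TGF = TGF, AMC = AMC,
    MMP = MMP, TIMP = TIMP, COL = COL)
}

# Closed-form first-order AGE relaxation at constant glucose:
# AGE(t) = AGE_inf + (AGE_0 - AGE_inf) exp(-mu_AGE t)
oracle_age_decay <- function(p, glucose, age0, t_days) {
  hillf <- function(X, K, n) { r <- (X / K)^n; r / (1 + r) }
  age_inf <- p$lambda_AGE * hillf(glucose, p$K_GLU, p$n_GLU) / p$mu_AGE
  age_inf + (age0 - age_inf) * exp(-p$mu_AGE * t_days)
}

# Reported healthy-state concentrations used for validation (g/mL).
reported_initial_values <- c(
  AGE = 1.5e-7, MCP = 1.783e-10, MAC = 3.37e-13, TGF = 9.91e-10,
  AMC = 6.35e-4, MMP = 1.46e-6, TIMP = 9.05e-10, COL = 2.94
)

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
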