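# Independent oracles and small fixture builders used across the suite.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Brute-force 1:1 equilibrium: bisection on the mass-action residual
# g(x) = Ka (P - x)(Q - x) - x over [0, min(P, Q)], independent of the
# closed-form quadratic used by the package.
bisect1to1 <- function(P, Q, Ka, iter = 200L) {
  lo <- 0; hi <- min(P, Q)
  g <- function(x) Ka * (P - x) * (Q - x) - x
  if (hi == 0 || Ka == 0) return(0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force competitive equilibrium: scan free protein on a 1e4-point log
# grid, then bisect inside the bracketing interval. Only the mass balance is
# used; no Newton steps, no shared code with the package solver.
bruteCompetitive <- function(P, Q, M, KaQ, KaM, gridN = 1e4, iter = 200L) {
  resid <- function(p) p * (1 + KaQ * Q / (1 + KaQ * p) +
                              KaM * M / (1 + KaM * p)) - P
  grid <- exp(seq(log(P * 1e-12), log(P), length.out = gridN))
  s <- sign(resid(grid))
  k <- which(diff(s) != 0)[1]
  if (is.na(k)) {
    p <- grid[which.min(abs(resid(grid)))]
  } else {
    lo <- grid[k]; hi <- grid[k + 1]
    for (i in seq_len(iter)) {
      mid <- (lo + hi) / 2
      if (resid(mid) < 0) lo <- mid else hi <- mid
    }
    p <- (lo + hi) / 2
  }
  c(PQ = KaQ * p * Q / (1 + KaQ * p), PM = KaM * p * M / (1 + KaM * p),
    P_free = p)
}

# Noise-free Stern-Volmer curve from the generating constant.
makeSvCurve <- function(Ksv, concs = seq(0, 3.2e-6, length.out = 9),
                        F0 = 1000, temperature = 298) {
  QuenchCurve(concs, F0, F0 / (1 + Ksv * concs), temperature = temperature)
}

# Noise-free 1:1 static quenching curve (non-fluorescent complex) at the
# standard albumin titration conditions.
makeStaticCurve <- function(Ka, P = 1.6e-6,
                            concs = seq(0, 3.2e-6, length.out = 9),
                            F0 = 1000, temperature = 298) {
  cplx <- solveEquilibrium1to1(P, concs, Ka)
  QuenchCurve(concs, F0, F0 * (P - cplx) / P, temperature = temperature)
}
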