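#' 1:1 mass-action equilibrium
#'
#' Equilibrium complex concentration for P + Q <-> PQ with association
#' constant Ka: the root in `[0, min(P, Q)]` of
#' \deqn{K_a x^2 - (K_a(P+Q) + 1)x + K_a P Q = 0,}
#' computed with the numerically stable branch
#' \eqn{x = 2 K_a P Q / (b + \sqrt{b^2 - 4 K_a^2 P Q})},
#' \eqn{b = K_a(P+Q)+1}, which avoids cancellation for small or large Ka.
#'
#' @param P numeric, total protein concentration (mol/L), >= 0.
#' @param Q numeric, total ligand concentration (mol/L), >= 0.
#' @param Ka numeric, association constant (L/mol), >= 0.
#' @return Complex concentration (mol/L); vectorized over the longest input.
#' @examples
#' solveEquilibrium1to1(1e-6, 1e-6, 1e6)   # 3.8197e-07
#' @export
solveEquilibrium1to1 <- function(P, Q, Ka) {
  if (any(P < 0) || any(Q < 0) || any(Ka < 0))
    stop("totals and Ka must be >= 0")
  n <- max(length(P), length(Q), length(Ka))
  P <- rep_len(P, n); Q <- rep_len(Q, n); Ka <- rep_len(Ka, n)
  b <- Ka * (P + Q) + 1
  disc <- b^2 - 4 * Ka^2 * P * Q
  2 * Ka * P * Q / (b + sqrt(pmax(disc, 0)))
}

#' Competitive two-ligand mass-action equilibrium
#'
#' Solves the coupled equilibria P + Q <-> PQ and P + M <-> PM (a ligand and
#' a site marker competing for the same protein) by bounded root-finding on
#' the free-protein concentration followed by Newton polishing; all three
#' mass balances are satisfied to ~1e-12 relative. The free-protein residual
#' \deqn{f(p) = p\left(1 + \frac{K_Q Q}{1 + K_Q p} +
#'       \frac{K_M M}{1 + K_M p}\right) - P}
#' is strictly increasing on `[0, P]`, so the root is unique.
#'
#' @param P,Q,M numeric(1), total protein, ligand and marker concentrations
#'   (mol/L), >= 0.
#' @param KaQ,KaM numeric(1), association constants of ligand and marker
#'   (L/mol), >= 0.
#' @param maxIter integer, Newton polishing iterations (default 50; far more
#'   than needed).
#' @return Named numeric: `PQ`, `PM`, `P_free`, `Q_free`, `M_free` (mol/L).
#' @examples
#' solveEquilibriumCompetitive(1.6e-6, 1.6e-6, 1.6e-6, 3.98e6, 2.4e5)
#' @export
solveEquilibriumCompetitive <- function(P, Q, M, KaQ, KaM, maxIter = 50L) {
  stopifnot(length(P) == 1L, length(Q) == 1L, length(M) == 1L)
  if (any(c(P, Q, M, KaQ, KaM) < 0))
    stop("totals and constants must be >= 0")
  if (P == 0)
    return(c(PQ = 0, PM = 0, P_free = 0, Q_free = Q, M_free = M))
  f <- function(p) p * (1 + KaQ * Q / (1 + KaQ * p) +
                          KaM * M / (1 + KaM * p)) - P
  p <- if (f(P) <= 0) P else
    uniroot(f, c(0, P), tol = .Machine$double.eps * max(P, 1))$root
  # Newton polish to mass-balance residuals at machine precision
  for (i in seq_len(maxIter)) {
    res <- f(p)
    if (abs(res) <= 1e-14 * P) break
    dfdp <- 1 + KaQ * Q / (1 + KaQ * p)^2 + KaM * M / (1 + KaM * p)^2
    pNew <- p - res / dfdp
    if (!is.finite(pNew) || pNew < 0) pNew <- p / 2
    if (pNew == p) break
    p <- pNew
  }
  if (abs(f(p)) > 1e-10 * P)
    stop(sprintf("competitive solver did not converge: residual %.3g (relative)",
                 abs(f(p)) / P))
  Qf <- Q / (1 + KaQ * p)
  Mf <- M / (1 + KaM * p)
  c(PQ = KaQ * p * Qf, PM = KaM * p * Mf,
    P_free = p, Q_free = Qf, M_free = Mf)
}
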