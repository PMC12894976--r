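# Independent oracles used across tests. These are deliberately naive
# (bisection, full enumeration) and share no code with the package paths
# they check.

# Bisection root of f(T) = 0.5 for the sigmoid melting curve.
bisectTm <- function(a, b, p, lo = 1e-6, hi = 1e6, tol = 1e-10) {
  f <- function(T) (1 - p) / (1 + exp(b - a / T)) + p - 0.5
  # curve is decreasing in T, so f(small T) > 0 and f(large T) < 0
  flo <- f(lo); fhi <- f(hi)
  stopifnot(flo * fhi < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (fm * flo > 0) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
permutationMannWhitneyP <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  uStat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- uStat(seq_len(n1))
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, uStat)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
enumFisherP <- function(a, b, c2, d) {
  m <- a + c2; n <- b + d; k <- a + b
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Small synthetic experiment shared by several tests.
smallSim <- function(n = 40, noise = 0, seed = 101, ...) {
  simulateTppExperiment(SimConfig(nProteins = n, noiseCv = noise,
                                  seed = seed, ...))
}

fitAllConditions <- function(sim) {
  f <- suppressWarnings(do.call(rbind, lapply(sim$quants, fitProteome)))
  rownames(f) <- NULL
  f
}

# Minimal converged MeltFit for call-level tests.
mkFit <- function(tm, r2 = 0.95, plateau = 0.1, slope = -0.1, qc = TRUE,
                  converged = TRUE) {
  b <- 20
  a <- tm * (b + log(1 - 2 * plateau))
  new("MeltFit", params = MeltParams(a, b, plateau), tm = tm,
      slope = slope, r2 = r2, converged = converged, qcPass = qc)
}
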