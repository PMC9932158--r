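# Independent oracles used across the suite.

# Dense 2-D grid oracle for the corrected-VAF estimator: log-spaced grids
# over p and q, trapezoid marginalization over q for the point estimate
# (parabolic refinement at the grid maximum), and a profile scan (max
# over the q grid) with linear interpolation at the chi-square cutoff for
# the confidence bounds.
grid_oracle <- function(k1, n1, k2, n2, level = 0.95,
                        np = 2001L, nq = 2001L) {
  pg <- c(0, 10^seq(-7, 0, length.out = np - 1L))
  qg <- c(0, 10^seq(-9, 0, length.out = nq - 1L))
  ll_ctl <- dbinom(k1, n1, qg, log = TRUE)
  rate <- outer(pg, qg, function(p, q) pmin(pmax(p + (1 - p) * q, 0), 1))
  ll <- sweep(dbinom(k2, n2, rate, log = TRUE), 2, ll_ctl, "+")
  M <- max(ll[is.finite(ll)])
  L <- exp(ll - M)

  w <- diff(qg)
  marg <- as.vector(log((L[, -1L] + L[, -ncol(L)]) %*% w / 2)) + M
  i <- which.max(marg)
  p_hat <- pg[i]
  if (i > 1L && i < length(pg)) {
    # parabola through the three points around the maximum
    x <- pg[(i - 1L):(i + 1L)]; y <- marg[(i - 1L):(i + 1L)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
            x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
            x[1]^2 * (y[2] - y[3])) / denom
    if (a < 0) p_hat <- -b / (2 * a)
  }

  prof <- apply(ll, 1L, max)
  cut <- max(prof) - qchisq(level, 1) / 2
  ok <- prof >= cut
  il <- min(which(ok)); ih <- max(which(ok))
  lo <- if (il == 1L) pg[1L] else
    approx(prof[(il - 1L):il], pg[(il - 1L):il], xout = cut)$y
  hi <- if (ih == length(pg)) pg[ih] else
    approx(prof[ih:(ih + 1L)], pg[ih:(ih + 1L)], xout = cut)$y
  c(p_hat = p_hat, ci_low = lo, ci_high = hi)
}

# Straight log-gamma binomial log-pmf (independent of dbinom).
lgamma_binom_lpmf <- function(k, n, p) {
  if (p == 0) return(if (k == 0) 0 else -Inf)
  if (p == 1) return(if (k == n) 0 else -Inf)
  lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
    k * log(p) + (n - k) * log1p(-p)
}

# Exhaustive trio genotype enumeration at Hardy-Weinberg proportions.
# Returns the joint probability of every (father, mother, child) genotype
# combination for an unrelated "child", plus the classification each
# combination receives.
trio_enumeration_unrelated <- function(maf) {
  hw <- c(AA = (1 - maf)^2, AB = 2 * maf * (1 - maf), BB = maf^2)
  combos <- expand.grid(father = names(hw), mother = names(hw),
                        child = names(hw), stringsAsFactors = FALSE)
  combos$prob <- hw[combos$father] * hw[combos$mother] * hw[combos$child]
  combos$class <- mapply(dnmrisk::classify_informative, combos$father,
                         combos$mother, combos$child, USE.NAMES = FALSE)
  combos
}
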