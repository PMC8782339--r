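# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

# Kruskal-Wallis by the direct rank formula with tie correction:
# H = [12/(N(N+1)) * sum Ri^2/ni - 3(N+1)] / [1 - sum(t^3 - t)/(N^3 - N)]
kw_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  Ri <- tapply(r, groups, sum)
  ni <- tapply(values, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# pairwise AUC by exhaustive pair enumeration
auc_oracle <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(b))
}

# EER by exhaustive threshold sweep on an independent grid construction:
# evaluate FRR/FAR at every data value and midpoint, then interpolate
# linearly between the bracketing operating points
eer_oracle <- function(ss, ds) {
  pts <- sort(unique(c(ss, ds)))
  cand <- sort(unique(c(pts, head(pts, -1) + diff(pts) / 2, max(pts) + 1)))
  frr <- vapply(cand, function(t) mean(ss < t), numeric(1))
  far <- vapply(cand, function(t) mean(ds >= t), numeric(1))
  d <- frr - far
  i <- which(d >= 0)[1]
  if (d[i] == 0 || i == 1) return(frr[i])
  a <- (far[i - 1] - frr[i - 1]) /
    ((frr[i] - frr[i - 1]) - (far[i] - far[i - 1]))
  frr[i - 1] + a * (frr[i] - frr[i - 1])
}

# two-level LR by numerical quadrature: within-source normal around theta,
# theta ~ kernel mixture over background means (bandwidth h)
lr_quadrature_oracle <- function(x, y, mu, s2, h) {
  A <- s2 / length(x); B <- s2 / length(y)
  xb <- mean(x); yb <- mean(y)
  # integrate kernel component by component, each over a window centred on
  # the (narrow) peak of its Gaussian product, so quadrature never misses mass
  comp <- function(f, centre_prec) {
    vapply(mu, function(m_i) {
      prec <- centre_prec$prec(m_i)
      c_i <- centre_prec$centre(m_i) / prec
      s_i <- 1 / sqrt(prec)
      stats::integrate(function(th) f(th, m_i), c_i - 25 * s_i, c_i + 25 * s_i,
                       rel.tol = 1e-13, subdivisions = 2000L)$value
    }, numeric(1))
  }
  num <- mean(comp(
    function(th, m_i) dnorm(xb, th, sqrt(A)) * dnorm(yb, th, sqrt(B)) *
      dnorm(th, m_i, h),
    list(prec = function(m_i) 1 / A + 1 / B + 1 / h^2,
         centre = function(m_i) xb / A + yb / B + m_i / h^2)))
  d1 <- mean(comp(
    function(th, m_i) dnorm(xb, th, sqrt(A)) * dnorm(th, m_i, h),
    list(prec = function(m_i) 1 / A + 1 / h^2,
         centre = function(m_i) xb / A + m_i / h^2)))
  d2 <- mean(comp(
    function(th, m_i) dnorm(yb, th, sqrt(B)) * dnorm(th, m_i, h),
    list(prec = function(m_i) 1 / B + 1 / h^2,
         centre = function(m_i) yb / B + m_i / h^2)))
  log10(num / (d1 * d2))
}

# direct Eq-style Cllr evaluation from plain LRs
cllr_direct <- function(lr_ss, lr_ds) {
  0.5 * (mean(log2(1 + 1 / lr_ss)) + mean(log2(1 + lr_ds)))
}
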