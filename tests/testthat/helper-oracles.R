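# Independent brute-force oracles used to check the package implementations.
# These are deliberately written as plain scalar loops / direct enumerations,
# sharing no code with the package internals.

# Direct per-period summation of the abundance-weighted temporal index.
oracle_ri_temporal <- function(A, B, A_total, B_total) {
  sH <- 0
  sC <- 0
  for (i in seq_along(A)) {
    if (A[i] + B[i] == 0) next
    sH <- sH + (A[i] / A_total) * (B[i] / (A[i] + B[i])) *
      (B_total / (A_total + B_total))
    sC <- sC + (A[i] / A_total) * (A[i] / (A[i] + B[i])) *
      (A_total / (A_total + B_total))
  }
  1 - 2 * sH / (sH + sC)
}

# Two-sided Fisher exact p for a 2x2 table (rows = groups of size n1, n2;
# a, c = successes) by hypergeometric enumeration: sum the probabilities of
# all tables with the observed margins whose probability does not exceed the
# observed table's.
oracle_fisher_p <- function(a, n1, c, n2) {
  k <- a + c
  lo <- max(0L, k - n2)
  hi <- min(n1, k)
  support <- lo:hi
  probs <- dhyper(support, n1, n2, k)
  p_obs <- dhyper(a, n1, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form Bray-Curtis dissimilarity.
oracle_bray <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# Brute-force dilation: pixel (i,j) is set iff any set source pixel lies
# within r pixels under the Chebyshev (square) or Euclidean (disk) metric.
oracle_dilate <- function(m, r, element = "square") {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  src <- which(m, arr.ind = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (s in seq_len(nrow(src))) {
      dy <- src[s, 1] - i; dx <- src[s, 2] - j
      hit <- if (element == "square") max(abs(dy), abs(dx)) <= r
             else dy * dy + dx * dx <= r * r + 1e-9
      if (hit) { out[i, j] <- TRUE; break }
    }
  }
  out
}

# Brute-force pixel-by-pixel overlap classification.
oracle_classify <- function(f, o, r_pixels, element = "square") {
  fd <- oracle_dilate(f, r_pixels, element)
  od <- oracle_dilate(o, r_pixels, element)
  shared <- (f & o) | (fd & o) | (f & od)
  list(shared = sum(shared),
       focal_only = sum(f & !shared),
       other_only = sum(o & !shared),
       shared_from_model = sum(f & o))
}

# Exhaustive scan for the equal-training-sensitivity/specificity threshold.
oracle_etss <- function(presence, background) {
  cand <- sort(unique(c(presence, background)))
  best_t <- NA
  best_gap <- Inf
  for (t in cand) {
    sens <- mean(presence >= t)
    spec <- mean(background < t)
    gap <- abs(sens - spec)
    if (gap < best_gap - 1e-15) { best_gap <- gap; best_t <- t }
  }
  best_t
}

# Exhaustive-permutation rank-sum: returns the observed rank-sum statistic
# (sum of midranks of group x, shifted to the Mann-Whitney U scale) and the
# two-sided permutation p over all choose(n, nx) group assignments.
oracle_rank_sum <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(u = u_obs, p = p)
}

# Expected Bray-Curtis between independent multinomial draws with fixed
# proportion vectors p, q and totals n, m: sum of E[min(X_k, Y_k)] computed
# from the exact binomial marginals.
oracle_expected_bray <- function(p, q, n, m) {
  emin <- 0
  for (k in seq_along(p)) {
    px <- dbinom(0:n, n, p[k])
    py <- dbinom(0:m, m, q[k])
    # E[min] = sum_v P(min > v) over v = 0.. (min > v iff X > v and Y > v)
    sx <- rev(cumsum(rev(px)))  # sx[v+1] = P(X >= v)
    sy <- rev(cumsum(rev(py)))
    vmax <- min(n, m)
    pm <- 0
    for (v in 1:vmax) pm <- pm + sx[v + 1] * sy[v + 1]
    emin <- emin + pm
  }
  1 - 2 * emin / (n + m)
}

# Closed-form RI4A of the crossing generator's parameters for each stage.
oracle_generating_ri <- function(cfg) {
  cr <- cfg$crossing
  c(adhesion = 1 - 2 * cr$adhesion_mean[["hybrid"]] /
      (cr$adhesion_mean[["hybrid"]] + cr$adhesion_mean[["parental"]]),
    germination = 1 - 2 * cr$germination_p[["hybrid"]] /
      (cr$germination_p[["hybrid"]] + cr$germination_p[["parental"]]),
    seed_set = 1 - 2 * cr$seed_rate[["hybrid"]] /
      (cr$seed_rate[["hybrid"]] + cr$seed_rate[["parental"]]))
}

# Random small flowering series for property tests.
random_series <- function() {
  n <- sample(2:8, 1)
  A_total <- sample(3:40, 1)
  B_total <- sample(3:40, 1)
  A <- sample(0:A_total, n, replace = TRUE)
  B <- sample(0:B_total, n, replace = TRUE)
  if (all(A == 0)) A[sample(n, 1)] <- 1
  list(A = A, B = B, A_total = A_total, B_total = B_total)
}
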