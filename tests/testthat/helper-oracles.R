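# Independent arithmetic oracle for the raw W statistic: scalar cell-by-cell
# computation straight from the proportion formulation
#   z_i = log[(p1/(1-p1)) / (p0/(1-p0))] / SE_i
# with the 0.5 continuity correction on any collapse containing a zero.
oracle_w_raw <- function(case_counts, control_counts) {
  k <- length(case_counts)
  n1 <- sum(case_counts)
  n0 <- sum(control_counts)
  S <- 0
  for (i in seq_len(k)) {
    a <- case_counts[i]
    b <- n1 - a
    cc <- control_counts[i]
    d <- n0 - cc
    if (a == 0 || b == 0 || cc == 0 || d == 0) {
      a <- a + 0.5
      b <- b + 0.5
      cc <- cc + 0.5
      d <- d + 0.5
    }
    p1 <- a / (a + b)
    p0 <- cc / (cc + d)
    lor <- log((p1 / (1 - p1)) / (p0 / (1 - p0)))
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    S <- S + (lor / se)^2
  }
  S
}

# random valid contingency tables with n1, n0 <= nmax and 2 <= k <= 6;
# every category non-empty in at least one group
random_table <- function(kk, nmax = 30L) {
  repeat {
    n1 <- sample(kk:nmax, 1L)
    n0 <- sample(kk:nmax, 1L)
    case_counts <- as.vector(stats::rmultinom(1L, n1, prob = runif(kk, 0.2, 1)))
    control_counts <- as.vector(stats::rmultinom(1L, n0, prob = runif(kk, 0.2, 1)))
    if (all(case_counts + control_counts > 0L)) {
      return(list(case_counts = case_counts, control_counts = control_counts))
    }
  }
}

# Independent logistic maximum-likelihood fit: hand-coded Newton (Fisher
# scoring) on the log-likelihood, iterated to machine-level convergence.
oracle_logit_fit <- function(X, y, max_iter = 60L) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-14)
    step <- solve(crossprod(X, w * X), crossprod(X, y - p))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < 1e-13) break
  }
  eta <- as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  list(beta = beta, deviance = -2 * sum(y * log(p) + (1 - y) * log1p(-p)))
}

# 1-df interaction LRT p-value from the independent fits
oracle_lr_interaction_p <- function(g, m, y) {
  Xf <- cbind(1, g, m, g * m)
  Xr <- Xf[, 1:3]
  lrt <- oracle_logit_fit(Xr, y)$deviance - oracle_logit_fit(Xf, y)$deviance
  stats::pchisq(max(0, lrt), df = 1, lower.tail = FALSE)
}
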