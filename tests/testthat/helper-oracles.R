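# Independent oracles used to cross-check the package implementations.
# These deliberately use different code paths (formula-interface lm,
# bitmask enumeration, explicit pair counting) than the package.

# exhaustive minimum-t break search via formula-interface lm()
naive_za <- function(y, days = seq_along(y), trim = 0.15) {
  n <- length(y)
  k <- ceiling(trim * n)
  dat <- data.frame(dy = diff(y), ylag = y[-n], tt = 2:n)
  best_t <- Inf
  best_b <- NA
  for (b in (1 + k):(n - k)) {
    dat$du <- as.numeric(dat$tt >= b)
    fit <- lm(dy ~ du + tt + ylag, data = dat)
    cf <- suppressWarnings(summary(fit)$coefficients)
    if (!"ylag" %in% rownames(cf)) next
    sig <- suppressWarnings(summary(fit)$sigma)
    if (!is.finite(sig) || sig^2 < 1e-12) next
    tst <- cf["ylag", "t value"]
    if (is.finite(tst) && tst < best_t) {
      best_t <- tst
      best_b <- b
    }
  }
  list(tp_day = days[best_b], t_min = best_t)
}

# exact two-sided Mann-Whitney p by bitmask enumeration (n1 + n2 <= ~12)
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  centre <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cnt <- 0L
  tot <- 0L
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    if (sum(bits) != n1) next
    u <- sum(r[bits == 1]) - n1 * (n1 + 1) / 2
    tot <- tot + 1L
    if (abs(u - centre) >= abs(u_obs - centre) - 1e-9) cnt <- cnt + 1L
  }
  cnt / tot
}

# Kendall tau-b by explicit O(n^2) concordant/discordant pair counting,
# with the no-ties normal-approximation p-value
kendall_pairs <- function(t, x) {
  n <- length(x)
  conc <- 0
  disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- sign(t[j] - t[i]) * sign(x[j] - x[i])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  S <- conc - disc
  n0 <- n * (n - 1) / 2
  tiet <- table(t)
  tiex <- table(x)
  n1 <- sum(tiet * (tiet - 1) / 2)
  n2 <- sum(tiex * (tiex - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  z <- S / sqrt(n * (n - 1) * (2 * n + 5) / 18)
  list(tau = tau, p_noties = 2 * pnorm(-abs(z)))
}

# a Poisson step series over the standard 29-day window
step_series <- function(break_day = 39, mu1 = 5, mu2 = 15,
                        days = 16:44) {
  rpois(length(days), ifelse(days >= break_day, mu2, mu1))
}
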