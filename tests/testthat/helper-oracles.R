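# Independent oracles used to check the package's statistical primitives.
# Each deliberately takes a different computational route from the
# implementation it verifies.

# closed-form simple OLS (textbook moment formulas)
oracle_ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  Sxx <- sum((x - mx)^2)
  Sxy <- sum((x - mx) * (y - my))
  beta <- Sxy / Sxx
  a <- my - beta * mx
  res <- y - a - beta * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / Sxx)
  tt <- beta / se
  list(beta = beta, se = se, t = tt,
       p = 2 * stats::pt(-abs(tt), n - 2))
}

# brute-force Benjamini-Hochberg: q_i = min over j with p_(j) >= p_i of
# m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  cand <- m * ps / seq_len(m)
  vapply(p, function(pi) min(1, min(cand[ps >= pi])), numeric(1))
}

# Levene-Haldane exact HWE p by pmf recurrence (no gamma functions):
# P(h + 2) / P(h) = 4 nAA(h) naa(h) / ((h + 1)(h + 2))
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  m <- 2 * min(n_AA, n_aa) + n_Aa
  if (m == 0) return(1)
  hs <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  w <- numeric(length(hs))
  w[1] <- 1
  if (length(hs) > 1) for (i in 2:length(hs)) {
    h <- hs[i - 1]
    naa_h <- (m - h) / 2
    nAA_h <- n - naa_h - h
    w[i] <- w[i - 1] * 4 * nAA_h * naa_h / ((h + 1) * (h + 2))
  }
  probs <- w / sum(w)
  p_obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# one-sided Welch t-test computed from the textbook formulas
oracle_welch_greater <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tt, df = df, p = stats::pt(tt, df, lower.tail = FALSE))
}

# build an association table directly (one record per (x, y) pair)
make_assoc <- function(x_id, y_id, beta, p, n = 79, q = NA_real_) {
  data.frame(x_id = x_id, y_id = y_id, beta = beta,
             se = abs(beta) / 2, t = sign(beta) * 2, p = p, n = n, q = q,
             stringsAsFactors = FALSE)
}

# tiny cohort used across tests; ... overrides the defaults below
small_cohort <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_samples = 79, n_snps = 300, n_mirnas = 30, n_mrnas = 100,
         n_planted_eqtls = 8, n_planted_regulations = 20, n_catalog = 20,
         seed = seed),
    list(...))
  simulate_cohort(do.call(sim_config, args))
}
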