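# Independent brute-force oracles and small fixture builders. The oracles are
# literal loop implementations of the defining formulas, kept free of any
# package internals so they can certify the fast implementations.

# direct-loop statistical moments (population convention)
oracle_moments <- function(x) {
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v / n
  s2 <- 0
  for (v in x) s2 <- s2 + (v - mu)^2 / n
  s <- sqrt(s2)
  sk <- 0; ku <- 0
  for (v in x) {
    sk <- sk + ((v - mu) / s)^3 / n
    ku <- ku + ((v - mu) / s)^4 / n
  }
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  c(skewness = sk, kurtosis = ku, mean = mu, median = med,
    min = min(x), max = max(x))
}

# direct-loop Pearson correlation
oracle_correlation <- function(x, y) {
  T_ <- length(x)
  mx <- sum(x) / T_; my <- sum(y) / T_
  num <- 0; dx <- 0; dy <- 0
  for (t in seq_len(T_)) {
    num <- num + (x[t] - mx) * (y[t] - my)
    dx <- dx + (x[t] - mx)^2
    dy <- dy + (y[t] - my)^2
  }
  num / sqrt(dx * dy)
}

# pair-counting Mann-Whitney U (#x>y plus half ties) and Cliff's delta
oracle_pairs <- function(x, y) {
  wins <- 0; losses <- 0; ties <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) wins <- wins + 1
    else if (xi < yj) losses <- losses + 1
    else ties <- ties + 1
  }
  list(u = wins + ties / 2,
       delta = (wins - losses) / (length(x) * length(y)))
}

# two-sided Fisher exact p for a 2x2 table by full hypergeometric enumeration
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  prob <- function(a) {
    # table with [1,1] = a given fixed margins
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(n, c1))
  }
  p_obs <- prob(tab[1, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(support, prob, numeric(1))[
    vapply(support, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# wrap a plain symmetric matrix as a labelled connectivity input
new_conn_for_test <- function(m) {
  dimnames(m) <- list(paste0("n", seq_len(nrow(m))),
                      paste0("n", seq_len(nrow(m))))
  m
}

# quick multi-channel segment fixture: band-limited-ish random data
rand_segment <- function(n_ch = 21, n = 500, fs = 100, seed = 1,
                         band = NULL) {
  set.seed(seed)
  rec <- eeg_recording(matrix(rnorm(n_ch * n), n_ch),
                       fs = fs,
                       channel_names = if (n_ch == 21) montage_1020()
                                       else paste0("ch", seq_len(n_ch)))
  seg <- cut_segment(rec, n / fs)
  attr(seg, "band") <- band
  seg
}

# tiny synthetic cohort for pipeline tests (kept small: unit tests only)
tiny_cohort <- function(n_sf = 3, n_nsf = 3, fs = 100, seed = 1,
                        effect_band = c(30, 32), amp_nsf = 80,
                        rate_nsf = 8, amp_sf = 30, rate_sf = 1) {
  generate_cohort(synthetic_cohort_spec(
    n_sf = n_sf, n_nsf = n_nsf, fs = fs, duration_s = 320,
    effect_band = effect_band,
    event_rate_sf = rate_sf, event_rate_nsf = rate_nsf,
    event_amp_sf = amp_sf, event_amp_nsf = amp_nsf, seed = seed))
}
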