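# Independent brute-force oracles, deliberately naive implementations.

# Exhaustive O(n*k) window scan for admissible local minima with the same
# tie semantics: a candidate needs its full +/-k window with no strictly
# smaller value; tied candidates within k of an earlier candidate are
# suppressed.
brute_local_minima <- function(values, k) {
  n <- length(values)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (i - k < 1 || i + k > n) next
    ok <- TRUE
    for (j in (i - k):(i + k)) {
      if (values[j] < values[i]) ok <- FALSE
    }
    if (ok) cand <- c(cand, i)
  }
  out <- integer(0)
  for (i in cand) {
    suppressed <- FALSE
    for (j in cand[cand < i]) {
      if (i - j <= k && values[j] == values[i]) suppressed <- TRUE
    }
    if (!suppressed) out <- c(out, i)
  }
  out
}

# naive two-point moving average
brute_smooth2 <- function(values) {
  out <- numeric(length(values) - 1)
  for (i in seq_along(out)) out[i] <- (values[i] + values[i + 1]) / 2
  out
}

# closed-form OLS slope
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# naive consecutive-pair shortening rate
brute_diffquot <- function(lengths, pds) {
  r <- numeric(0)
  for (i in 2:length(lengths)) {
    r <- c(r, (lengths[i - 1] - lengths[i]) / (pds[i] - pds[i - 1]))
  }
  mean(r)
}

# one simulated clone taken through growth + potential
sim_clone_potential <- function(cfg, seed, clone_id = "c1",
                                condition = "EV") {
  traj <- simulate_telomere_trajectory(cfg, seed = seed, clone_id = clone_id)
  growth <- simulate_daily_culture(traj, cfg, seed = seed + 1000000L,
                                   condition = condition)
  replicative_potential(growth)
}

# constant-length trajectory fixture
flat_trajectory <- function(length_bp, n_pd = 400, clone_id = "flat") {
  tibble::tibble(clone_id = clone_id, pd = as.numeric(0:n_pd),
                 length_bp = length_bp, event = "none")
}
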