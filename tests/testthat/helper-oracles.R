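# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package implementation.

# first |x| >= h per armed period; re-arm `rearm_n` samples after each onset
oracle_st <- function(x, h, rearm_n) {
  out <- integer(0)
  armed_at <- 1
  for (i in seq_along(x)) {
    if (i >= armed_at && abs(x[i]) >= h) {
      out <- c(out, i)
      armed_at <- i + rearm_n
    }
  }
  out
}

# exhaustive dwell check: first index >= from where env stays < h_off for
# dwell_n consecutive samples
oracle_dwell <- function(env, h_off, dwell_n, from) {
  n <- length(env)
  for (s in from:n) {
    if (s + dwell_n - 1 > n) return(NA_integer_)
    if (all(env[s:(s + dwell_n - 1)] < h_off)) return(s)
  }
  NA_integer_
}

oracle_vaf <- function(E, Ehat) {
  num <- 0; den <- 0
  for (i in seq_along(E)) {
    num <- num + (E[i] - Ehat[i])^2
    den <- den + E[i]^2
  }
  1 - num / den
}

oracle_fwhm <- function(p) {
  q <- p - min(p)
  if (max(q) < 1e-12) return(NA_real_)
  half <- max(q) / 2
  cnt <- 0
  for (v in q) if (v >= half) cnt <- cnt + 1
  100 * cnt / length(p)
}

oracle_coa <- function(p) {
  g <- length(p)
  S <- 0; C <- 0
  for (t in seq_len(g)) {
    th <- 2 * pi * (t - 1) / g
    S <- S + p[t] * sin(th)
    C <- C + p[t] * cos(th)
  }
  a <- atan2(S, C)
  if (a < 0) a <- a + 2 * pi
  100 * a / (2 * pi)
}

oracle_shares <- function(muscles, levels) {
  out <- numeric(length(levels))
  names(out) <- levels
  for (m in muscles) out[m] <- out[m] + 1
  100 * out / length(muscles)
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  ev <- sum(r) / 2
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}

# best assignment cosine similarity between planted and fitted synergy
# vectors over all permutations (greedy-free exhaustive search)
matched_cosine <- function(W0, W) {
  k <- ncol(W0)
  cosm <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  S <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cosm(W0[, i], W[, j])))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf; best_p <- NULL
  for (p in perms(seq_len(k))) {
    s <- min(S[cbind(seq_len(k), p)])
    if (s > best) { best <- s; best_p <- p }
  }
  list(min_cosine = best, perm = best_p,
       cosines = S[cbind(seq_len(k), best_p)])
}

# tiny raw-EMG burst recording: baseline noise plus rectangular bursts
make_burst_recording <- function(n = 2000, fs = 1000, burst_at = c(500, 1500),
                                 burst_len = 200, amp = 1, noise_sd = 0.01,
                                 muscle = "R-Sol", seed = 1) {
  set.seed(seed)
  x <- rnorm(n, 0, noise_sd)
  for (b in burst_at) {
    idx <- b:min(b + burst_len - 1, n)
    x[idx] <- x[idx] + amp * sin(2 * pi * 150 * (idx / fs))
  }
  emg_recording(matrix(x, ncol = 1), fs = fs, channel_map = muscle)
}
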