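# Independent brute-force oracles for the correlogram estimators and the
# burst classifier, plus a plain-R reference integrator for the
# deterministic single-cell dynamics.

# O(N1*N2) pair-counting cross-correlogram (linear lags), same
# normalisation as ccg(): coincidences/(N1*dt) - m2, in Hz.
oracle_ccg <- function(t1, t2, duration_ms, max_lag_ms, dt_ms) {
  L <- as.integer(round(max_lag_ms / dt_ms))
  b1 <- floor(t1 / dt_ms)
  b2 <- floor(t2 / dt_ms)
  counts <- numeric(2 * L + 1)
  for (a in b1) {
    for (b in b2) {
      lag <- b - a
      if (abs(lag) <= L) counts[lag + L + 1] <- counts[lag + L + 1] + 1
    }
  }
  counts / (length(t1) * dt_ms / 1000) - length(t2) / (duration_ms / 1000)
}

# exhaustive cycle-pair enumeration of the within-cycle (raw) and
# cross-cycle (shuffle) correlograms with circular lags, mirroring the
# per-cycle normalisation; returns values on lags ordered as the package
# does (ascending, -B/2+1 .. B/2).
oracle_cycle <- function(X1, X2, dt_ms) {
  B <- nrow(X1); M <- ncol(X1)
  dt_s <- dt_ms / 1000
  P_s <- B * dt_s
  N1 <- colSums(X1)
  m2 <- colSums(X2) / P_s
  valid <- which(N1 > 0)
  one <- function(k, j) {
    v <- numeric(B)
    for (tau in 0:(B - 1)) {
      s <- 0
      for (b in 0:(B - 1)) {
        s <- s + X1[b + 1, k] * X2[(b + tau) %% B + 1, j]
      }
      v[tau + 1] <- s / (N1[k] * dt_s) - m2[j]
    }
    v
  }
  raw <- rowMeans(sapply(valid, function(k) one(k, k)))
  shuf <- numeric(B)
  np <- 0
  for (k in valid) {
    for (j in seq_len(M)[-k]) {
      shuf <- shuf + one(k, j)
      np <- np + 1
    }
  }
  shuf <- shuf / np
  lag_idx <- 0:(B - 1)
  lag <- ifelse(lag_idx > B / 2, lag_idx - B, lag_idx)
  ord <- order(lag)
  list(lag_ms = lag[ord] * dt_ms, raw = raw[ord], shuffle = shuf[ord])
}

# sequential re-implementation of the exclusive burst-assignment rule,
# written directly from its verbal statement.
oracle_bursts <- function(times) {
  n <- length(times)
  assigned <- rep(FALSE, n)
  onsets <- numeric(0)
  sizes <- integer(0)
  for (i in seq_len(n)) {
    quad <- (i - 3):i
    if (i >= 4 && !any(assigned[quad]) && times[i] - times[i - 3] <= 45) {
      assigned[quad] <- TRUE
      onsets <- c(onsets, times[i - 3])
      sizes <- c(sizes, 4L)
    } else if (i >= 5) {
      pair <- c(i - 4, i - 3)
      if (!any(assigned[pair]) && diff(times[pair]) <= 15) {
        assigned[pair] <- TRUE
        onsets <- c(onsets, times[i - 4])
        sizes <- c(sizes, 2L)
      }
    }
  }
  list(onset = onsets, size = sizes, assigned = assigned)
}

# deterministic plain-R integrator for one SP cell (no noise, no
# feedback), mirroring the update order of the compiled core.
r_reference_sp <- function(sp, I, duration_ms, dt = 0.05, burn_ms = 100,
                           kappa = 0, f = 4) {
  n_steps <- round((duration_ms + burn_ms) / dt)
  burn_steps <- round(burn_ms / dt)
  ref_steps <- ceiling(sp$r_s / dt)
  V <- sp$V_rest; ref <- 0L
  t_n <- -1e18; nspk <- 0L; q <- 1; r_d <- sp$D
  out <- numeric(0)
  for (k in seq_len(n_steps) - 1) {
    tn <- (k - burn_steps) * dt + dt
    if (ref > 0) {
      ref <- ref - 1L
      V <- sp$V_rest
      r_d <- r_d + dt * (sp$D - r_d) / sp$E
      next
    }
    ts <- tn - t_n - sp$r_s
    dap <- if (ts > 0) {
      sp$gamma * sp$alpha * q * (ts / sp$tau^2) * exp(-ts / sp$tau)
    } else 0
    stim <- max(kappa * sin(2 * pi * f * tn / 1000), 0)
    V <- V + dt * (-sp$g_leak * (V - sp$E_leak) + I + stim + dap) / sp$C
    if (V >= sp$V_threshold) {
      V <- sp$V_rest
      ref <- ref_steps
      isi <- tn - t_n
      success <- nspk == 0L || isi > r_d
      q <- if (success) 1 else sp$A * q
      r_d <- sp$B * r_d
      t_n <- tn; nspk <- nspk + 1L
      if (tn >= 0 && tn < duration_ms) out <- c(out, tn)
    }
    r_d <- r_d + dt * (sp$D - r_d) / sp$E
  }
  out
}

# random spike train helper
random_train <- function(n, duration_ms, min_gap = 1) {
  sort(runif(n, 0, duration_ms - 1e-6))
}
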