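# shared fixtures: small parameter sets and hand-built states

# short-horizon defaults for fast simulator tests
fast_params <- function(...) {
  gcr_params(schedule = list(t_end = 6), ...)
}

# a gc_state built directly from vectors (bypasses the schedule)
make_state <- function(sigma, cb, cc = 0 * cb, mem = 0 * cb, pla = 0 * cb,
                       n_mut = 0L * seq_along(sigma), time = 10, step = 40L) {
  n <- length(sigma)
  state <- list(
    time = time, step = step, next_id = n + 1L,
    id = seq_len(n), parent_id = rep(NA_integer_, n),
    sigma = as.numeric(sigma), n_mut = as.integer(n_mut),
    birth_step = integer(n),
    cb = as.numeric(cb), cc = as.numeric(cc),
    mem = as.numeric(mem), pla = as.numeric(pla),
    removed_mem = 0, removed_pla = 0
  )
  class(state) <- "gc_state"
  state
}

# brute-force expansion threshold: scan every candidate count
oracle_threshold <- function(counts, p = 1) {
  for (c in seq_len(max(counts) + 1L)) {
    if (sum(counts == c) < p) return(c)
  }
}

# independent linear-ODE oracle for one subclone with frozen signals and
# density factor pinned at 1 (matrix exponential via Matrix::expm)
oracle_linear_advance <- function(y0, sigma, s_d, s_a, rates, dt) {
  m <- matrix(0, 4, 4)
  m[1, 1] <- rates$rho_cb - (1 - s_d) * rates$eta_cb_cc
  m[1, 2] <- rates$eta_cc_cb
  m[2, 1] <- (1 - s_d) * rates$eta_cb_cc
  m[2, 2] <- -rates$eta_cc_cb - (1 - s_a) * rates$mu_cc - rates$eta_cc_m -
    rates$eta_cc_p * sigma
  m[3, 2] <- rates$eta_cc_m
  m[3, 3] <- -rates$mu_m
  m[4, 2] <- rates$eta_cc_p * sigma
  m[4, 4] <- -rates$mu_p
  as.numeric(Matrix::expm(m * dt) %*% y0)
}
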