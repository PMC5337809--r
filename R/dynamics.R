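# Deterministic core: relative-affinity scaling, Hill-type survival signals,
# density-limited proliferation, and the four coupled ODEs per subclone
# advanced over one 6-h division interval with an adaptive Dormand-Prince
# RK45 integrator.

#' Relative affinities of the living population
#'
#' Absolute affinities are scaled by the population maximum, so relative
#' affinities lie in (0, 1] with the current best binder exactly at 1. The
#' emergence of a higher-affinity subclone therefore pushes every other
#' subclone to a lower relative affinity and hence a weaker survival signal.
#'
#' @param sigma numeric vector of absolute affinities of living subclones.
#' @return Vector of relative affinities in (0, 1].
#' @export
relative_affinities <- function(sigma) {
  if (length(sigma) == 0) stop("no living subclones")
  sigma / max(sigma)
}

#' Sigmoidal survival signal
#'
#' `S(x) = x^n / (k^n + x^n)`: converts a relative affinity into a signal
#' strength in \[0, 1) with half-max at `x = k`. The differentiation and
#' apoptosis signals use separate (k, n) pairs; both rates are multiplied by
#' `(1 - S)`, so a strong signal slows CB->CC differentiation (longer
#' dark-zone residence) and protects CCs from apoptosis.
#'
#' @param sigma_rel relative affinity in \[0, 1\] (vectorized).
#' @param k half-max point (> 0).
#' @param n Hill exponent (>= 1).
#' @return Signal value(s) in \[0, 1).
#' @export
survival_signal <- function(sigma_rel, k, n) {
  x <- sigma_rel^n
  x / (k^n + x)
}

#' Density-dependent proliferation factor
#'
#' `A^h / (CB_total^h + A^h) = 1 / (1 + (CB_total/A)^h)`: non-specific
#' resource competition that throttles centroblast proliferation as the
#' total CB count approaches the carrying capacity `A`. Evaluated in log
#' space (`plogis(-h * log(CB_total / A))`) so that the default `h = 20`
#' cannot overflow.
#'
#' @param cb_total total centroblast count (>= 0, vectorized).
#' @param capacity carrying capacity A (cells).
#' @param hill_h capacity Hill exponent h.
#' @return Factor in (0, 1\]; equals 0.5 at `cb_total = capacity`.
#' @export
density_factor <- function(cb_total, capacity, hill_h) {
  out <- numeric(length(cb_total))
  pos <- cb_total > 0
  out[!pos] <- 1
  out[pos] <- stats::plogis(-hill_h * (log(cb_total[pos]) - log(capacity)))
  out
}

#' Right-hand side of the per-subclone ODE system
#'
#' For each subclone i (with fixed survival signals S_d,i and S_a,i over the
#' interval):
#' \deqn{dCB_i/dt = \rho_{CB} f(CB_{tot}) CB_i + \eta_{CC\to CB} CC_i -
#'   (1 - S_{d,i}) \eta_{CB\to CC} CB_i}
#' \deqn{dCC_i/dt = (1 - S_{d,i}) \eta_{CB\to CC} CB_i - \eta_{CC\to CB} CC_i
#'   - (1 - S_{a,i}) \mu_{CC} CC_i - \eta_{CC\to M} CC_i -
#'   \eta_{CC\to P} \sigma_i CC_i}
#' \deqn{dM_i/dt = \eta_{CC\to M} CC_i - \mu_M M_i}
#' \deqn{dP_i/dt = \eta_{CC\to P} \sigma_i CC_i - \mu_P P_i}
#' where `f` is [density_factor()] of the summed CB counts and plasma-cell
#' differentiation scales with the absolute affinity `sigma_i`, keeping
#' plasma output low early in the reaction.
#'
#' @param cb,cc,mem,pla compartment count vectors (one entry per subclone).
#' @param sigma absolute affinities (uM).
#' @param s_d,s_a per-subclone differentiation and apoptosis signals.
#' @param rates rate parameter group (see [gcr_params()]).
#' @return List of derivative vectors `dcb`, `dcc`, `dmem`, `dpla`.
#' @export
gc_derivatives <- function(cb, cc, mem, pla, sigma, s_d, s_a, rates) {
  dens <- density_factor(sum(cb), rates$capacity, rates$hill_h)
  diff_cb <- (1 - s_d) * rates$eta_cb_cc * cb
  plasma_in <- rates$eta_cc_p * sigma * cc
  list(
    dcb = rates$rho_cb * dens * cb + rates$eta_cc_cb * cc - diff_cb,
    dcc = diff_cb - rates$eta_cc_cb * cc - (1 - s_a) * rates$mu_cc * cc -
      rates$eta_cc_m * cc - plasma_in,
    dmem = rates$eta_cc_m * cc - rates$mu_m * mem,
    dpla = plasma_in - rates$mu_p * pla
  )
}

# Dormand-Prince RK45 coefficients
DP_A <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
DP_B5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
DP_B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
           187 / 2100, 1 / 40)

# adaptive RK45 on a flat state vector; fun(y) returns dy. The contract is
# the error tolerance, not the algorithm: local error per step is controlled
# to atol + rtol * |y|.
rk45 <- function(y, fun, t_len, rtol, atol, max_steps = 100000L) {
  t <- 0
  h <- t_len / 20
  n_acc <- 0L
  k <- vector("list", 7L)
  for (iter in seq_len(max_steps)) {
    if (t >= t_len) return(list(y = y, steps = n_acc))
    h <- min(h, t_len - t)
    k[[1]] <- fun(y)
    for (s in 1:6) {
      a <- DP_A[[s]]
      incr <- a[1] * k[[1]]
      if (s > 1) for (j in 2:s) incr <- incr + a[j] * k[[j]]
      k[[s + 1]] <- fun(y + h * incr)
    }
    y5 <- y
    y4 <- y
    for (s in 1:7) {
      if (DP_B5[s] != 0) y5 <- y5 + h * DP_B5[s] * k[[s]]
      y4 <- y4 + h * DP_B4[s] * k[[s]]
    }
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (is.na(err) || !is.finite(err)) {
      h <- h / 2
      next
    }
    if (err <= 1) {
      t <- t + h
      # clip integrator undershoot: compartments are counts and stay >= 0
      y <- pmax(y5, 0)
      n_acc <- n_acc + 1L
    }
    fac <- if (err == 0) 5 else 0.9 * err^(-0.2)
    h <- h * min(5, max(0.2, fac))
  }
  stop("ODE integrator failed to converge within ", max_steps,
       " steps (state length ", length(y), ")")
}

#' Advance the population over one division interval
#'
#' Integrates the per-subclone ODE system over `dt` days with survival
#' signals held fixed at their interval-start values (the operator-splitting
#' scheme: affinities, and hence signals, change only at the discrete SHM
#' events between intervals). During the monoclonal-expansion clamp
#' (`state$time < clamp_days`) both signals are replaced by `clamp_value`
#' for every subclone.
#'
#' @param state a `gc_state` object.
#' @param dt interval length in days (one CB division = 0.25).
#' @param params a `gcr_params` object.
#' @return The state advanced by `dt`, with nonnegative compartments.
#' @export
integrate_interval <- function(state, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  n <- length(state$cb)
  if (n == 0L) {
    state$time <- state$time + dt
    return(state)
  }
  sig <- interval_signals(state, params)
  rates <- params$rates
  sigma <- state$sigma
  idx <- list(cb = 1:n, cc = n + 1:n, mem = 2 * n + 1:n, pla = 3 * n + 1:n,
              births = 4 * n + 1:n)
  # the 5th block accumulates births (integrated proliferation), the number
  # of cell divisions in the interval, which division-coupled SHM consumes
  fun <- function(y) {
    cb <- y[idx$cb]
    d <- gc_derivatives(cb, y[idx$cc], y[idx$mem], y[idx$pla],
                        sigma, sig$s_d, sig$s_a, rates)
    births <- rates$rho_cb *
      density_factor(sum(cb), rates$capacity, rates$hill_h) * cb
    c(d$dcb, d$dcc, d$dmem, d$dpla, births)
  }
  y0 <- c(state$cb, state$cc, state$mem, state$pla, numeric(n))
  sol <- tryCatch(
    rk45(y0, fun, dt, params$ode$rtol, params$ode$atol),
    error = function(e) {
      stop("integration failed at t = ", state$time, " with ", n,
           " subclones: ", conditionMessage(e))
    }
  )
  state$cb <- sol$y[idx$cb]
  state$cc <- sol$y[idx$cc]
  state$mem <- sol$y[idx$mem]
  state$pla <- sol$y[idx$pla]
  state$births <- sol$y[idx$births]
  state$time <- state$time + dt
  state
}

# per-subclone signals at interval start (clamped during monoclonal expansion)
interval_signals <- function(state, params) {
  sg <- params$signals
  if (state$time < sg$clamp_days) {
    n <- length(state$cb)
    list(s_d = rep.int(sg$clamp_value, n), s_a = rep.int(sg$clamp_value, n))
  } else {
    rel <- relative_affinities(state$sigma)
    list(s_d = survival_signal(rel, sg$k_d, sg$n_d),
         s_a = survival_signal(rel, sg$k_a, sg$n_a))
  }
}
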