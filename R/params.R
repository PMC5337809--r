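#' Model parameters for a germinal-center reaction simulation
#'
#' Builds the full, validated parameter set of the model with literature
#' defaults. The model describes a single germinal center (GC) in which every
#' B-cell subclone `i` carries four continuous compartments -- centroblasts
#' (CB), centrocytes (CC), memory cells (M) and plasma cells (P) -- coupled by
#' proliferation, differentiation and apoptosis rates, with selection acting
#' through two Hill-type survival signals driven by the subclone's relative
#' affinity, and diversification through stochastic somatic hypermutation
#' (SHM) imposed after every 6-h centroblast division.
#'
#' Parameter groups (override any subset by passing a named list with the
#' same nesting, e.g. `gcr_params(rates = list(mu_cc = 8))`):
#'
#' \describe{
#'   \item{rates}{`rho_cb` CB proliferation (4/day), `eta_cb_cc` CB->CC
#'     differentiation (6/day), `eta_cc_cb` CC->CB recycling (1/day),
#'     `eta_cc_m` CC->memory (1/day), `eta_cc_p` CC->plasma coefficient
#'     (0.1/day per uM of absolute affinity), apoptosis/death rates
#'     `mu_cc` (4/day), `mu_p` (0.25/day), `mu_m` (0.01/day), carrying
#'     `capacity` A (8000 cells) and the capacity Hill exponent `hill_h` (20).}
#'   \item{signals}{Half-max and Hill exponent of the differentiation signal
#'     (`k_d` = 0.06, `n_d` = 1) and of the apoptosis signal (`k_a` = 0.1,
#'     `n_a` = 4); `clamp_value` (0.9) replaces both signals during the first
#'     `clamp_days` (4) of monoclonal expansion.}
#'   \item{tree}{Branch probabilities of the SHM fate tree: `p_fwr` that a
#'     mutation falls in the framework region, `p_repl_fwr` / `p_repl_cdr`
#'     that a FWR/CDR mutation is a replacement, `p_lethal_fwr` that a FWR
#'     replacement is lethal, `p_affinity_cdr` that a CDR replacement changes
#'     affinity. These are figure-only in the source model (taken from older
#'     mouse data) and should be regarded as tunable; the defaults
#'     (0.75, 0.75, 0.75, 0.5, 0.5) are documented literature-style choices,
#'     not measured values.}
#'   \item{affinity}{Inverse-gamma `shape` (3) and `rate` (0.3) of the
#'     affinity-change distribution, its `parameterization` ("scale": the rate
#'     value is the inverse-gamma scale, mean r/(s-1); "rate": it is the
#'     inverse scale), the `shift_coeff` (0.1 per uM) that discourages further
#'     improvement in already-good binders, and `min_affinity` (0.001 uM), the
#'     floor applied when a drawn change would push affinity to zero or below.}
#'   \item{shm}{`lambda` expected mutations per division (0.6 = 600 nt x 1e-3
#'     per bp per division), `mode`: "per_division" (default; the daughters
#'     at risk of mutation are the cells born during the interval, i.e. the
#'     integrated density-limited proliferation -- SHM is replication-
#'     coupled), "per_cell" (all floor(CB) standing cells mutate each 6 h)
#'     or "per_subclone" (one representative daughter per subclone),
#'     `eligibility_floor` (CB >= 1 required for SHM),
#'     `level` "nucleotide" (every non-lethal mutation spawns a subclone) or
#'     "peptide" (only CDR replacements spawn), and `peptide_spawn`
#'     ("any_cdr_replacement" or "affinity_only").}
#'   \item{schedule}{`t_end` 21 days, `dt` 0.25 day (one CB division),
#'     `shm_start_day` 4, `n_founders` 3, `founder_affinities`
#'     c(0.1, 0.3, 0.5) uM, `removal_threshold` 0.1 (subclones with
#'     CB + CC below it are pruned).}
#'   \item{ode}{Integrator tolerances `rtol` (1e-6), `atol` (1e-8).}
#' }
#'
#' @param ... named parameter groups (partial nested lists) overriding the
#'   defaults.
#' @return A validated object of class `gcr_params`.
#' @examples
#' p <- gcr_params()
#' p$rates$rho_cb
#' p2 <- gcr_params(rates = list(mu_cc = 8), shm = list(level = "peptide"))
#' @export
gcr_params <- function(...) {
  defaults <- list(
    rates = list(
      rho_cb = 4, eta_cb_cc = 6, eta_cc_cb = 1, eta_cc_m = 1, eta_cc_p = 0.1,
      mu_cc = 4, mu_p = 0.25, mu_m = 0.01, capacity = 8000, hill_h = 20
    ),
    signals = list(
      k_d = 0.06, n_d = 1, k_a = 0.1, n_a = 4,
      clamp_value = 0.9, clamp_days = 4
    ),
    tree = list(
      p_fwr = 0.75, p_repl_fwr = 0.75, p_repl_cdr = 0.75,
      p_lethal_fwr = 0.5, p_affinity_cdr = 0.5
    ),
    affinity = list(
      shape = 3, rate = 0.3, parameterization = "scale",
      shift_coeff = 0.1, min_affinity = 0.001
    ),
    shm = list(
      lambda = 0.6, mode = "per_division", eligibility_floor = 1,
      level = "nucleotide", peptide_spawn = "any_cdr_replacement"
    ),
    schedule = list(
      t_end = 21, dt = 0.25, shm_start_day = 4,
      n_founders = 3, founder_affinities = c(0.1, 0.3, 0.5),
      removal_threshold = 0.1
    ),
    ode = list(rtol = 1e-6, atol = 1e-8)
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  p <- modify_params(defaults, overrides)
  class(p) <- "gcr_params"
  validate_params(p)
  p
}

# recursive merge of a partial override list into the defaults; unknown keys
# are an error so typos cannot silently fall back to defaults
modify_params <- function(base, overrides, path = character()) {
  if (length(overrides) == 0) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("parameter overrides must be named (at ",
         if (length(path)) paste(path, collapse = ".") else "top level", ")")
  }
  for (nm in nms) {
    here <- c(path, nm)
    if (!nm %in% names(base)) {
      stop("unknown parameter: ", paste(here, collapse = "."))
    }
    if (is.list(base[[nm]]) && !is.list(overrides[[nm]])) {
      stop("parameter group '", paste(here, collapse = "."),
           "' must be overridden with a named list")
    }
    if (is.list(base[[nm]])) {
      base[[nm]] <- modify_params(base[[nm]], overrides[[nm]], here)
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Set a parameter by dotted key path
#'
#' Convenience accessor used by the configuration reader and parameter sweeps:
#' `set_param(p, "rates.mu_cc", 8)`.
#'
#' @param params a `gcr_params` object.
#' @param path dotted key path, e.g. `"signals.k_d"`.
#' @param value replacement value.
#' @return The modified, re-validated `gcr_params` object.
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) != 2L || !keys[1] %in% names(params) ||
      !keys[2] %in% names(params[[keys[1]]])) {
    stop("unknown parameter path: ", path)
  }
  params[[keys[1]]][[keys[2]]] <- value
  validate_params(params)
  params
}

#' Get a parameter by dotted key path
#' @inheritParams set_param
#' @return The parameter value.
#' @export
get_param <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) != 2L || !keys[1] %in% names(params) ||
      !keys[2] %in% names(params[[keys[1]]])) {
    stop("unknown parameter path: ", path)
  }
  params[[keys[1]]][[keys[2]]]
}

chk <- function(ok, key, msg) {
  if (!isTRUE(ok)) stop("invalid parameter ", key, ": ", msg, call. = FALSE)
}

#' Validate a parameter set
#'
#' Checks every invariant of the model configuration (probabilities in
#' \[0, 1\], nonnegative rates, shape > 2 so the affinity-change mean exists,
#' a schedule whose step divides the horizon, ...). Called automatically by
#' [gcr_params()] and [set_param()].
#'
#' @param params a `gcr_params` object.
#' @return Invisibly `TRUE`; errors name the offending key.
#' @export
validate_params <- function(params) {
  r <- params$rates
  for (k in c("rho_cb", "eta_cb_cc", "eta_cc_cb", "eta_cc_m", "eta_cc_p",
              "mu_cc", "mu_p", "mu_m")) {
    chk(is.numeric(r[[k]]) && length(r[[k]]) == 1 && r[[k]] >= 0,
        paste0("rates.", k), "must be a single nonnegative number")
  }
  chk(r$capacity > 0, "rates.capacity", "must be > 0")
  chk(r$hill_h >= 1, "rates.hill_h", "must be >= 1")

  s <- params$signals
  chk(s$k_d > 0 && s$k_d <= 1, "signals.k_d", "must be in (0, 1]")
  chk(s$k_a > 0 && s$k_a <= 1, "signals.k_a", "must be in (0, 1]")
  chk(s$n_d >= 1, "signals.n_d", "must be >= 1")
  chk(s$n_a >= 1, "signals.n_a", "must be >= 1")
  chk(s$clamp_value >= 0 && s$clamp_value <= 1, "signals.clamp_value",
      "must be in [0, 1]")
  chk(s$clamp_days >= 0, "signals.clamp_days", "must be >= 0")

  tr <- params$tree
  for (k in names(tr)) {
    chk(is.numeric(tr[[k]]) && length(tr[[k]]) == 1 &&
          tr[[k]] >= 0 && tr[[k]] <= 1,
        paste0("tree.", k), "must be a probability in [0, 1]")
  }

  a <- params$affinity
  chk(a$shape > 2, "affinity.shape",
      "must be > 2 (inverse-gamma mean and variance must exist)")
  chk(a$rate > 0, "affinity.rate", "must be > 0")
  chk(a$parameterization %in% c("scale", "rate"), "affinity.parameterization",
      "must be \"scale\" or \"rate\"")
  chk(a$shift_coeff >= 0, "affinity.shift_coeff", "must be >= 0")
  chk(a$min_affinity > 0, "affinity.min_affinity", "must be > 0")

  m <- params$shm
  chk(m$lambda >= 0, "shm.lambda", "must be >= 0")
  chk(m$mode %in% c("per_division", "per_cell", "per_subclone"), "shm.mode",
      "must be \"per_division\", \"per_cell\" or \"per_subclone\"")
  chk(m$eligibility_floor >= 0, "shm.eligibility_floor", "must be >= 0")
  chk(m$level %in% c("nucleotide", "peptide"), "shm.level",
      "must be \"nucleotide\" or \"peptide\"")
  chk(m$peptide_spawn %in% c("any_cdr_replacement", "affinity_only"),
      "shm.peptide_spawn",
      "must be \"any_cdr_replacement\" or \"affinity_only\"")

  sc <- params$schedule
  chk(sc$t_end > 0, "schedule.t_end", "must be > 0")
  chk(sc$dt > 0, "schedule.dt", "must be > 0")
  chk(abs(sc$t_end / sc$dt - round(sc$t_end / sc$dt)) < 1e-9, "schedule.dt",
      "must divide t_end evenly")
  chk(sc$shm_start_day >= 0, "schedule.shm_start_day", "must be >= 0")
  chk(sc$n_founders >= 1, "schedule.n_founders", "must be >= 1")
  chk(length(sc$founder_affinities) == sc$n_founders,
      "schedule.founder_affinities",
      "length must equal schedule.n_founders")
  chk(all(sc$founder_affinities >= a$min_affinity),
      "schedule.founder_affinities",
      "all founders must be >= affinity.min_affinity")
  chk(sc$removal_threshold >= 0, "schedule.removal_threshold", "must be >= 0")
  if (anyDuplicated(sc$founder_affinities)) {
    warning("duplicate founder affinities: founders were meant to start ",
            "with distinct values to establish initial competition")
  }

  chk(params$ode$rtol > 0, "ode.rtol", "must be > 0")
  chk(params$ode$atol > 0, "ode.atol", "must be > 0")
  invisible(TRUE)
}

#' @export
print.gcr_params <- function(x, ...) {
  cat("Germinal-center simulation parameters\n")
  for (grp in names(x)) {
    vals <- vapply(x[[grp]], function(v) paste(format(v), collapse = ","), "")
    cat(sprintf("  %-9s %s\n", grp,
                paste(names(vals), vals, sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Flatten / unflatten parameters to dotted key paths
#'
#' Used by the config file round-trip and by parameter sweeps.
#' @param params a `gcr_params` object.
#' @return A named list `group.key -> value`.
#' @export
flatten_params <- function(params) {
  out <- list()
  for (grp in names(params)) {
    for (k in names(params[[grp]])) {
      out[[paste(grp, k, sep = ".")]] <- params[[grp]][[k]]
    }
  }
  out
}

# inverse-gamma helpers ------------------------------------------------------

# scale of the inverse gamma under either reading of the "rate" parameter
invgamma_scale <- function(shape, rate, parameterization = "scale") {
  if (parameterization == "scale") rate else 1 / rate
}

#' Analytic mean of the configured inverse-gamma distribution
#'
#' The affinity-change rule centers its inverse-gamma draw by subtracting the
#' analytic mean, so the mean must exist (shape > 2 is enforced at validation
#' so the variance exists too).
#'
#' @param shape inverse-gamma shape (> 2).
#' @param rate second parameter, interpreted per `parameterization`.
#' @param parameterization `"scale"` (mean = rate / (shape - 1)) or `"rate"`
#'   (mean = 1 / (rate * (shape - 1))).
#' @return The mean, a single number.
#' @export
invgamma_mean <- function(shape, rate, parameterization = "scale") {
  if (shape <= 2) stop("inverse-gamma shape must be > 2")
  invgamma_scale(shape, rate, parameterization) / (shape - 1)
}

# draws from the configured inverse gamma: X = scale / Gamma(shape, rate = 1)
rinvgamma <- function(n, shape, rate, parameterization = "scale") {
  invgamma_scale(shape, rate, parameterization) /
    stats::rgamma(n, shape = shape, rate = 1)
}
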