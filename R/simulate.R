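# Orchestration of the 21-day germinal-center reaction: founder
# initialization, alternating 6-h ODE / SHM steps, the day-4 switches (SHM
# on, signal clamp off), pruning of vanished subclones, and replicates.

#' Initialize a germinal-center state
#'
#' The reaction starts at day 0 with `n_founders` single centroblasts of
#' distinct low affinities (defaults 0.1, 0.3, 0.5 uM, chosen to establish
#' initial competition); all other compartments start empty.
#'
#' @param params a `gcr_params` object.
#' @return A `gc_state` object: parallel vectors `id`, `parent_id`, `sigma`,
#'   `n_mut`, `birth_step`, `cb`, `cc`, `mem`, `pla`, plus `time`, `step`,
#'   `next_id` and the cumulative memory/plasma output of pruned subclones.
#' @export
gcr_initialize <- function(params = gcr_params()) {
  sc <- params$schedule
  n <- sc$n_founders
  state <- list(
    time = 0, step = 0L, next_id = n + 1L,
    id = seq_len(n), parent_id = rep(NA_integer_, n),
    sigma = as.numeric(sc$founder_affinities),
    n_mut = integer(n), birth_step = integer(n),
    cb = rep(1, n), cc = rep(0, n), mem = rep(0, n), pla = rep(0, n),
    removed_mem = 0, removed_pla = 0
  )
  class(state) <- "gc_state"
  state
}

#' Advance the reaction by one 6-h division step
#'
#' (1) integrates the ODE system over `dt` (with clamped signals while
#' `time < clamp_days`); (2) if the step started at or after `shm_start_day`,
#' imposes somatic hypermutation; (3) prunes every subclone whose CB + CC has
#' fallen below `removal_threshold`, adding its memory and plasma tallies to
#' the cumulative removed output.
#'
#' @param state a `gc_state` object.
#' @param params a `gcr_params` object.
#' @return The advanced state; attribute `"step_log"` carries the spawn /
#'   lethal / prune records of this step.
#' @export
gcr_step <- function(state, params) {
  t_start <- state$time
  state$step <- state$step + 1L
  state <- integrate_interval(state, params$schedule$dt, params)

  if (t_start >= params$schedule$shm_start_day - 1e-9 &&
      length(state$cb) > 0L) {
    state <- apply_shm_step(state, params)
    shm_log <- attr(state, "shm_log")
    attr(state, "shm_log") <- NULL
  } else {
    shm_log <- list(n_lethal = 0L, spawns = empty_spawn_frame())
  }
  state$births <- NULL  # consumed by SHM; stale after the population edits

  keep <- (state$cb + state$cc) >= params$schedule$removal_threshold
  pruned <- list(id = state$id[!keep], mem = state$mem[!keep],
                 pla = state$pla[!keep])
  if (any(!keep)) {
    state$removed_mem <- state$removed_mem + sum(pruned$mem)
    state$removed_pla <- state$removed_pla + sum(pruned$pla)
    for (f in c("id", "parent_id", "sigma", "n_mut", "birth_step",
                "cb", "cc", "mem", "pla")) {
      state[[f]] <- state[[f]][keep]
    }
  }
  attr(state, "step_log") <- list(shm = shm_log, pruned = pruned)
  state
}

#' Run one complete germinal-center reaction
#'
#' Executes `t_end / dt` division steps (84 with defaults: 21 days in 6-h
#' intervals). Somatic hypermutation and unclamped selection signals switch
#' on at the first step starting at `shm_start_day`. The run is fully
#' deterministic given `(params, seed)`.
#'
#' @param params a `gcr_params` object.
#' @param seed integer seed for the replicate's random stream.
#' @param record `"summary"` keeps per-step population summaries, the event
#'   genealogy and the final state; `"full"` additionally keeps the per-step
#'   per-subclone trajectory table (large for default runs).
#' @param replicate replicate index stored in the result.
#' @return A `gcr_result` list: `seed`, `replicate`, `params`, `extinct`,
#'   `step_summary` (per step: totals, number of subclones with CC >= 1, max
#'   mutation counts, cell-weighted mean affinity), `events` (founder /
#'   spawn / lethal / prune records; founders and spawns together list every
#'   subclone ever created with its fixed affinity), `final` (per-subclone
#'   state at day `t_end`), `cumulative_removed_output`, and optionally
#'   `trajectory`.
#' @export
gcr_simulate <- function(params = gcr_params(), seed = 1L,
                         record = c("summary", "full"), replicate = 1L) {
  record <- match.arg(record)
  set.seed(as.integer(seed))
  state <- gcr_initialize(params)
  n_steps <- round(params$schedule$t_end / params$schedule$dt)

  summaries <- vector("list", n_steps + 1L)
  events <- vector("list", n_steps + 1L)
  traj <- if (record == "full") vector("list", n_steps + 1L) else NULL
  summaries[[1]] <- state_summary(state)
  events[[1]] <- founder_events(state)
  if (record == "full") traj[[1]] <- state_snapshot(state)

  extinct <- FALSE
  for (i in seq_len(n_steps)) {
    state <- gcr_step(state, params)
    log <- attr(state, "step_log")
    attr(state, "step_log") <- NULL
    events[[i + 1L]] <- step_events(log, state$step, state$time)
    summaries[[i + 1L]] <- state_summary(state)
    if (record == "full") traj[[i + 1L]] <- state_snapshot(state)
    if (length(state$cb) == 0L) {
      extinct <- TRUE
      break
    }
  }

  res <- list(
    seed = as.integer(seed), replicate = as.integer(replicate),
    params = params, extinct = extinct,
    step_summary = do.call(rbind, summaries[!vapply(summaries, is.null, TRUE)]),
    events = do.call(rbind, events[!vapply(events, is.null, TRUE)]),
    final = state_snapshot(state),
    cumulative_removed_output = c(mem = state$removed_mem,
                                  pla = state$removed_pla)
  )
  if (record == "full") {
    res$trajectory <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  }
  class(res) <- "gcr_result"
  res
}

state_summary <- function(state) {
  cc1 <- state$cc >= 1
  living <- state$cb + state$cc
  data.frame(
    step = state$step, time = state$time,
    n_living = length(state$cb),
    cb_total = sum(state$cb), cc_total = sum(state$cc),
    mem_total = sum(state$mem), pla_total = sum(state$pla),
    n_cc1 = sum(cc1),
    max_mut = if (length(state$n_mut)) max(state$n_mut) else NA_integer_,
    max_mut_cc1 = if (any(cc1)) max(state$n_mut[cc1]) else NA_integer_,
    aff_mean_cell = if (sum(living) > 0) {
      sum(state$sigma * living) / sum(living)
    } else NA_real_
  )
}

state_snapshot <- function(state) {
  data.frame(
    step = rep.int(state$step, length(state$id)),
    time = rep.int(state$time, length(state$id)),
    id = state$id, parent_id = state$parent_id,
    sigma = state$sigma, n_mut = state$n_mut,
    birth_step = state$birth_step,
    cb = state$cb, cc = state$cc, mem = state$mem, pla = state$pla
  )
}

event_frame <- function(type, step, time, id = NA_integer_,
                        parent_id = NA_integer_, sigma = NA_real_,
                        delta_sigma = NA_real_, n_mut_added = NA_integer_,
                        count = NA_integer_, mem_carried = NA_real_,
                        pla_carried = NA_real_) {
  data.frame(type = type, step = step, time = time, id = id,
             parent_id = parent_id, sigma = sigma, delta_sigma = delta_sigma,
             n_mut_added = n_mut_added, count = count,
             mem_carried = mem_carried, pla_carried = pla_carried)
}

founder_events <- function(state) {
  event_frame("founder", 0L, 0, id = state$id, parent_id = NA_integer_,
              sigma = state$sigma, delta_sigma = 0, n_mut_added = 0L)
}

step_events <- function(log, step, time) {
  out <- list()
  sp <- log$shm$spawns
  if (nrow(sp) > 0L) {
    out$spawn <- event_frame("spawn", step, time, id = sp$id,
                             parent_id = sp$parent_id, sigma = sp$sigma,
                             delta_sigma = sp$delta_sigma,
                             n_mut_added = sp$n_mut_added)
  }
  if (log$shm$n_lethal > 0L) {
    out$lethal <- event_frame("lethal", step, time, count = log$shm$n_lethal)
  }
  if (length(log$pruned$id) > 0L) {
    out$prune <- event_frame("prune", step, time, id = log$pruned$id,
                             mem_carried = log$pruned$mem,
                             pla_carried = log$pruned$pla)
  }
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

#' @export
print.gcr_result <- function(x, ...) {
  ss <- x$step_summary
  peak <- which.max(ss$cb_total + ss$cc_total)
  cat("Germinal-center simulation (seed ", x$seed, ", ",
      x$params$shm$level, " level)\n", sep = "")
  cat(sprintf("  %d steps over %.1f days; peak CB+CC = %.0f at day %.2f\n",
              max(ss$step), max(ss$time),
              ss$cb_total[peak] + ss$cc_total[peak], ss$time[peak]))
  cat(sprintf("  subclones ever created: %d; alive at end: %d (%d with CC >= 1)\n",
              sum(x$events$type %in% c("founder", "spawn")),
              nrow(x$final), ss$n_cc1[nrow(ss)]))
  if (x$extinct) cat("  NOTE: population went extinct before t_end\n")
  invisible(x)
}

#' Run replicate simulations
#'
#' Somatic hypermutation makes the reaction stochastic; summary statistics
#' are therefore averaged over repeated runs from identical initial
#' conditions (the source analysis used 15 replicates).
#'
#' @param params a `gcr_params` object.
#' @param seeds vector of distinct integer seeds, one per replicate.
#' @param record passed to [gcr_simulate()].
#' @return List of `gcr_result` objects.
#' @export
gcr_replicates <- function(params = gcr_params(), seeds = 1:15,
                           record = c("summary", "full")) {
  if (anyDuplicated(seeds)) stop("replicate seeds must be distinct")
  record <- match.arg(record)
  lapply(seq_along(seeds), function(i) {
    gcr_simulate(params, seed = seeds[i], record = record, replicate = i)
  })
}

#' One-row summary of a completed run
#'
#' @param result a `gcr_result`.
#' @return Data frame with peak size/day, final totals, late-phase subclone
#'   diversity and maximum mutation count.
#' @export
gcr_summary_row <- function(result) {
  ss <- result$step_summary
  total <- ss$cb_total + ss$cc_total
  peak <- which.max(total)
  late <- ss$time >= max(ss$time) / 2
  data.frame(
    seed = result$seed, replicate = result$replicate,
    extinct = result$extinct,
    peak_total = total[peak], peak_day = ss$time[peak],
    final_total = total[nrow(ss)],
    mean_n_cc1_late = mean(ss$n_cc1[late]),
    max_mut_final = ss$max_mut_cc1[nrow(ss)],
    n_subclones_ever = sum(result$events$type %in% c("founder", "spawn"))
  )
}

#' Parameter sweep
#'
#' Runs the simulation over a grid of parameter overrides (sensitivity
#' analysis). No ranking or inference is performed; each grid point x seed
#' yields one [gcr_summary_row()].
#'
#' @param params base `gcr_params`.
#' @param grid named list mapping dotted parameter paths (e.g.
#'   `"rates.mu_cc"`) to value vectors; the full Cartesian product is run.
#' @param seeds one or more seeds per grid point.
#' @return Data frame: one row per grid point x seed, grid values as leading
#'   columns.
#' @export
parameter_sweep <- function(params = gcr_params(), grid = list(),
                            seeds = 1L) {
  for (path in names(grid)) get_param(params, path)  # validate before any run
  combos <- if (length(grid) == 0) {
    data.frame(row.names = 1)
  } else {
    expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    p <- params
    for (path in names(grid)) p <- set_param(p, path, combos[i, path])
    for (s in seeds) {
      row <- gcr_summary_row(gcr_simulate(p, seed = s))
      if (length(grid)) row <- cbind(combos[i, , drop = FALSE], row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
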