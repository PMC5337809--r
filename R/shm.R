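# Somatic hypermutation engine: mutation counts, the per-mutation fate tree,
# inverse-gamma affinity changes, and the population rewrite after a division.
# Randomness uses R's global RNG stream; simulations seed it once per
# replicate so every draw is reproducible from (params, seed).

MUTATION_LEAVES <- c("silent", "fwr_replacement_lethal",
                     "fwr_replacement_viable", "cdr_replacement_neutral",
                     "cdr_replacement_affinity")

#' Number of somatic mutations acquired in one division
#'
#' The B-cell receptor is modeled as a 600-nt entity mutating at 1e-3 per bp
#' per division, i.e. Poisson with mean `lambda` = 0.6 mutations per division.
#'
#' @param n number of daughter cells to draw for.
#' @param lambda expected mutations per division (>= 0).
#' @return Integer vector of mutation counts.
#' @export
draw_mutation_count <- function(n, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("lambda must be a single nonnegative number")
  }
  stats::rpois(n, lambda)
}

# leaf probabilities implied by the branch probabilities of the fate tree
tree_leaf_probs <- function(tree) {
  with(tree, c(
    silent = p_fwr * (1 - p_repl_fwr) + (1 - p_fwr) * (1 - p_repl_cdr),
    fwr_replacement_lethal = p_fwr * p_repl_fwr * p_lethal_fwr,
    fwr_replacement_viable = p_fwr * p_repl_fwr * (1 - p_lethal_fwr),
    cdr_replacement_neutral = (1 - p_fwr) * p_repl_cdr * (1 - p_affinity_cdr),
    cdr_replacement_affinity = (1 - p_fwr) * p_repl_cdr * p_affinity_cdr
  ))
}

#' Route one somatic mutation through the fate tree
#'
#' Each mutation falls in the framework region (FWR) with probability
#' `p_fwr`, else in a complementarity-determining region (CDR); it is a
#' replacement with probability `p_repl_fwr` / `p_repl_cdr`; an FWR
#' replacement is lethal with probability `p_lethal_fwr`; a CDR replacement
#' changes affinity (rather than being neutral) with probability
#' `p_affinity_cdr`. Branches are sampled sequentially, so over many draws
#' each of the five leaves occurs with the product of its branch
#' probabilities.
#'
#' @param tree list of the five branch probabilities (see [gcr_params()]
#'   group `tree`).
#' @return One of `"silent"`, `"fwr_replacement_lethal"`,
#'   `"fwr_replacement_viable"`, `"cdr_replacement_neutral"`,
#'   `"cdr_replacement_affinity"`.
#' @export
classify_mutation <- function(tree) {
  if (stats::runif(1) < tree$p_fwr) {
    if (stats::runif(1) < tree$p_repl_fwr) {
      if (stats::runif(1) < tree$p_lethal_fwr) "fwr_replacement_lethal"
      else "fwr_replacement_viable"
    } else "silent"
  } else {
    if (stats::runif(1) < tree$p_repl_cdr) {
      if (stats::runif(1) < tree$p_affinity_cdr) "cdr_replacement_affinity"
      else "cdr_replacement_neutral"
    } else "silent"
  }
}

# vectorized leaf sampling for many mutations at once (same distribution as
# classify_mutation, used on the hot path)
sample_mutation_leaves <- function(n, tree) {
  if (n == 0L) return(integer(0))
  sample.int(5L, n, replace = TRUE, prob = tree_leaf_probs(tree))
}

#' Draw an affinity change for an affinity-altering CDR replacement
#'
#' The change is `X - mu - shift_coeff * sigma_parent`, where `X` is
#' inverse-gamma(shape, rate) and `mu` its analytic mean. Centering by `mu`
#' gives roughly equal chances of improving and worsening affinity, the
#' right skew of the inverse gamma leaves a small chance of large
#' improvements (key mutations), and the parent-affinity shift makes further
#' improvement increasingly unlikely in already strong binders.
#'
#' @param n number of draws.
#' @param sigma_parent parent subclone absolute affinity (uM), scalar or
#'   length-n vector.
#' @param affinity affinity-change parameter group (see [gcr_params()]).
#' @return Numeric vector of affinity changes (uM).
#' @export
draw_affinity_delta <- function(n, sigma_parent, affinity) {
  if (any(sigma_parent < 0)) stop("sigma_parent must be >= 0")
  mu <- invgamma_mean(affinity$shape, affinity$rate, affinity$parameterization)
  x <- rinvgamma(n, affinity$shape, affinity$rate, affinity$parameterization)
  x - mu - affinity$shift_coeff * sigma_parent
}

#' Fate of one daughter cell after division
#'
#' Classifies each of the cell's `n_mutations` mutations through the fate
#' tree and reduces them to a disposition: any lethal FWR replacement kills
#' the cell; otherwise, at the nucleotide tracking level any mutated cell
#' founds a new subclone, while at the peptide level only cells with a CDR
#' replacement do (configurable to affinity-changing replacements only). If
#' one or more affinity-changing mutations occurred, a single affinity change
#' is drawn regardless of their number.
#'
#' @param n_mutations number of mutations this daughter acquired.
#' @param sigma_parent parent absolute affinity (uM).
#' @param params a `gcr_params` object (groups `tree`, `affinity`, `shm`).
#' @return List with `disposition` (`"unchanged"`, `"dies"`, or
#'   `"spawns_new_subclone"`), `outcomes` (character vector of leaf names),
#'   `n_mutations`, and `total_delta_affinity`.
#' @export
decide_cell_fate <- function(n_mutations, sigma_parent, params) {
  if (n_mutations < 0) stop("n_mutations must be >= 0")
  outcomes <- MUTATION_LEAVES[sample_mutation_leaves(n_mutations, params$tree)]
  lethal <- any(outcomes == "fwr_replacement_lethal")
  affinity_hit <- any(outcomes == "cdr_replacement_affinity")
  spawns <- spawn_rule(n_mutations >= 1,
                       any(startsWith(outcomes, "cdr_replacement")),
                       affinity_hit, params$shm)
  delta <- if (!lethal && affinity_hit) {
    draw_affinity_delta(1L, sigma_parent, params$affinity)
  } else 0
  list(
    n_mutations = n_mutations,
    outcomes = outcomes,
    disposition = if (lethal) "dies"
                  else if (spawns) "spawns_new_subclone"
                  else "unchanged",
    total_delta_affinity = delta
  )
}

# spawn rule by tracking level (vectorized over cells)
spawn_rule <- function(any_mutation, any_cdr_repl, any_affinity, shm) {
  if (shm$level == "nucleotide") {
    any_mutation
  } else if (shm$peptide_spawn == "any_cdr_replacement") {
    any_cdr_repl
  } else {
    any_affinity
  }
}

#' Impose somatic hypermutation on a population after one division
#'
#' For every subclone whose CB count is at least the eligibility floor,
#' `floor(CB)` daughter cells each acquire a Poisson number of mutations and
#' a fate. A dying daughter decrements the parent's CB count by one; a
#' spawning daughter decrements it by one and founds a new subclone with
#' CB = 1, CC = M = P = 0, affinity clamped at `min_affinity`, mutation count
#' equal to the parent's plus its own, and a recorded parent link. Subclones
#' with CB below the floor are left untouched so that sub-unit continuous
#' counts cannot generate cells.
#'
#' @param state a `gc_state` object (see [gcr_initialize()]).
#' @param params a `gcr_params` object.
#' @return The updated state, with attribute `"shm_log"` carrying a list
#'   (`n_lethal`, and a data frame `spawns` with one row per new subclone:
#'   id, parent_id, sigma, delta_sigma, n_mut_added, plus per-leaf mutation
#'   counts).
#' @export
apply_shm_step <- function(state, params) {
  shm <- params$shm
  eligible <- which(state$cb >= shm$eligibility_floor)
  empty_log <- list(n_lethal = 0L, spawns = empty_spawn_frame())
  if (length(eligible) == 0L) {
    attr(state, "shm_log") <- empty_log
    return(state)
  }

  if (shm$mode == "per_division") {
    # SHM is replication-coupled: the daughters at risk of mutation are the
    # cells born in the past interval (integrated rho * density * CB, kept
    # by the integrator), not the whole standing CB count -- near carrying
    # capacity only a fraction of cells divides per 6 h
    births <- state$births
    if (is.null(births)) {
      dens <- density_factor(sum(state$cb), params$rates$capacity,
                             params$rates$hill_h)
      births <- params$rates$rho_cb * dens * state$cb * params$schedule$dt
    }
    n_daughters <- pmin(stats::rpois(length(eligible), births[eligible]),
                        floor(state$cb[eligible]))
  } else if (shm$mode == "per_cell") {
    n_daughters <- floor(state$cb[eligible])
  } else {
    # per_subclone: one representative daughter per subclone and division
    n_daughters <- rep.int(1L, length(eligible))
  }
  parent_idx <- rep.int(eligible, n_daughters)   # one entry per daughter cell
  n_cells <- length(parent_idx)
  m <- draw_mutation_count(n_cells, shm$lambda)

  hit <- which(m > 0L)
  if (length(hit) == 0L) {
    attr(state, "shm_log") <- empty_log
    return(state)
  }
  parent_hit <- parent_idx[hit]
  m_hit <- m[hit]

  # classify all mutations of all mutated cells in one vectorized pass
  cell_of_mut <- rep.int(seq_along(hit), m_hit)
  leaves <- sample_mutation_leaves(sum(m_hit), params$tree)
  leaf_count <- matrix(0L, nrow = length(hit), ncol = 5L,
                       dimnames = list(NULL, MUTATION_LEAVES))
  for (l in 1:5) {
    tab <- tabulate(cell_of_mut[leaves == l], nbins = length(hit))
    leaf_count[, l] <- tab
  }

  lethal <- leaf_count[, "fwr_replacement_lethal"] > 0L
  affinity_hit <- leaf_count[, "cdr_replacement_affinity"] > 0L
  cdr_repl <- affinity_hit | leaf_count[, "cdr_replacement_neutral"] > 0L
  spawns <- !lethal & spawn_rule(rep(TRUE, length(hit)), cdr_repl,
                                 affinity_hit, shm)

  # parent CB decrements: one per dying and one per spawning daughter
  dec <- tabulate(parent_hit[lethal | spawns], nbins = length(state$cb))
  state$cb <- state$cb - dec

  sp <- which(spawns)
  if (length(sp) > 0L) {
    sp_parent <- parent_hit[sp]
    sigma_parent <- state$sigma[sp_parent]
    delta <- numeric(length(sp))
    aff <- affinity_hit[sp]
    if (any(aff)) {
      # one draw per cell regardless of how many affinity-changing mutations
      delta[aff] <- draw_affinity_delta(sum(aff), sigma_parent[aff],
                                        params$affinity)
    }
    sigma_new <- pmax(sigma_parent + delta, params$affinity$min_affinity)
    ids <- state$next_id + seq_along(sp) - 1L
    spawn_log <- data.frame(
      id = ids,
      parent_id = state$id[sp_parent],
      sigma = sigma_new,
      delta_sigma = delta,
      n_mut_added = m_hit[sp]
    )
    spawn_log <- cbind(spawn_log, as.data.frame(leaf_count[sp, , drop = FALSE]))

    state$id <- c(state$id, ids)
    state$parent_id <- c(state$parent_id, state$id[sp_parent])
    state$sigma <- c(state$sigma, sigma_new)
    state$n_mut <- c(state$n_mut, state$n_mut[sp_parent] + m_hit[sp])
    state$birth_step <- c(state$birth_step,
                          rep.int(state$step, length(sp)))
    state$cb <- c(state$cb, rep.int(1, length(sp)))
    state$cc <- c(state$cc, rep.int(0, length(sp)))
    state$mem <- c(state$mem, rep.int(0, length(sp)))
    state$pla <- c(state$pla, rep.int(0, length(sp)))
    state$next_id <- state$next_id + length(sp)
  } else {
    spawn_log <- empty_spawn_frame()
  }

  attr(state, "shm_log") <- list(n_lethal = sum(lethal), spawns = spawn_log)
  state
}

empty_spawn_frame <- function() {
  out <- data.frame(id = integer(0), parent_id = integer(0),
                    sigma = numeric(0), delta_sigma = numeric(0),
                    n_mut_added = integer(0))
  for (l in MUTATION_LEAVES) out[[l]] <- integer(0)
  out
}
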