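# mutation counts ------------------------------------------------------------

test_that("mutation counts are Poisson with the configured mean", {
  set.seed(1)
  m <- draw_mutation_count(1e5, 0.6)
  expect_equal(mean(m), 0.6, tolerance = 0.01 / 0.6)
  # closed-form pmf check: P(m = 0) = exp(-0.6)
  expect_equal(mean(m == 0), exp(-0.6), tolerance = 0.02)
  expect_true(all(draw_mutation_count(100, 0) == 0))
  expect_error(draw_mutation_count(1, -0.5), "lambda")
})

# fate tree -------------------------------------------------------------------

test_that("forced branches reach the expected leaves", {
  lethal_tree <- list(p_fwr = 1, p_repl_fwr = 1, p_repl_cdr = 0,
                      p_lethal_fwr = 1, p_affinity_cdr = 0)
  silent_tree <- list(p_fwr = 0, p_repl_fwr = 0, p_repl_cdr = 0,
                      p_lethal_fwr = 0, p_affinity_cdr = 0)
  set.seed(2)
  expect_true(all(replicate(20, classify_mutation(lethal_tree)) ==
                    "fwr_replacement_lethal"))
  expect_true(all(replicate(20, classify_mutation(silent_tree)) == "silent"))
})

test_that("leaf frequencies converge to the branch-probability products", {
  trees <- list(
    gcr_params()$tree,
    list(p_fwr = 0.6, p_repl_fwr = 0.8, p_repl_cdr = 0.5,
         p_lethal_fwr = 0.3, p_affinity_cdr = 0.2),
    list(p_fwr = 0.9, p_repl_fwr = 0.2, p_repl_cdr = 0.9,
         p_lethal_fwr = 0.7, p_affinity_cdr = 0.9)
  )
  set.seed(3)
  for (tree in trees) {
    probs <- gcrsim:::tree_leaf_probs(tree)
    expect_equal(sum(probs), 1)
    n <- 1e5
    draws <- gcrsim:::sample_mutation_leaves(n, tree)
    freq <- tabulate(draws, nbins = 5) / n
    se <- sqrt(probs * (1 - probs) / n)
    expect_true(all(abs(freq - probs) <= 4 * se + 1e-9))
  }
  # the scalar sequential sampler draws from the same leaf distribution
  set.seed(4)
  tree <- trees[[2]]
  scalar <- table(factor(replicate(3e4, classify_mutation(tree)),
                         levels = gcrsim:::MUTATION_LEAVES)) / 3e4
  probs <- gcrsim:::tree_leaf_probs(tree)
  se <- sqrt(probs * (1 - probs) / 3e4)
  expect_true(all(abs(as.numeric(scalar) - probs) <= 5 * se + 1e-9))
})

# affinity changes ------------------------------------------------------------

test_that("affinity-change draws are centered at -shift * parent affinity", {
  aff <- gcr_params()$affinity
  set.seed(5)
  n <- 2e5
  d0 <- draw_affinity_delta(n, 0, aff)
  d2 <- draw_affinity_delta(n, 2, aff)
  sd_x <- aff$rate / ((aff$shape - 1) * sqrt(aff$shape - 2))
  tol <- 5 * sd_x / sqrt(n)
  expect_lt(abs(mean(d0)), tol)
  expect_lt(abs(mean(d2) - (-0.2)), tol)
  # right skew: small chance of large improvements (key mutations)
  z <- d0 - mean(d0)
  expect_gt(mean(z^3) / stats::sd(d0)^3, 0)
})

test_that("mean change is strictly decreasing in parent affinity", {
  aff <- gcr_params()$affinity
  set.seed(6)
  means <- vapply(c(0, 1, 5),
                  function(s) mean(draw_affinity_delta(5e4, s, aff)),
                  numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("shape <= 2 is rejected (undefined mean/variance)", {
  expect_error(gcr_params(affinity = list(shape = 1.5)), "affinity.shape")
  expect_error(draw_affinity_delta(1, 0, list(shape = 2, rate = 0.3,
                                              parameterization = "scale",
                                              shift_coeff = 0.1,
                                              min_affinity = 0.001)),
               "shape")
})

# cell fate -------------------------------------------------------------------

test_that("cell fates follow the level rules", {
  p <- gcr_params()
  set.seed(7)
  f0 <- decide_cell_fate(0, 1, p)
  expect_equal(f0$disposition, "unchanged")
  expect_equal(f0$total_delta_affinity, 0)

  lethal <- gcr_params(tree = list(p_fwr = 1, p_repl_fwr = 1,
                                   p_lethal_fwr = 1))
  expect_equal(decide_cell_fate(2, 1, lethal)$disposition, "dies")

  silent <- gcr_params(tree = list(p_fwr = 0, p_repl_cdr = 0))
  # a silent mutation spawns at the nucleotide level but not at the peptide
  expect_equal(decide_cell_fate(1, 1, silent)$disposition,
               "spawns_new_subclone")
  silent_pep <- gcr_params(tree = list(p_fwr = 0, p_repl_cdr = 0),
                           shm = list(level = "peptide"))
  expect_equal(decide_cell_fate(1, 1, silent_pep)$disposition, "unchanged")

  # neutral CDR replacement: spawns at peptide level by default, not under
  # the stricter affinity-only rule
  cdr_neutral <- list(tree = list(p_fwr = 0, p_repl_cdr = 1,
                                  p_affinity_cdr = 0))
  expect_equal(
    decide_cell_fate(1, 1, gcr_params(c(cdr_neutral,
                                        list(shm = list(level = "peptide"))))
                     )$disposition,
    "spawns_new_subclone")
  expect_equal(
    decide_cell_fate(1, 1, gcr_params(c(cdr_neutral,
      list(shm = list(level = "peptide",
                      peptide_spawn = "affinity_only")))))$disposition,
    "unchanged")
})

# population rewrite ----------------------------------------------------------

test_that("subclones below one CB cell are exempt from mutation", {
  p <- gcr_params(shm = list(mode = "per_cell"))
  state <- make_state(sigma = 0.5, cb = 0.7, cc = 0.2)
  set.seed(8)
  out <- apply_shm_step(state, p)
  expect_equal(out$cb, 0.7)
  expect_equal(length(out$id), 1L)
  expect_equal(nrow(attr(out, "shm_log")$spawns), 0L)
})

test_that("all-silent mutations conserve CB and spawn at nucleotide level", {
  p <- gcr_params(tree = list(p_fwr = 0, p_repl_cdr = 0),
                  shm = list(mode = "per_cell"))
  state <- make_state(sigma = c(0.5, 1), cb = c(10, 5))
  set.seed(9)
  out <- apply_shm_step(state, p)
  log <- attr(out, "shm_log")
  expect_equal(log$n_lethal, 0L)
  expect_equal(sum(out$cb), sum(state$cb))  # spawns offset parent decrements
  expect_true(all(log$spawns$delta_sigma == 0))
  expect_equal(out$sigma[match(log$spawns$id, out$id)], log$spawns$sigma)
  # every spawned CB of 1 matches a parent decrement of 1
  dec_by_parent <- table(log$spawns$parent_id)
  for (pid in names(dec_by_parent)) {
    i <- match(as.integer(pid), state$id)
    expect_equal(out$cb[i], state$cb[i] - dec_by_parent[[pid]])
  }
})

test_that("lethal fates remove exactly one CB cell each", {
  p <- gcr_params(tree = list(p_fwr = 1, p_repl_fwr = 1, p_lethal_fwr = 1),
                  shm = list(mode = "per_cell"))
  state <- make_state(sigma = 0.5, cb = 8)
  set.seed(10)
  out <- apply_shm_step(state, p)
  log <- attr(out, "shm_log")
  expect_equal(nrow(log$spawns), 0L)
  expect_equal(sum(out$cb), sum(state$cb) - log$n_lethal)
})

test_that("CB conservation holds for arbitrary trees and modes (property)", {
  set.seed(11)
  for (rep in 1:15) {
    p <- gcr_params(
      tree = list(p_fwr = runif(1), p_repl_fwr = runif(1),
                  p_repl_cdr = runif(1), p_lethal_fwr = runif(1),
                  p_affinity_cdr = runif(1)),
      shm = list(mode = sample(c("per_cell", "per_division",
                                 "per_subclone"), 1),
                 level = sample(c("nucleotide", "peptide"), 1)))
    n <- sample(1:6, 1)
    state <- make_state(sigma = runif(n, 0.1, 3), cb = runif(n, 0, 12))
    out <- apply_shm_step(state, p)
    log <- attr(out, "shm_log")
    expect_equal(sum(out$cb), sum(state$cb) - log$n_lethal)
    expect_true(all(out$cb >= -1e-12))
    if (nrow(log$spawns) > 0) {
      expect_true(all(log$spawns$sigma >= p$affinity$min_affinity))
      spawned <- match(log$spawns$id, out$id)
      expect_true(all(out$cb[spawned] == 1))
      expect_true(all(out$cc[spawned] == 0))
    }
  }
})

test_that("mutation counts accumulate along the parent chain", {
  res <- gcr_simulate(fast_params(), seed = 12)
  ev <- res$events
  born <- ev[ev$type %in% c("founder", "spawn"), ]
  added <- stats::setNames(born$n_mut_added, born$id)
  parent <- stats::setNames(born$parent_id, born$id)
  chain_total <- function(id) {
    tot <- 0L
    while (!is.na(id)) {
      tot <- tot + added[[as.character(id)]]
      id <- parent[[as.character(id)]]
    }
    tot
  }
  fin <- res$final
  expect_gt(nrow(fin), 3)
  for (i in seq_len(nrow(fin))) {
    expect_equal(chain_total(fin$id[i]), fin$n_mut[i])
  }
})
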