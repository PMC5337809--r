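# expansion threshold ---------------------------------------------------------

test_that("gap threshold follows the frequency-histogram rule", {
  call <- expansion_threshold(c(1, 1, 2, 3, 7))
  expect_equal(call$threshold, 4L)   # F(4) = 0 is the first gap
  expect_equal(call$expanded_ids, 5L) # only the count-7 subclone
  expect_equal(expansion_threshold(c(1, 1, 1))$threshold, 2L)
  expect_length(expansion_threshold(c(1, 1, 1))$expanded_ids, 0)
  # gap-free counts: T = max + 1 and nothing is expanded
  nogap <- expansion_threshold(c(1, 2, 3, 4, 5))
  expect_equal(nogap$threshold, 6L)
  expect_length(nogap$expanded_ids, 0)
  expect_error(expansion_threshold(integer(0)), "empty")
  expect_error(expansion_threshold(c(1, 2.5)), "integers")
})

test_that("relaxed thresholds and the brute-force oracle agree (property)", {
  set.seed(30)
  for (rep in 1:40) {
    n <- sample(1:400, 1)
    counts <- sample(1:30, n, replace = TRUE,
                     prob = 1 / (1:30)^runif(1, 1, 3))
    p <- sample(1:3, 1)
    call <- expansion_threshold(counts, relax_p = p)
    expect_equal(call$threshold, oracle_threshold(counts, p))
    expect_setequal(call$expanded_ids, which(counts > call$threshold))
  }
})

# affinity threshold ----------------------------------------------------------

test_that("percentile threshold interpolates between order statistics", {
  expect_equal(affinity_threshold(c(1, 2, 3, 4)), 3.25)
  expect_equal(affinity_threshold(rep(2.5, 10)), 2.5)
  expect_equal(affinity_threshold(c(1, 2, 3, 4), percentile = 100), 4)
  expect_error(affinity_threshold(numeric(0)), "empty")
})

# clonal sizes ----------------------------------------------------------------

test_that("clonal sizes are count fractions", {
  expect_equal(clonal_sizes(c(5, 5, 10)), c(0.25, 0.25, 0.5))
  expect_equal(clonal_sizes(42), 1)
  expect_equal(sum(clonal_sizes(rpois(50, 5) + 1)), 1)
  expect_error(clonal_sizes(c(0, 0)), "positive")
})

# abundance x affinity --------------------------------------------------------

stub_result <- function(cc, sigma, ever_sigma = sigma) {
  n <- length(cc)
  res <- list(
    final = data.frame(id = seq_len(n), parent_id = NA_integer_,
                       sigma = sigma, n_mut = 0L, birth_step = 0L,
                       cb = 0, cc = cc, mem = 0, pla = 0,
                       step = 84L, time = 21),
    events = data.frame(type = "spawn", step = 1L, time = 4.25,
                        id = seq_along(ever_sigma), parent_id = NA_integer_,
                        sigma = ever_sigma, delta_sigma = 0,
                        n_mut_added = 1L, count = NA_integer_,
                        mem_carried = NA_real_, pla_carried = NA_real_)
  )
  class(res) <- "gcr_result"
  res
}

test_that("final CC counts are rounded and zero counts dropped", {
  res <- stub_result(cc = c(6.4, 0.2, 1.6), sigma = c(1, 2, 3))
  obs <- cc_counts_for_expansion(res)
  expect_equal(obs$id, c(1L, 3L))
  expect_equal(obs$count, c(6L, 2L))
})

test_that("perfectly monotone count-affinity pairs give rho of +/-1", {
  res <- stub_result(cc = c(10, 20, 30), sigma = c(1, 2, 3))
  expect_equal(affinity_abundance_summary(res)$spearman_rho, 1)
  res2 <- stub_result(cc = c(10, 20, 30), sigma = c(3, 2, 1))
  expect_equal(affinity_abundance_summary(res2)$spearman_rho, -1)
})

test_that("the 2x2 table partitions the observable subclones", {
  set.seed(31)
  cc <- c(rpois(60, 2) + 1, 40, 55)
  sigma <- runif(62, 0.5, 4)
  res <- stub_result(cc = cc, sigma = sigma)
  summ <- affinity_abundance_summary(res)
  expect_equal(sum(summ$table), nrow(summ$data))
  expect_equal(sum(summ$data$expanded),
               length(summ$expansion$expanded_ids))
  # thresholds derive from every subclone ever created, not just survivors
  res_wide <- stub_result(cc = cc, sigma = sigma,
                          ever_sigma = c(sigma, rep(10, 200)))
  expect_gt(affinity_abundance_summary(res_wide)$affinity_threshold,
            summ$affinity_threshold)
  expect_error(affinity_abundance_summary(stub_result(0.2, 1)),
               "no subclone")
})

test_that("summary trajectories track the monoclonal phase and diversity", {
  res <- gcr_simulate(fast_params(), seed = 32)
  tr <- summary_trajectories(res)
  mono <- tr$time >= 1.5 & tr$time < 4
  expect_true(all(tr$n_subclones[mono] == 3))
  expect_true(all(tr$cb_cc_ratio[tr$time >= 2] > 0))
  # SHM created new subclones after day 4 (they need longer to reach CC >= 1)
  expect_gt(max(res$step_summary$n_living), 3)
  # affinity-class cell totals require (and follow from) a full trajectory
  full <- gcr_simulate(gcr_params(schedule = list(t_end = 5)), seed = 32,
                       record = "full")
  trf <- summary_trajectories(full, affinity_breaks = c(0, 0.25, 0.45, Inf))
  class_cols <- grep("^cells_aff_", names(trf), value = TRUE)
  expect_length(class_cols, 3)
  expect_equal(rowSums(trf[, class_cols]),
               trf$cb_total + trf$cc_total, tolerance = 1e-8)
})
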