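test_that("pattern sequences have one active pattern per window and are seeded", {
  mp <- multi_input_params()
  ps <- pattern_sequence(mp, n_windows = 200, seed = 8, expand = TRUE)
  expect_equal(dim(ps$rates), c(200, 40))
  hi <- ps$rates == mp$pattern_rate_hi
  expect_true(all(rowSums(hi) == mp$pattern_size))
  expect_true(all(ps$rates[!hi] == mp$rho_E_base))
  # active neurons form the contiguous block of the drawn pattern
  for (w in c(1, 57, 200)) {
    k <- ps$pattern[w, 1]
    expect_equal(which(hi[w, ]), (k - 1) * 4 + 1:4)
  }
  ps2 <- pattern_sequence(mp, n_windows = 200, seed = 8, expand = TRUE)
  expect_identical(ps, ps2)
})

test_that("patterns are drawn uniformly across inputs", {
  mp <- multi_input_params()
  pat <- pattern_sequence(mp, n_windows = 10000, seed = 123)$pattern
  tab <- tabulate(pat, nbins = mp$n_inputs)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("selectivity analysis handles the degenerate weight layouts", {
  mp <- multi_input_params()
  uni <- analyze_selectivity(rep(0.03, 40), params = mp)
  expect_equal(uni$selectivity, 0)
  expect_equal(uni$preferred, 1)  # ties break to the lowest input index

  onehot <- rep(0, 40); onehot[13:16] <- 1  # input 4 only
  oh <- analyze_selectivity(onehot, params = mp)
  expect_equal(oh$selectivity, 1)
  expect_equal(oh$preferred, 4)

  # block-diagonal recurrent matrix maximizes within-group bidirectionality
  w_ff <- matrix(0, 4, 40)
  w_ff[1, 1:4] <- 1; w_ff[2, 1:4] <- 1    # neurons 1-2 prefer input 1
  w_ff[3, 5:8] <- 1; w_ff[4, 5:8] <- 1    # neurons 3-4 prefer input 2
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.5
  rep <- analyze_selectivity(w_ff, W, params = mp)
  expect_equal(rep$preferred, c(1, 1, 2, 2))
  expect_equal(rep$within_mean, 0.5)
  expect_equal(rep$across_mean, 0)
  expect_equal(rep$bidir_within, 0.5)
  expect_equal(rep$bidir_across, 0)
  # display threshold zeroes sub-threshold entries
  expect_true(all(rep$adjacency %in% c(0, 0.5)))
})

test_that("without disinhibition the circuit is homeostatic and unselective", {
  mp <- multi_input_params()
  r <- run_multi_input(mp, "none", T_baseline = 5, T_post = 5, seed = 2)
  expect_false(r$diverged)
  tr <- r$trajectory
  settled <- tr[tr$t > 2, ]
  # time-averaged postsynaptic rate within 10% of the target rate
  expect_equal(mean(settled$nu_E), mp$c_post_I, tolerance = 0.1)
  expect_lt(r$report$selectivity[1], 0.2)
  # weights essentially stationary once the rate sits at the target
  late <- tr[tr$t > max(tr$t) - 2, ]
  expect_lt(max(apply(late[, grep("w_EE", names(late))], 2,
                      function(x) diff(range(x)))), 0.01)
})

test_that("specific but not unspecific disinhibition forms a receptive field", {
  mp <- multi_input_params()
  rs <- run_multi_input(mp, "specific", seed = 5)
  ru <- run_multi_input(mp, "unspecific", seed = 5)
  expect_false(rs$diverged); expect_false(ru$diverged)
  expect_gt(rs$report$selectivity[1], 0.5)
  expect_lt(ru$report$selectivity[1], 0.2)
  # winning input's weights dominate in the specific run
  mw <- rs$report$mean_w_per_input[1, ]
  expect_gt(max(mw), 5 * sort(mw, decreasing = TRUE)[2])
})

test_that("multi-input runs are bit-reproducible for a fixed seed", {
  mp <- multi_input_params()
  a <- run_multi_input(mp, "specific", T_baseline = 1, T_post = 1, seed = 17)
  b <- run_multi_input(mp, "specific", T_baseline = 1, T_post = 1, seed = 17)
  expect_identical(a$w_EE, b$w_EE)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$report$selectivity, b$report$selectivity)
})

test_that("recurrent network forms assemblies among same-preference neurons", {
  rr <- run_recurrent(seed = 3)
  expect_false(rr$diverged)
  r <- rr$report
  # most neurons keep a receptive field through the release ramp
  expect_gt(mean(r$selectivity > 0.5), 0.8)
  expect_gt(stats::median(r$selectivity), 0.5)
  expect_gt(length(unique(r$preferred)), 1)
  expect_gt(r$within_mean, r$across_mean)
  expect_gt(r$bidir_within, r$bidir_across)
  # the thresholded adjacency keeps only the strong connections
  expect_true(all(r$adjacency == 0 | r$adjacency >= 0.03))
})

test_that("correlated pattern sequences strengthen the assembly structure", {
  # measured at the end of the disinhibition window, where the recurrent
  # structure is sharpest; independent sequences remove the co-activation
  # that drives within-group potentiation
  gap <- function(corr, seed) {
    mp <- multi_input_params(disinhibition_duration = 30,
                             release_ramp = 0.001)
    rr <- run_recurrent(params = mp,
                        rec = recurrent_params(n_post = 12,
                                               pattern_correlation = corr),
                        T_baseline = 5, T_post = 0.001, seed = seed)
    rr$report$within_mean - rr$report$across_mean
  }
  gaps <- vapply(1:3, function(s) c(gap(0.5, s), gap(0, s)), numeric(2))
  expect_gt(mean(gaps[1, ] - gaps[2, ]), 0)
})
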