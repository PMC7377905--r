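make_tc <- function(value, dt = 0.5) {
  tibble::tibble(time = seq_along(value) * dt - dt, value = value)
}

test_that("RT outlier exclusion implements the 2.5 SD rule", {
  tr <- tibble::tibble(rt = c(rep(1, 20), 1.2, 0.8, 5))
  kept <- filter_rt_outliers(tr)
  expect_equal(nrow(kept), 22)
  expect_equal(attr(kept, "excluded")$rt, 5)

  # zero SD: nothing excluded
  same <- filter_rt_outliers(tibble::tibble(rt = rep(0.7, 10)))
  expect_equal(nrow(same), 10)

  # infinite threshold: identity
  all_kept <- filter_rt_outliers(tr, threshold_sd = Inf)
  expect_equal(nrow(all_kept), nrow(tr))
  expect_error(filter_rt_outliers(tibble::tibble(rt = c(-1, 2))), "positive")
})

test_that("epoch extraction interpolates onto the oversampled grid", {
  # constant signal -> constant epochs (drift filter off)
  tc <- make_tc(rep(3, 400))
  ep <- extract_epochs(tc, onsets = c(50, 100), highpass_s = NULL)
  expect_equal(dim(ep$epochs), c(2, length(ep$time)))
  expect_equal(unique(as.vector(ep$epochs)), 3)
  expect_equal(range(ep$time), c(-2, 10), tolerance = 0.15)
  expect_equal(diff(ep$time)[1], 0.144)

  # impulse response: epoch peak at the HRF peak latency
  t_grid <- seq(0, 200, by = 0.25)
  sig <- hrf_double_gamma(t_grid - 60)
  ep2 <- extract_epochs(tibble::tibble(time = t_grid, value = sig),
                        onsets = 60, highpass_s = NULL)
  hrf_peak <- t_grid[which.max(hrf_double_gamma(t_grid))]
  expect_equal(ep2$time[which.max(ep2$epochs[1, ])], hrf_peak,
               tolerance = 0.2)

  # time equivariance: shifting onsets by +1 s shifts content by -1 s
  ep3 <- extract_epochs(tibble::tibble(time = t_grid, value = sig),
                        onsets = 61, highpass_s = NULL)
  expect_equal(ep3$time[which.max(ep3$epochs[1, ])], hrf_peak - 1,
               tolerance = 0.2)

  # epochs extending past the recording are dropped with a warning
  expect_warning(
    ep4 <- extract_epochs(tc, onsets = c(50, 198), highpass_s = NULL),
    "dropped")
  expect_equal(nrow(ep4$epochs), 1)
  expect_equal(ep4$dropped, 2L)
})

test_that("the drift filter removes slow components and keeps fast ones", {
  t_grid <- seq(0, 500, by = 0.5)
  slow <- sin(2 * pi * t_grid / 400) # period 400 s >> 128 s cutoff
  fast <- sin(2 * pi * t_grid / 20)
  filt <- dct_highpass(slow + fast, t_grid, cutoff_s = 128)
  expect_lt(sd(filt - fast), 0.2 * sd(fast))
})

test_that("pointwise regression recovers injected weights and matches OLS oracle", {
  n <- 120
  priv <- withr::with_seed(1, rnorm(n))
  noise <- withr::with_seed(2, matrix(rnorm(n * 10, sd = 0.3), n))
  ep <- structure(list(epochs = noise, time = seq(0, 4.5, by = 0.5),
                       onsets = seq_len(n), dropped = integer()),
                  class = "epoch_matrix")
  ep$epochs[, 4] <- ep$epochs[, 4] + 2 * priv # effect at one timepoint only
  bt <- pointwise_glm(ep, tibble::tibble(private = priv))
  b_priv <- bt$beta[bt$term == "private"]
  expect_equal(b_priv[4], 2, tolerance = 0.15)
  expect_lt(max(abs(b_priv[-4])), 0.15)

  # agreement with explicit normal equations at every timepoint
  X <- cbind(1, (priv - mean(priv)) / sd(priv))
  for (ti in c(1, 4, 9)) {
    expect_equal(b_priv[ti], oracle_ols(X, ep$epochs[, ti])[2],
                 tolerance = 1e-8)
  }

  # row-permutation invariance
  perm <- withr::with_seed(3, sample(n))
  ep_p <- ep; ep_p$epochs <- ep$epochs[perm, ]
  bt_p <- pointwise_glm(ep_p, tibble::tibble(private = priv[perm]))
  expect_equal(bt_p$beta, bt$beta, tolerance = 1e-10)

  expect_error(pointwise_glm(ep, tibble::tibble(p = priv[-1])), "align")
})

test_that("the PPI regression recovers seed-coupled effects and rejects misalignment", {
  n <- 150
  tp <- seq(0, 4.5, by = 0.5)
  set.seed(11)
  seed_act <- matrix(rnorm(n * length(tp)), n)
  priv <- rnorm(n); rep_conf <- rnorm(n)
  target <- matrix(rnorm(n * length(tp), sd = 0.3), n)
  # inject coupling seed x reported at late timepoints 8..10
  for (ti in 8:10) target[, ti] <- target[, ti] + 0.8 * seed_act[, ti] * rep_conf
  mk <- function(m) structure(list(epochs = m, time = tp,
                                   onsets = seq_len(n), dropped = integer()),
                              class = "epoch_matrix")
  pp <- ppi_glm(mk(target), mk(seed_act), priv, rep_conf)
  sr <- pp[pp$term == "seed:reported", ]
  expect_gt(min(sr$beta[8:10]), 0.5)
  expect_lt(max(abs(sr$beta[1:6])), 0.2)
  # the uninjected interactions stay in the null band
  sp <- pp[pp$term == "seed:private", ]
  expect_lt(max(abs(sp$beta)), 0.2)

  bad <- mk(seed_act[-1, , drop = FALSE])
  bad$onsets <- seq_len(n - 1)
  expect_error(ppi_glm(mk(target), bad, priv, rep_conf), "aligned")
})

test_that("group timepoint tests mask at the per-timepoint alpha", {
  grid <- seq(-2, 10, by = 0.5)
  zero <- tidyr::expand_grid(subject = 1:8, time = grid, term = "x")
  zero$beta <- 0
  gz <- group_timepoint_test(zero)
  expect_false(any(gz$significant))

  shifted <- zero
  shifted$beta <- 1 + withr::with_seed(4, rnorm(nrow(shifted), sd = 0.05))
  gs <- group_timepoint_test(shifted)
  expect_true(all(gs$significant))

  # type-I calibration: many null timepoints, rejection rate about alpha
  null <- tidyr::expand_grid(subject = 1:12, time = seq_len(2000), term = "x")
  null$beta <- withr::with_seed(5, rnorm(nrow(null)))
  gn <- group_timepoint_test(null)
  expect_lt(abs(mean(gn$significant) - 0.05), 0.012)
})
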