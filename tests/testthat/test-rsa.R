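test_that("shrinkage noise covariance is well conditioned and correct in limits", {
  # white noise, many samples: close to sigma^2 I
  R <- withr::with_seed(1, matrix(rnorm(4000 * 10, sd = 2), 4000))
  S <- noise_covariance(R)
  expect_equal(diag(S), rep(4, 10), tolerance = 0.3)
  off <- S[row(S) != col(S)]
  expect_lt(max(abs(off)), 0.3)

  # lambda = 1 gives exactly the diagonal target
  R2 <- withr::with_seed(2, matrix(rnorm(50 * 8), 50))
  S1 <- noise_covariance(R2, lambda = 1)
  expect_equal(unclass(S1) - diag(diag(S1)), matrix(0, 8, 8),
               ignore_attr = TRUE, tolerance = 1e-12)

  # positive definite even with fewer observations than voxels
  R3 <- withr::with_seed(3, matrix(rnorm(6 * 12), 6))
  S3 <- noise_covariance(R3)
  expect_gt(min(eigen(S3, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(noise_covariance(matrix(1, 1, 5)), "observation")
})

test_that("split-data RDM matches hand computation and brute force", {
  # degenerate: identical patterns everywhere -> all zero
  arr0 <- array(1, c(3, 4, 2))
  expect_equal(unclass(sdrdm(pattern_array(arr0, tibble::tibble(c = 1:4)))),
               matrix(0, 4, 4), ignore_attr = TRUE)

  # 2 runs, 2 conditions, 2 voxels, hand-set values, identity covariance
  arr <- array(0, c(2, 2, 2))
  arr[1, 1, ] <- c(1, 0); arr[1, 2, ] <- c(0, 1)
  arr[2, 1, ] <- c(2, 0); arr[2, 2, ] <- c(0, 2)
  pa <- pattern_array(arr, tibble::tibble(c = 1:2))
  m <- sdrdm(pa)
  # run 1 vs run 2 means: d(1,1)=1, d(1,2)=sqrt(1+4); run 2: d(1,1)=1 ...
  expect_equal(m[1, 1], 1)
  expect_equal(m[1, 2], mean(c(sqrt(1 + 4), sqrt(4 + 1))))

  # homogeneity: scaling patterns by c scales distances by |c|
  m3 <- sdrdm(pattern_array(arr * -3, tibble::tibble(c = 1:2)))
  expect_equal(unclass(m3), unclass(m) * 3, ignore_attr = TRUE)

  # brute-force double loop on random arrays, squared and unsquared
  for (s in 1:5) {
    arrr <- withr::with_seed(s, array(rnorm(4 * 6 * 5), c(4, 6, 5)))
    par <- pattern_array(arrr, tibble::tibble(c = 1:6))
    expect_equal(unclass(sdrdm(par)), oracle_sdrdm(arrr),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unclass(sdrdm(par, squared = TRUE)),
                 oracle_sdrdm(arrr, squared = TRUE),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # Mahalanobis distance with a known covariance: whitening by hand
  sigma <- matrix(c(2, 0.5, 0.5, 1), 2)
  paw <- pattern_array(arr, tibble::tibble(c = 1:2))
  mw <- sdrdm(paw, noise_cov = sigma, squared = TRUE)
  v <- arr[1, 1, ] - arr[2, 1, ]
  expect_equal(mw[1, 1],
               mean(c(
                 drop(t(arr[1, 1, ] - arr[2, 1, ]) %*% solve(sigma) %*%
                        (arr[1, 1, ] - arr[2, 1, ])),
                 drop(t(arr[2, 1, ] - arr[1, 1, ]) %*% solve(sigma) %*%
                        (arr[2, 1, ] - arr[1, 1, ]))
               )),
               tolerance = 1e-10)
})

test_that("EDI is off-diagonal minus diagonal mean with null expectation zero", {
  expect_equal(edi(matrix(5, 3, 3)), 0)
  m <- matrix(3, 4, 4); diag(m) <- 1
  expect_equal(edi(m), 2)
  expect_error(edi(matrix(1, 1, 1)), "2 conditions")

  # exchangeable (null) patterns: group-mean EDI within 2 SEs of 0
  edis <- vapply(1:28, function(s) {
    edi(sdrdm(generate_patterns(pattern_spec(n_voxels = 20), seed = s)))
  }, numeric(1))
  expect_lt(abs(mean(edis)), 2 * sd(edis) / sqrt(length(edis)))

  # permuting condition labels within each run destroys a positive EDI
  spec_sig <- pattern_spec(es_coherence = 0.6, es_context = 0.6,
                           n_voxels = 20)
  real <- numeric(20); perm <- numeric(20)
  for (s in 1:20) {
    pa <- generate_patterns(spec_sig, seed = 100 + s)
    real[s] <- edi(sdrdm(pa))
    shuf <- pa$patterns
    withr::with_seed(s, for (r in 1:dim(shuf)[1]) {
      shuf[r, , ] <- shuf[r, sample(dim(shuf)[2]), ]
    })
    perm[s] <- edi(sdrdm(pattern_array(shuf, pa$conditions)))
  }
  expect_gt(mean(real), 4 * sd(real) / sqrt(20))
  expect_lt(abs(mean(perm)), 3 * sd(perm) / sqrt(20))
})

test_that("EDI grows with the condition-separation of the generator", {
  ladder <- c(0, 0.3, 0.6, 1.2)
  mean_edi <- vapply(ladder, function(es) {
    mean(vapply(1:12, function(s) {
      edi(sdrdm(generate_patterns(
        pattern_spec(es_coherence = es, es_context = es, n_voxels = 20),
        seed = 1000 * es + s)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_edi) > 0))
})

test_that("sub-space collapse keeps the targeted factor's signal only", {
  pa <- generate_patterns(pattern_spec(es_coherence = 1), seed = 7)
  cK <- collapse_to_subspace(pa, "coherence")
  cC <- collapse_to_subspace(pa, "context")
  expect_equal(dim(cK$patterns)[2], 4)
  expect_equal(dim(cC$patterns)[2], 4)
  # linearity: collapsed pattern equals the marginal mean
  sel <- which(pa$conditions$coherence_level == 2)
  expect_equal(cK$patterns[1, 2, ],
               colMeans(matrix(pa$patterns[1, sel, ],
                               ncol = dim(pa$patterns)[3])),
               tolerance = 1e-12)

  # coherence-only signal: K sub-space discriminable, C not
  ediK <- ediC <- numeric(16)
  for (s in 1:16) {
    pas <- generate_patterns(pattern_spec(es_coherence = 0.8, n_voxels = 20),
                             seed = 200 + s)
    sp <- edi_by_space(pas)
    ediK[s] <- sp$edi[sp$space == "K"]
    ediC[s] <- sp$edi[sp$space == "C"]
  }
  expect_gt(mean(ediK), 4 * sd(ediK) / sqrt(16))
  expect_lt(abs(mean(ediC)), 3 * sd(ediC) / sqrt(16))

  expect_error(collapse_to_subspace(
    pattern_array(array(rnorm(24), c(2, 3, 4)), tibble::tibble(c = 1:3)),
    "coherence"), "labels")
})

test_that("one-tailed signed-rank inference uses the exact small-sample law", {
  # all positive, n = 10: p = 1 / 2^10
  res <- signrank_group_test(seq(0.1, 1, by = 0.1))
  expect_equal(res$p_value, 1 / 2^10, tolerance = 1e-12)
  expect_true(res$exact)

  # zeros are dropped
  res0 <- signrank_group_test(c(0, 0, seq(0.1, 1, by = 0.1)))
  expect_equal(res0$n, 10L)
  expect_equal(res0$p_value, res$p_value)

  # symmetric-about-zero samples: p about 0.5 on average
  ps <- vapply(1:200, function(s) {
    signrank_group_test(withr::with_seed(s, rnorm(15)))$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.08)

  expect_error(signrank_group_test(c(1, 2, 3)), "5 subjects")
  expect_error(signrank_group_test(rep(0, 8)), "zero")
})
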