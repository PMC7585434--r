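test_that("detrending returns least-squares residuals", {
  expect_equal(detrend_series(c(2, 4, 6, 8)), rep(0, 4), tolerance = 1e-12)
  expect_equal(detrend_series(c(5, 5, 5)), rep(0, 3), tolerance = 1e-12)
  expect_equal(detrend_series(c(1, 3, 2)), c(-0.5, 1, -0.5),
               tolerance = 1e-12)
  expect_error(detrend_series(c(1, 2)), "insufficient")
})

test_that("temporal moments reproduce hand-computed covariances", {
  cov_arr <- array(0, dim = c(2, 2, 3),
                   dimnames = list(c("a", "b"), 1:2, 1:3))
  cov_arr[1, 1, ] <- c(1, 2, 3); cov_arr[2, 2, ] <- c(1, 3, 2)
  biom <- rbind(c(1, 2, 3), c(1, 3, 2))
  tensor <- community_tensor(cov_arr, biom, "s", "Control")
  mo <- temporal_moments(tensor)
  expect_equal(unname(mo$mu), c(2, 2))
  expect_equal(unname(mo$v), rbind(c(1, 0.5), c(0.5, 1)), tolerance = 1e-12)
  # constant series carry zero variance; detrended linear series too
  cov_arr[1, 2, ] <- 7
  t2 <- community_tensor(cov_arr, biom, "s", "Control")
  mo2 <- temporal_moments(t2)
  expect_equal(sum(abs(mo2$w[, 3])), 0)          # constant series: zero column
  expect_equal(mo2$w[1, 4], 0.5)                 # cov((1,2,3), (1,3,2))
  lin <- community_tensor(cov_arr, rbind(c(2, 4, 6), c(1, 2, 3)), "s", "Control")
  expect_equal(unname(diag(temporal_moments(lin, detrend = TRUE)$v)), c(0, 0),
               tolerance = 1e-12)
})

test_that("the partition reproduces the hand-worked two-subplot example", {
  cov_arr <- array(0, dim = c(2, 2, 3),
                   dimnames = list(c("a", "b"), 1:2, 1:3))
  cov_arr[1, 1, ] <- c(1, 2, 3); cov_arr[2, 2, ] <- c(1, 3, 2)
  biom <- rbind(c(1, 2, 3), c(1, 3, 2))  # biomass = community cover
  st <- stability_partition(temporal_moments(
    community_tensor(cov_arr, biom, "s", "Control")))
  expect_equal(st$species_asynchrony, 1, tolerance = 1e-12)
  expect_equal(st$alpha_stability, 2, tolerance = 1e-12)
  expect_equal(st$spatial_asynchrony, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(st$gamma_stability, 4 / sqrt(3), tolerance = 1e-12)
  expect_equal(st$species_stability, 2, tolerance = 1e-12)
})

test_that("perfect within-subplot compensation flags infinite asynchrony", {
  cov_arr <- array(0, dim = c(2, 2, 3),
                   dimnames = list(c("a", "b"), 1:2, 1:3))
  for (k in 1:2) { cov_arr[1, k, ] <- c(1, 2, 3); cov_arr[2, k, ] <- c(3, 2, 1) }
  biom <- rbind(c(100, 120, 90), c(100, 90, 130))
  st <- stability_partition(temporal_moments(
    community_tensor(cov_arr, biom, "s", "Control")))
  expect_true(is.infinite(st$species_asynchrony))
  expect_true("species_asynchrony" %in% st$flags)
})

test_that("log transform maps flagged infinities to NA with a count", {
  expect_equal(as.numeric(log_transform_set(1)), 0)
  expect_equal(as.numeric(log_transform_set(exp(1))), 1)
  expect_warning(out <- log_transform_set(c(2, Inf, 0)), "2 ")
  expect_equal(attr(out, "dropped"), 2)
  expect_equal(is.na(out), c(FALSE, TRUE, TRUE))
  expect_equal(as.numeric(log_transform_set(100, base = "log10")), 2)
})

test_that("multiplicative identities hold on random tensors", {
  set.seed(101)
  for (i in 1:100) {
    tensor <- random_tensor(S = sample(2:6, 1), K = sample(2:3, 1),
                            T_ = sample(3:8, 1))
    for (dt in c(FALSE, TRUE)) {
      st <- stability_partition(temporal_moments(tensor, dt))
      expect_equal(st$alpha_stability * st$spatial_asynchrony,
                   st$gamma_stability, tolerance = 1e-10)
      expect_equal(st$species_stability * st$species_asynchrony,
                   cover_alpha_stability(tensor, dt), tolerance = 1e-10)
      expect_gte(st$species_asynchrony, 1 - 1e-12)
      expect_gte(st$spatial_asynchrony, 1 - 1e-12)
    }
  }
})

test_that("all five statistics match the brute-force oracle", {
  set.seed(55)
  for (i in 1:40) {
    tensor <- random_tensor(S = sample(2:3, 1), K = 2, T_ = sample(3:5, 1))
    dt <- i %% 2 == 0
    st <- stability_partition(temporal_moments(tensor, dt))
    or <- brute_stability(tensor, dt)
    for (v in names(or))
      expect_equal(st[[v]], or[[v]], tolerance = 1e-10, label = v)
  }
})

test_that("constructed synchronous tensors sit exactly at the bound", {
  set.seed(77)
  for (i in 1:10) {
    st <- stability_partition(temporal_moments(synchronous_tensor()))
    expect_equal(st$species_asynchrony, 1, tolerance = 1e-12)
    expect_equal(st$spatial_asynchrony, 1, tolerance = 1e-12)
  }
})

test_that("a shared linear trend is removed by detrending", {
  set.seed(31)
  tensor <- random_tensor(S = 3, K = 2, T_ = 6)
  trend <- 5 * seq_len(6)
  shifted_cover <- tensor$cover
  for (i in 1:3) for (k in 1:2) shifted_cover[i, k, ] <- tensor$cover[i, k, ] + trend
  shifted <- community_tensor(shifted_cover,
                              tensor$biomass + rep(trend, each = 2),
                              "s1", "Control")
  st0 <- stability_partition(temporal_moments(tensor, detrend = TRUE))
  st1 <- stability_partition(temporal_moments(shifted, detrend = TRUE))
  # denominators are unchanged, so the asynchrony ratios agree exactly
  expect_equal(st1$species_asynchrony, st0$species_asynchrony,
               tolerance = 1e-10)
  expect_equal(st1$spatial_asynchrony, st0$spatial_asynchrony,
               tolerance = 1e-10)
})
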