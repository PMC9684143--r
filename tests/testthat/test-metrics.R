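test_that("matching handles identity, spurious points and empty sets", {
  tr <- cbind(c(0, 10, 20), c(0, 0, 0))
  est <- data.frame(x = tr[, 1], y = tr[, 2], sigma_x = 1, sigma_y = 1)
  m <- match_emitters(tr, est)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(m$pairs$distance, rep(0, 3))
  expect_equal(jaccard(m), 1)
  expect_equal(rmse(m), 0)
  # one far spurious estimate stays unmatched
  est2 <- rbind(est, data.frame(x = 500, y = 500, sigma_x = 1, sigma_y = 1))
  m2 <- match_emitters(tr, est2)
  expect_equal(nrow(m2$pairs), 3)
  expect_equal(jaccard(m2), 3 / 4)
  # both sets empty: vacuous perfection
  m0 <- match_emitters(tr[0, , drop = FALSE], est[0, ], cutoff = 1)
  expect_equal(jaccard(m0), 1)
  expect_true(is.na(rmse(m0)))
})

test_that("assignment equals permutation brute force up to n = 6", {
  set.seed(81)
  for (rep in 1:12) {
    nt <- sample(2:6, 1); ne <- sample(2:6, 1)
    tr <- cbind(runif(nt, 0, 20), runif(nt, 0, 20))
    est <- data.frame(x = runif(ne, 0, 20), y = runif(ne, 0, 20),
                      sigma_x = 1, sigma_y = 1)
    cutoff <- runif(1, 4, 15)
    m <- match_emitters(tr, est, cutoff = cutoff)
    b <- match_brute(tr, as.matrix(est[, 1:2]), cutoff)
    expect_equal(nrow(m$pairs), nrow(b))
    expect_equal(sum(m$pairs$distance), sum(b$distance), tolerance = 1e-9)
  }
})

test_that("jaccard and rmse follow their definitions", {
  fake <- structure(list(pairs = data.frame(true = 1:6, est = 1:6,
                                            distance = c(3, 4, rep(0, 4))),
                         n_true = 8, n_est = 8, cutoff = 10),
                    class = "match_result")
  expect_equal(jaccard(fake), 6 / (6 + 2 + 2))
  two <- structure(list(pairs = data.frame(true = 1:2, est = 1:2,
                                           distance = c(3, 4)),
                        n_true = 2, n_est = 2, cutoff = 10),
                   class = "match_result")
  expect_equal(rmse(two), sqrt(12.5))
  # relabeling the emitters does not change JAC
  set.seed(82)
  tr <- cbind(runif(5, 0, 10), runif(5, 0, 10))
  est <- data.frame(x = tr[, 1] + rnorm(5, 0, 0.1),
                    y = tr[, 2] + rnorm(5, 0, 0.1),
                    sigma_x = 0.5, sigma_y = 0.5)
  j1 <- jaccard(match_emitters(tr, est))
  prm <- sample(5)
  j2 <- jaccard(match_emitters(tr[prm, ], est[sample(5), ]))
  expect_equal(j1, j2)
})

test_that("three-sigma cutoff rule is per-estimate", {
  tr <- cbind(c(0, 100), c(0, 0))
  est <- data.frame(x = c(4, 104), y = c(0, 0),
                    sigma_x = c(2, 0.5), sigma_y = c(2, 0.5))
  m <- match_emitters(tr, est, cutoff_rule = "three_sigma", cutoff = 10)
  # first pair: 4 <= 3*2 kept; second: 4 > 3*0.5 dropped
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$est, 1)
})

test_that("radial accuracy prediction is a Rayleigh density", {
  sigma <- 2
  r <- seq(0.01, 12, by = 0.01)
  f <- r / sigma^2 * exp(-r^2 / (2 * sigma^2))
  expect_equal(r[which.max(f)], sigma, tolerance = 0.02)   # peak at sigma
  expect_equal(sum(f) * 0.01, 1, tolerance = 1e-3)         # unit area
  set.seed(83)
  d <- sqrt(rnorm(5000, 0, sigma)^2 + rnorm(5000, 0, sigma)^2)
  ks <- stats::ks.test(d, function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
  ad <- accuracy_distribution(d, sigma)
  expect_equal(sum(ad$curve) * mean(diff(ad$r)),
               sum(ad$hist$counts) * mean(diff(ad$hist$breaks)),
               tolerance = 1e-6)  # equal areas after scaling
})

test_that("nearest-neighbor distances match brute force", {
  set.seed(84)
  p <- cbind(runif(200, 0, 50), runif(200, 0, 50))
  d <- nnd_distribution(p)
  dm <- as.matrix(dist(p)); diag(dm) <- Inf
  expect_equal(d, unname(apply(dm, 1, min)), tolerance = 1e-12)
})

test_that("Hopkins statistic separates random, clustered and regular", {
  set.seed(85)
  unifp <- cbind(runif(2000), runif(2000))
  h <- hopkins(unifp, m = 10, iters = 400)
  expect_lt(abs(mean(h) - 0.5), 0.03)
  clus <- cbind(rnorm(2000, 0.5, 0.01), rnorm(2000, 0.5, 0.01))
  expect_gt(mean(hopkins(clus, m = 10, iters = 100)), 0.9)
  g <- as.matrix(expand.grid(seq(0, 1, length.out = 45),
                             seq(0, 1, length.out = 45)))
  expect_lt(mean(hopkins(g, m = 10, iters = 100)), 0.5)
})

test_that("Hopkins under uniformity follows Beta(m, m)", {
  set.seed(86)
  unifp <- cbind(runif(4000), runif(4000))
  h <- hopkins(unifp, m = 10, iters = 1000)
  ks <- stats::ks.test(h, function(q) pbeta(q, 10, 10))
  expect_gt(ks$p.value, 0.01)
})
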