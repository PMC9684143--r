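fake_chain <- function(K_per_sample, mu_list, xi = 50, n_loc = 50) {
  # hand-built chain object: mu_list[[s]] is a K x 2 matrix for sample s
  em <- do.call(rbind, lapply(seq_along(mu_list), function(s) {
    m <- mu_list[[s]]
    data.frame(sample = s, x = m[, 1], y = m[, 2], ax = 0, ay = 0,
               n_loc = n_loc)
  }))
  structure(list(K = K_per_sample, xi = rep(xi, length(K_per_sample)),
                 emitters = em, accept = NULL, box = c(-50, 50, -50, 50),
                 N = 100L, config = sampler_config(n_samples =
                                                     length(K_per_sample),
                                                   lambda = xi)),
            class = "locfuse_chain")
}

test_that("single-emitter chains recover jitter mean and spread", {
  set.seed(41)
  n <- 500
  mu <- lapply(seq_len(n), function(s) cbind(rnorm(1, 10, 0.8),
                                             rnorm(1, -5, 0.8)))
  ch <- fake_chain(rep(1L, n), mu)
  m <- mapn_extract(ch)
  expect_equal(m$K_map, 1L)
  expect_equal(m$emitters$x, 10, tolerance = 0.15)
  expect_equal(m$emitters$y, -5, tolerance = 0.15)
  expect_equal(m$emitters$sigma_x, 0.8, tolerance = 0.15)
})

test_that("two stable emitters give two clusters at their means", {
  set.seed(42)
  n <- 400
  mu <- lapply(seq_len(n), function(s)
    rbind(c(rnorm(1, 0, 0.3), rnorm(1, 0, 0.3)),
          c(rnorm(1, 30, 0.3), rnorm(1, 30, 0.3)))[sample(2), , drop = FALSE])
  ch <- fake_chain(rep(2L, n), mu)
  m <- mapn_extract(ch)
  expect_equal(m$K_map, 2L)
  ord <- order(m$emitters$x)
  expect_equal(m$emitters$x[ord], c(0, 30), tolerance = 0.1)
  expect_equal(m$emitters$n_samples, c(n, n))
})

test_that("modal-K ties break toward the smaller model", {
  mu1 <- lapply(1:10, function(s) cbind(0, 0))
  mu2 <- lapply(1:10, function(s) rbind(c(0, 0), c(20, 20)))
  ch <- fake_chain(c(rep(1L, 10), rep(2L, 10)), c(mu1, mu2))
  expect_equal(mapn_extract(ch)$K_map, 1L)
})

test_that("sample-aware refinement survives unequal cluster widths", {
  # one broad posterior cluster next to two tight ones: pooled k-means is
  # prone to splitting the broad one; the one-member-per-sample constraint
  # must keep exactly one center per true emitter
  set.seed(43)
  n <- 600
  mu <- lapply(seq_len(n), function(s)
    rbind(c(rnorm(1, 0, 2.5), rnorm(1, 0, 2.5)),
          c(rnorm(1, 10, 0.3), rnorm(1, 0, 0.3)),
          c(rnorm(1, 15, 0.3), rnorm(1, 5, 0.3)))[sample(3), , drop = FALSE])
  ch <- fake_chain(rep(3L, n), mu)
  m <- mapn_extract(ch)
  expect_equal(m$K_map, 3L)
  expect_equal(sort(m$emitters$n_samples), c(n, n, n))
  ord <- order(m$emitters$x)
  expect_equal(m$emitters$x[ord], c(0, 10, 15), tolerance = 0.4)
})

test_that("posterior image is a normalized 2-D histogram of the chain", {
  spec <- render_spec(1, c(-5, 45, -5, 45))
  # fixed single position -> all mass in one pixel
  ch1 <- fake_chain(rep(1L, 50), lapply(1:50, function(s) cbind(10.5, 20.5)))
  img1 <- posterior_image(ch1, spec)
  expect_equal(sum(img1), 1)
  expect_equal(max(img1), 1)
  # alternation between two positions -> 0.5 each
  ch2 <- fake_chain(rep(1L, 50),
                    lapply(1:50, function(s)
                      cbind(c(10.5, 30.5)[1 + s %% 2], 20.5)))
  img2 <- posterior_image(ch2, spec)
  expect_equal(sort(img2[img2 > 0]), c(0.5, 0.5))
  # total mass equals the mean K of the chain
  set.seed(44)
  Ks <- sample(1:3, 50, replace = TRUE)
  ch3 <- fake_chain(Ks, lapply(Ks, function(K)
    cbind(runif(K, 0, 40), runif(K, 0, 40))))
  expect_equal(sum(posterior_image(ch3, spec)), mean(Ks))
  # second moment of scattered samples matches the sample variance
  set.seed(45)
  xs <- rnorm(2000, 20, 3)
  ch4 <- fake_chain(rep(1L, 2000), lapply(xs, function(v) cbind(v, 20)))
  img4 <- posterior_image(ch4, spec)
  xc <- seq(-4.5, 44.5, by = 1)
  mass <- colSums(img4)
  m1 <- sum(xc * mass) / sum(mass)
  v1 <- sum((xc - m1)^2 * mass) / sum(mass)
  expect_equal(v1, var(xs) + 1 / 12, tolerance = 0.5)  # binning adds 1/12
})
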