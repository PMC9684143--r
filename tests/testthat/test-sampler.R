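make_cluster_set <- function(n, center = c(0, 0), sigma = 2, seed = 1) {
  set.seed(seed)
  localizations(rnorm(n, center[1], sigma), rnorm(n, center[2], sigma),
                sigma, frame = seq_len(n) - 1L)
}

test_that("chains are reproducible and translation-equivariant", {
  s <- make_cluster_set(40, sigma = 2, seed = 3)
  cfg <- sampler_config(n_samples = 300, lambda = 40)
  set.seed(11); c1 <- run_chain(s, cfg, box = c(-10, 10, -10, 10))
  set.seed(11); c2 <- run_chain(s, cfg, box = c(-10, 10, -10, 10))
  expect_identical(c1$K, c2$K)
  expect_identical(c1$emitters, c2$emitters)
  # shifting data and box shifts every position draw by the same offset
  s3 <- s; s3$x <- s$x + 100; s3$y <- s$y - 50
  class(s3) <- class(s)
  set.seed(11); c3 <- run_chain(s3, cfg, box = c(90, 110, -60, -40))
  expect_identical(c1$K, c3$K)
  expect_equal(c3$emitters$x, c1$emitters$x + 100, tolerance = 1e-9)
  expect_equal(c3$emitters$y, c1$emitters$y - 50, tolerance = 1e-9)
})

test_that("Move is always accepted and its draws match the conditional", {
  # a single emitter with known allocations: mu | Z is Gaussian with
  # inverse-variance mean and variance
  s <- localizations(c(-1, 1), c(0.5, -0.5), 2, frame = c(0, 1))
  cfg <- sampler_config(n_samples = 4000, lambda = 2,
                        jump_probs = c(1, 0, 0, 0))  # Move only
  set.seed(4)
  ch <- run_chain(s, cfg, box = c(-20, 20, -20, 20))
  expect_equal(unname(ch$accept["move", "accepted"]),
               unname(ch$accept["move", "proposed"]))
  expect_true(all(ch$K == 1))
  # conditional: mean 0, sd 2/sqrt(2) = sqrt(2) per axis
  expect_equal(mean(ch$emitters$x), 0, tolerance = 4 * sqrt(2) / sqrt(4000))
  expect_equal(stats::sd(ch$emitters$x), sqrt(2), tolerance = 0.05)
  expect_equal(stats::sd(ch$emitters$y), sqrt(2), tolerance = 0.05)
})

test_that("with drift the Move conditional matches weighted least squares", {
  set.seed(6)
  n <- 60
  tt <- seq(0, 1, length.out = n)
  sig <- runif(n, 1, 3)
  x <- 5 + 8 * tt + rnorm(n, 0, sig)
  s <- localizations(x, rnorm(n, 0, sig), sig,
                     frame = as.integer(round(tt * (n - 1))))
  cfg <- sampler_config(n_samples = 6000, lambda = n, drift = TRUE,
                        drift_prior_sd = 50, jump_probs = c(1, 0, 0, 0))
  set.seed(7)
  ch <- run_chain(s, cfg, box = c(-30, 40, -30, 30), t_range = c(0, n - 1))
  # WLS oracle with the same zero-mean slope prior
  w <- 1 / sig^2
  X <- cbind(1, tt)
  P <- t(X) %*% (w * X) + diag(c(0, 1 / 50^2))
  m <- solve(P, t(X) %*% (w * x))
  expect_equal(mean(ch$emitters$x), m[1], tolerance = 0.1)
  expect_equal(mean(ch$emitters$ax), m[2], tolerance = 0.25)
  expect_equal(stats::sd(ch$emitters$ax), sqrt(solve(P)[2, 2]),
               tolerance = 0.1)
})

test_that("posterior over K matches exhaustive enumeration on toy data", {
  # three localizations, two spatial groups; all K in {1, 2, 3} enumerated
  s <- localizations(c(-3, -2.5, 3), c(0, 0.5, 0), 1.5, frame = 0:2)
  box <- c(-8, 8, -4, 4)
  lambda <- 1.5
  p_oracle <- enumerate_K_posterior(s, lambda, box)
  cfg <- sampler_config(n_samples = 30000, n_burnin = 3000, lambda = lambda)
  set.seed(12)
  ch <- run_chain(s, cfg, box = box)
  for (K in 1:3) {
    ind <- as.numeric(ch$K == K)
    se <- max(batch_se(ind), 1e-3)
    expect_lt(abs(mean(ind) - p_oracle[K]), 3 * se + 0.01)
  }
})

test_that("coincident-emitter allocations follow the documented conditional", {
  # two emitters forced at the same spot: allocation counts n1 are
  # Binomial(N, 1/2) under the uniform allocation prior (verified against
  # full enumeration of the 2^N labellings with the likelihood equal across
  # them)
  s <- localizations(rnorm(6, 0, 0.5), rnorm(6, 0, 0.5), 2, frame = 0:5)
  box <- c(-6, 6, -6, 6)
  p_oracle <- enumerate_K_posterior(s, 3, box)  # sanity: K=2 is explored
  cfg <- sampler_config(n_samples = 20000, n_burnin = 2000, lambda = 3)
  set.seed(13)
  ch <- run_chain(s, cfg, box = box, store_z = TRUE)
  sel <- ch$K == 2
  expect_gt(sum(sel), 2000)  # enough K=2 visits for the comparison
  n1 <- rowSums(ch$z[sel, , drop = FALSE] == 1)
  # compare against enumeration restricted to K=2: distribution of n1
  z_all <- surjective_allocations(6, 2)
  lp <- apply(z_all, 1, function(z) {
    sum(vapply(1:2, function(k) {
      ii <- which(z == k)
      log_gauss_prod_integral(s$x[ii], s$sigma_x[ii], box[1], box[2]) +
        log_gauss_prod_integral(s$y[ii], s$sigma_y[ii], box[3], box[4])
    }, numeric(1)))
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  p_n1 <- vapply(1:5, function(v) sum(w[rowSums(z_all == 1) == v]), numeric(1))
  emp <- vapply(1:5, function(v) mean(n1 == v), numeric(1))
  for (v in 1:5)
    expect_lt(abs(emp[v] - p_n1[v]), 3 * batch_se(as.numeric(n1 == v)) + 0.03)
})

test_that("hierarchical mean update matches the conjugate closed form", {
  # counts {50,48,52,50}: lambda | counts ~ Gamma(eta + N, K + eta/gamma)
  # in the total-count model; check both the Gibbs and the Metropolis samplers
  set.seed(21)
  scn <- sim_scene(cbind(c(0, 40, 80, 120), 0), lambda = 50, n_frames = 200)
  sim <- simulate_blinks(scn)
  N <- nrow(sim$set)
  for (sampler in c("gibbs", "mh")) {
    cfg <- sampler_config(n_samples = 8000, n_burnin = 2000,
                          xi_prior_eta = 1, xi_prior_gamma = 5,
                          xi_sampler = sampler, lambda_init = 40)
    set.seed(22)
    ch <- run_chain(sim$set, cfg, box = c(-20, 140, -20, 20))
    sel <- ch$K == 4
    post_mean <- (1 + N) / (4 + 1 / 5)
    post_sd <- sqrt(1 + N) / (4 + 1 / 5)
    expect_equal(mean(ch$xi[sel]), post_mean, tolerance = 4 * post_sd)
    expect_equal(stats::sd(ch$xi[sel]), post_sd, tolerance = 0.5 * post_sd)
  }
  # fixed mode never changes lambda
  cfgf <- sampler_config(n_samples = 500, lambda = 50)
  set.seed(23)
  chf <- run_chain(sim$set, cfgf, box = c(-20, 140, -20, 20))
  expect_true(all(chf$xi == 50))
})

test_that("modal K identifies well-separated clusters", {
  set.seed(31)
  scn <- sim_scene(rbind(c(0, 0), c(60, 0)), lambda = 50, n_frames = 100)
  sim <- simulate_blinks(scn)
  cfg <- sampler_config(n_samples = 1500, lambda = 50)
  set.seed(32)
  ch <- run_chain(sim$set, cfg)
  tab <- table(ch$K)
  expect_equal(as.integer(names(tab)[which.max(tab)]), 2L)
  # one tight cluster -> modal K 1
  s1 <- make_cluster_set(50, sigma = 2, seed = 33)
  set.seed(34)
  ch1 <- run_chain(s1, sampler_config(n_samples = 1500, lambda = 50))
  tab1 <- table(ch1$K)
  expect_equal(as.integer(names(tab1)[which.max(tab1)]), 1L)
})

test_that("empty input yields an explicit empty chain", {
  s <- localizations(numeric(0), numeric(0), numeric(0))
  ch <- run_chain(s, sampler_config(n_samples = 10, lambda = 5),
                  box = c(0, 1, 0, 1))
  expect_equal(length(ch$K), 0)
  expect_equal(mapn_extract(ch)$K_map, 0L)
})

test_that("sampler_config validates jump probabilities", {
  expect_error(sampler_config(jump_probs = c(0.5, 0.5, 0.5, 0.5)))
  expect_error(sampler_config(lambda = -1))
})
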