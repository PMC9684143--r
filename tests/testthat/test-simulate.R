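test_that("localization precision follows sigma_psf/sqrt(I)", {
  set.seed(61)
  scn <- sim_scene(cbind(0, 0), lambda = 400, mean_photons = 1800,
                   sigma_psf = 120, n_frames = 100)
  sim <- simulate_blinks(scn)
  expect_equal(sim$set$sigma_x, 120 / sqrt(sim$set$photons))
  # I = 1800 exactly gives sigma = 120/sqrt(1800) ~ 2.828 nm
  expect_equal(120 / sqrt(1800), 2.8284, tolerance = 1e-4)
  # K-S: sigma should follow the sigma_psf/sqrt(Exp(1800)) law
  set.seed(62)
  scn2 <- sim_scene(cbind(0, 0), lambda = 10000, n_frames = 100)
  s2 <- simulate_blinks(scn2)$set
  ks <- stats::ks.test(s2$sigma_x, function(q) 1 - pexp((120 / q)^2, 1 / 1800))
  expect_gt(ks$p.value, 0.01)
})

test_that("blink counts and position noise match their models", {
  set.seed(63)
  K <- 400
  scn <- sim_scene(cbind(seq_len(K) * 100, 0), lambda = 50, n_frames = 100)
  sim <- simulate_blinks(scn)
  counts <- tabulate(sim$emitter, nbins = K)
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / K))
  # residual spread matches the reported precision (standardized residuals)
  resx <- (sim$set$x - scn$positions[sim$emitter, 1]) / sim$set$sigma_x
  expect_lt(abs(sd(resx) - 1), 3 / sqrt(2 * length(resx)))
})

test_that("ring, dimer, line and cross geometries are exact", {
  r8 <- sim_8mer(10)
  expect_equal(nrow(r8$positions), 8)
  d <- as.matrix(dist(r8$positions))
  nn <- unname(apply(d + diag(Inf, 8), 1, min))
  expect_equal(nn, rep(2 * 10 * sin(pi / 8), 8))        # ~0.76 R
  expect_equal(2 * sin(pi / 8), 0.7654, tolerance = 1e-4)

  dm <- sim_dimer(5)
  expect_equal(nrow(dm$positions), 2)
  expect_equal(as.numeric(dist(dm$positions)), 5)

  lp <- sim_line_pair(6, length = 100, n_per_line = 70)
  expect_equal(nrow(lp$positions), 140)
  expect_equal(sort(unique(round(lp$positions[, 2], 9))), c(-3, 3))
  expect_true(all(abs(lp$positions[, 1]) <= 50))

  cr <- sim_cross(5, arm_length = 100)
  expect_equal(nrow(cr$positions), 40)
  on_h <- cr$positions[cr$positions[, 2] == 0, 1]
  expect_equal(min(diff(sort(on_h[on_h > 0]))), 5)
  expect_false(any(cr$positions[, 1] == 0 & cr$positions[, 2] == 0))
})

test_that("density fields hit the 1/(2 sqrt(rho)) neighbor law", {
  # expected NN distances: 15.8 nm at 1000/um^2, 5 nm at 10000, 3.8 at 17000
  expect_equal(1000 / (2 * sqrt(1000)), 15.81, tolerance = 0.01)
  expect_equal(1000 / (2 * sqrt(10000)), 5)
  expect_equal(1000 / (2 * sqrt(17000)), 3.835, tolerance = 0.01)
  set.seed(64)
  nn <- unlist(lapply(1:8, function(i) {
    f <- sim_density_field(10000, area = c(0, 500, 0, 500))
    nnd_distribution(f$positions)
  }))
  # boundary-free expectation holds in the field interior; 3 SE tolerance
  expect_lt(abs(mean(nn) - 5), 3 * sd(nn) / sqrt(length(nn)) + 0.15)
  expect_equal(nrow(sim_density_field(10000,
                                      area = c(0, 500, 0, 500))$positions),
               2500)
})

test_that("dSTORM kinetics give geometric blink counts", {
  set.seed(65)
  scn <- sim_scene(cbind(seq_len(2000), 0), lambda = 1, n_frames = 1e5,
                   k_on = 2e-4, k_off = 5e-2, k_b = 5e-2)
  ev <- sim_dstorm_kinetics(scn)
  counts <- lengths(ev)
  # activation: 1 - exp(-k_on * n_frames) > 99%
  expect_gt(mean(counts > 0), 0.99)
  # geometric with mean (k_off+k_b)/k_b = 2 among bleached fluorophores
  m <- mean(counts[counts > 0])
  se <- sd(counts[counts > 0]) / sqrt(sum(counts > 0))
  expect_lt(abs(m - 2), 3 * se)
  # near-instant bleaching yields exactly one blink
  scn2 <- sim_scene(cbind(1:200, 0), lambda = 1, n_frames = 1e5,
                    k_on = 2e-4, k_off = 5e-2, k_b = 1e4)
  c2 <- lengths(sim_dstorm_kinetics(scn2))
  expect_true(all(c2[c2 > 0] == 1))
})

test_that("drift is linear in normalized time and recoverable", {
  scn <- sim_scene(cbind(c(0, 100), c(0, 0)), lambda = 200, n_frames = 1000)
  # zero velocity leaves positions untouched
  set.seed(66); base <- simulate_blinks(scn)
  scn0 <- apply_drift(scn, velocity = 0)
  set.seed(66); drifted0 <- simulate_blinks(scn0)
  expect_equal(drifted0$set$x, base$set$x)
  # fixed vector: regression of noiseless positions on t returns the vector
  scn1 <- apply_drift(scn, vector = c(8, -4))
  scn1$sigma_psf <- 1e-6  # effectively noiseless
  set.seed(67)
  sim <- simulate_blinks(scn1)
  tt <- sim$set$frame / scn1$n_frames
  for (k in 1:2) {
    sel <- sim$emitter == k
    co <- coef(lm(sim$set$x[sel] ~ tt[sel]))
    expect_equal(unname(co[2]), 8, tolerance = 1e-3)
  }
  # random directions have the requested magnitude
  set.seed(68)
  scn2 <- apply_drift(scn, velocity = 2)
  expect_equal(sqrt(rowSums(scn2$drift^2)), c(2, 2))
})

test_that("generators are seed-reproducible", {
  set.seed(70); a <- simulate_blinks(sim_8mer(10, lambda = 20))
  set.seed(70); b <- simulate_blinks(sim_8mer(10, lambda = 20))
  expect_identical(a$set, b$set)
  expect_identical(a$emitter, b$emitter)
})
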