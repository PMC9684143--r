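test_that("relative intensity filter removes events above factor x mean", {
  s <- localizations(1:4, 1:4, 1, photons = c(1000, 1000, 1000, 5000))
  r <- intensity_filter(s, "relative", factor = 2)   # mean 2000, cutoff 4000
  expect_equal(nrow(r), 3)
  expect_equal(attr(r, "removed"), 1L)
  expect_false(5000 %in% r$photons)
  # equal intensities: nothing removed
  s2 <- localizations(1:3, 1:3, 1, photons = rep(800, 3))
  expect_equal(nrow(intensity_filter(s2, "relative", factor = 2)), 3)
  # absolute cutoff
  s3 <- localizations(1:5, 1:5, 1, photons = c(500, 2900, 3000, 3100, 9000))
  r3 <- intensity_filter(s3, "absolute", cutoff = 3000)
  expect_equal(r3$photons, c(500, 2900, 3000))
  expect_error(intensity_filter(localizations(1, 1, 1), "relative"), "photons")
})

test_that("psi counts neighbors within 3 median precisions, self excluded", {
  # two points 1 nm apart, all sigmas 5/3 -> radius 5
  s <- localizations(c(0, 1), c(0, 0), 5 / 3)
  r <- compute_psi(s)
  expect_equal(r$radius, 5)
  expect_equal(r$psi, c(1L, 1L))
  expect_equal(compute_psi(localizations(0, 0, 1))$psi, 0L)
  s2 <- localizations(c(0, 100), c(0, 0), 1)
  expect_equal(compute_psi(s2)$psi, c(0L, 0L))
})

test_that("psi agrees with all-pairs brute force", {
  set.seed(5)
  n <- 300
  s <- localizations(runif(n, 0, 100), runif(n, 0, 100), runif(n, 0.5, 3))
  r <- compute_psi(s)
  expect_equal(r$psi, psi_brute(s$x, s$y, r$radius))
})

test_that("valley threshold separates a labelled bimodal mixture", {
  set.seed(7)
  psi <- c(rpois(60, 2), rpois(250, 40))
  lab <- rep(c(TRUE, FALSE), c(60, 250))  # TRUE = spurious mode
  thr <- find_valley_threshold(psi)
  expect_gt(thr, 0)
  # brute-force oracle: the integer cut minimizing misassignment of the
  # generating mixture labels
  mis <- vapply(0:max(psi), function(td) sum(psi < td & !lab) + sum(psi >= td & lab),
                numeric(1))
  best <- which(mis == min(mis)) - 1L
  # the valley must classify nearly as well as the optimal cut
  expect_lte(mis[thr + 1L], min(mis) + 0.02 * length(psi))
  expect_gte(thr, min(best) - 6L)
  expect_lte(thr, max(best) + 6L)
})

test_that("degenerate psi histograms disable the filter", {
  expect_warning(t1 <- find_valley_threshold(rpois(300, 30)), "valley")
  expect_identical(t1, 0L)
  expect_identical(suppressWarnings(find_valley_threshold(rep(5L, 50))), 0L)
})

test_that("nnd filter removes isolated localizations", {
  set.seed(8)
  # a dense 8-mer cloud plus isolated spurious points
  sc <- sim_8mer(10, lambda = 40, n_frames = 100)
  dense <- simulate_blinks(sc)$set
  spur <- localizations(c(500, 600, 700, 800, 900),
                        c(500, 600, 700, 800, 900), 2)
  s <- rbind(dense, spur)
  class(s) <- class(dense)
  out <- nnd_filter(s, threshold_override = 3)
  expect_equal(out$report$threshold, 3L)
  # all isolated points gone (psi 0 < 3 by construction); survivors are a
  # subset of the dense cloud
  expect_false(any(out$set$x > 400))
  expect_lte(nrow(out$set), nrow(dense))
  expect_gt(nrow(out$set), 0.8 * nrow(dense))
  # threshold 0 is the identity
  out0 <- nnd_filter(s, threshold_override = 0)
  expect_equal(nrow(out0$set), nrow(s))
  # total removal warns
  iso <- localizations(c(0, 1000), c(0, 1000), 1)
  expect_warning(nnd_filter(iso, threshold_override = 1), "every")
})

test_that("frame connection merges by inverse-variance weighting", {
  # two coincident records in consecutive frames: sigma s -> s/sqrt(2)
  s <- localizations(c(10, 10), c(5, 5), 2, frame = c(0, 1))
  r <- frame_connect(s)
  expect_equal(nrow(r), 1)
  expect_equal(r$sigma_x, 2 / sqrt(2))
  expect_equal(r$x, 10)
  # chain of 4 equal-sigma records -> sigma s/2
  s4 <- localizations(rep(10, 4), rep(5, 4), 2, frame = 0:3)
  expect_equal(frame_connect(s4)$sigma_x, 1)
  # far-apart records stay separate
  sfar <- localizations(c(0, 100), c(0, 0), 2, frame = c(0, 1))
  expect_equal(nrow(frame_connect(sfar)), 2)
  # precision identity holds exactly for unequal sigmas
  su <- localizations(c(0, 0.1), c(0, 0), c(1, 3), frame = c(0, 1))
  r2 <- frame_connect(su)
  expect_equal(1 / r2$sigma_x^2, 1 + 1 / 9, tolerance = 1e-12)
})

test_that("filters only remove records, never modify survivors", {
  set.seed(9)
  s <- localizations(runif(50, 0, 50), runif(50, 0, 50), runif(50, 1, 3),
                     photons = rexp(50, 1 / 1800))
  f1 <- intensity_filter(s, "relative", factor = 2)
  expect_true(all(do.call(paste, as.data.frame(f1)) %in%
                  do.call(paste, as.data.frame(s))))
  f2 <- nnd_filter(s, threshold_override = 1)$set
  expect_true(all(do.call(paste, as.data.frame(f2)) %in%
                  do.call(paste, as.data.frame(s))))
})
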