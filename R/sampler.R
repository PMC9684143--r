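#' Sampler configuration
#'
#' Collects every tunable of the reversible-jump sampler. Defaults follow the
#' analysis settings used throughout the package: equal jump probabilities,
#' burn-in equal to the number of kept samples, hierarchical learning of the
#' localizations-per-emitter mean with a Gamma(shape eta, mean gamma)
#' hyperprior, and drift estimation off.
#'
#' @param n_samples Post-burn-in samples to keep.
#' @param n_burnin Burn-in iterations (default `n_samples`).
#' @param jump_probs Probabilities of (Move, Allocate, Birth, Death); must sum
#'   to 1.
#' @param lambda Fixed mean localizations per emitter. If `NULL`
#'   (default) the mean is learned hierarchically.
#' @param xi_prior_eta,xi_prior_gamma Shape and mean of the gamma hyperprior
#'   on the learned mean (eta = 1, gamma = 5 makes it exponential with mean 5).
#' @param count_model `"poisson"` for Poisson blink counts (DNA-PAINT) or
#'   `"gamma_poisson"` for gamma-mixed Poisson counts (dSTORM; negative
#'   binomial with size eta and mean gamma per emitter).
#' @param drift Estimate a per-emitter linear drift over the acquisition.
#' @param drift_prior_sd Scale (nm) of the zero-mean Gaussian prior on each
#'   drift component, expressed as total displacement over the acquisition.
#' @param xi_sampler `"gibbs"` draws the learned mean from its exact
#'   conditional; `"mh"` uses a log-normal Metropolis step (sd `xi_mh_sd`).
#' @param xi_mh_sd Log-scale Metropolis step size.
#' @param xi_stride Sampler sweeps between updates of the learned mean.
#' @param lambda_init Initial value of the mean when learning it (defaults to
#'   `xi_prior_gamma`).
#' @return List of class `"sampler_config"`.
#' @export
sampler_config <- function(n_samples = 3000, n_burnin = n_samples,
                           jump_probs = c(0.25, 0.25, 0.25, 0.25),
                           lambda = NULL,
                           xi_prior_eta = 1, xi_prior_gamma = 5,
                           count_model = c("poisson", "gamma_poisson"),
                           drift = FALSE, drift_prior_sd = 50,
                           xi_sampler = c("gibbs", "mh"),
                           xi_mh_sd = 0.05, xi_stride = 10,
                           lambda_init = NULL) {
  count_model <- match.arg(count_model)
  xi_sampler <- match.arg(xi_sampler)
  stopifnot(length(jump_probs) == 4, all(jump_probs >= 0),
            abs(sum(jump_probs) - 1) < 1e-9,
            n_samples >= 1, n_burnin >= 0,
            xi_prior_eta > 0, xi_prior_gamma > 0,
            drift_prior_sd > 0, xi_stride >= 1, xi_mh_sd > 0)
  if (!is.null(lambda)) stopifnot(lambda > 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_burnin = as.integer(n_burnin),
                 jump_probs = jump_probs,
                 lambda = lambda,
                 xi_prior_eta = xi_prior_eta, xi_prior_gamma = xi_prior_gamma,
                 count_model = count_model,
                 drift = drift, drift_prior_sd = drift_prior_sd,
                 xi_sampler = xi_sampler, xi_mh_sd = xi_mh_sd,
                 xi_stride = as.integer(xi_stride),
                 lambda_init = lambda_init),
            class = "sampler_config")
}

#' Run the reversible-jump chain on one region
#'
#' Explores the joint posterior over the number of emitters K, emitter
#' positions (and optional linear drifts), the allocation of localizations to
#' emitters, and the mean number of localizations per emitter. Move jumps are
#' exact conditional (Gibbs) draws and always accepted; Allocate, Birth and
#' Death are Metropolis-Hastings / reversible-jump proposals. The flat
#' position prior extends over `box`; the chain is fully reproducible under
#' `set.seed()`.
#'
#' @param set A [localizations] object (the region's data, typically one tile).
#' @param config A [sampler_config].
#' @param box Position-prior bounding box `c(xmin, xmax, ymin, ymax)` nm;
#'   default: data bounding box padded by 3 median precisions.
#' @param t_range Frame range `c(min, max)` used to normalize times to
#'   \[0, 1\] (defaults to the region's own frame range); pass the full
#'   dataset's range when analysing tiles so drift is expressed per whole
#'   acquisition.
#' @param store_z Keep the per-sample allocation matrix (memory heavy).
#' @param core_box Optional inner box `c(xmin, xmax, ymin, ymax)`: when
#'   learning the localizations-per-emitter mean, only emitters inside it
#'   enter the count statistics (emitters near the data-window edge carry
#'   censored counts). Default: the whole `box`.
#' @return Object of class `"locfuse_chain"`: element `K` (kept sample counts),
#'   `xi` (per-sample mean-localizations parameter), `emitters` (data frame
#'   with one row per emitter per sample: `sample, x, y, ax, ay, n_loc`),
#'   acceptance counters, and the run geometry.
#' @export
run_chain <- function(set, config = sampler_config(), box = NULL,
                      t_range = NULL, store_z = FALSE, core_box = NULL) {
  set <- validate_localizations(set)
  N <- nrow(set)
  if (N == 0) {
    return(structure(list(K = integer(0), xi = numeric(0),
                          emitters = data.frame(sample = integer(0), x = numeric(0),
                                                y = numeric(0), ax = numeric(0),
                                                ay = numeric(0), n_loc = integer(0)),
                          accept = NULL, box = box, N = 0L, config = config),
                     class = "locfuse_chain"))
  }
  if (is.null(box)) {
    pad <- 3 * stats::median(c(set$sigma_x, set$sigma_y))
    box <- c(min(set$x) - pad, max(set$x) + pad, min(set$y) - pad, max(set$y) + pad)
  }
  if (is.null(t_range)) t_range <- range(set$frame)
  tspan <- max(1, diff(t_range))
  tt <- (set$frame - t_range[1]) / tspan

  fixed <- !is.null(config$lambda)
  pts <- cbind(set$x, set$y)
  area <- (box[2] - box[1]) * (box[4] - box[3])
  if (fixed || !is.null(config$lambda_init)) {
    lambda0 <- if (fixed) config$lambda else config$lambda_init
    K0 <- max(1L, min(N, as.integer(round(N / lambda0))))
    ini <- init_kmeans(pts, K0)
  } else {
    # data-driven start for hierarchical runs: score a ladder of candidate K
    # (penalized-clustering criterion matching the sampler's K^-N * A^-K
    # prior), then start moderately over-split -- the chain merges surplus
    # emitters readily, whereas a badly over- or under-split start mixes
    # poorly because every global redistribution empties some emitter or
    # every birth is priced at the inflated per-emitter cost.
    ini <- init_ladder(pts, set$sigma_x, set$sigma_y, area,
                       oversplit = if (config$count_model == "poisson") 2 else 1.5)
    K0 <- nrow(ini$mu)
    lambda0 <- max(N / K0, 0.5)
  }
  if (config$count_model == "gamma_poisson") lambda0 <- config$xi_prior_gamma
  mu0 <- ini$mu
  z0 <- ini$z

  res <- rjmcmc_chain_cpp(set$x, set$y, set$sigma_x, set$sigma_y, tt,
                          as.numeric(box),
                          config$n_burnin, config$n_samples,
                          config$jump_probs,
                          ifelse(config$count_model == "poisson", 0L, 1L),
                          ifelse(fixed || config$count_model == "gamma_poisson",
                                 0L, 1L),
                          ifelse(config$xi_sampler == "gibbs", 0L, 1L),
                          lambda0, config$xi_prior_eta, config$xi_prior_gamma,
                          config$xi_mh_sd, config$xi_stride,
                          isTRUE(config$drift), config$drift_prior_sd,
                          as.integer(z0), mu0, isTRUE(store_z),
                          if (is.null(core_box)) numeric(0)
                          else as.numeric(core_box))
  acc <- res$accept
  dimnames(acc) <- list(c("move", "allocate", "birth", "death", "xi"),
                        c("proposed", "accepted"))
  out <- list(K = res$K, xi = res$xi,
              emitters = data.frame(sample = res$sample,
                                    x = res$mu[, 1], y = res$mu[, 2],
                                    ax = res$a[, 1], ay = res$a[, 2],
                                    n_loc = res$n_loc),
              accept = acc, box = as.numeric(box), N = N,
              t_range = t_range, config = config)
  if (store_z) out$z <- res$z
  structure(out, class = "locfuse_chain")
}

init_kmeans <- function(pts, K0) {
  K0 <- max(1L, min(nrow(pts), as.integer(K0)))
  if (K0 > 1 && nrow(unique(pts)) > K0) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(pts, centers = K0, nstart = 1,
                                     iter.max = 20)),
      error = function(e) NULL)
    if (!is.null(km)) return(list(mu = unname(km$centers), z = km$cluster))
  }
  list(mu = matrix(colMeans(pts), 1, 2), z = rep(1L, nrow(pts)))
}

# Pick an initial number of emitters by scoring k-means partitions at a
# geometric ladder of candidate K with  logLik - N log K - K log A  (the
# likelihood and emitter-count penalty of the sampler's target at the profiled
# count parameter), then over-split the winner by `oversplit`.
init_ladder <- function(pts, sx, sy, area, oversplit = 2) {
  N <- nrow(pts)
  # score on a central spatial crop: a random subsample would dilute the
  # localizations-per-emitter scale the score is meant to detect
  ns <- N
  sel <- seq_len(N)
  if (N > 1200L) {
    ctr <- c(stats::median(pts[, 1]), stats::median(pts[, 2]))
    span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
    h <- span * sqrt(1200 / N) / 2
    repeat {
      sel <- which(abs(pts[, 1] - ctr[1]) <= h & abs(pts[, 2] - ctr[2]) <= h)
      if (length(sel) >= 600 || h >= span) break
      h <- h * 1.4
    }
    ns <- length(sel)
  }
  ps <- pts[sel, , drop = FALSE]
  # cap the largest candidate: k-means at K ~ ns/2 costs more than the
  # chain it initializes and only matters when the mean is below ~4
  kcap <- if (ns > 700) 350L else as.integer(ceiling(ns / 2))
  cand <- unique(pmin(kcap, pmax(1L, as.integer(round(
    ns / c(2, 5, 12, 30, 75, 190, 480, 1200))))))
  best <- NULL; best_score <- -Inf
  for (K in cand) {
    ini <- init_kmeans(ps, K)
    K_eff <- nrow(ini$mu)
    ll <- sum(stats::dnorm(ps[, 1], ini$mu[ini$z, 1], sx[sel], log = TRUE)) +
          sum(stats::dnorm(ps[, 2], ini$mu[ini$z, 2], sy[sel], log = TRUE))
    score <- ll - ns * log(K_eff) - K_eff * log(area)
    if (score > best_score) { best_score <- score; best <- K_eff }
  }
  lambda_like <- ns / best
  init_kmeans(pts, min(N, max(1L, as.integer(round(
    N / lambda_like * oversplit)))))
}

#' @export
print.locfuse_chain <- function(x, ...) {
  cat(sprintf("<locfuse_chain> %d samples over %d localizations\n",
              length(x$K), x$N))
  if (length(x$K) > 0) {
    tab <- table(x$K)
    cat("  K posterior: ",
        paste(sprintf("%s:%.2f", names(tab), as.numeric(tab) / length(x$K)),
              collapse = " "), "\n")
    cat(sprintf("  mean xi: %.2f\n", mean(x$xi)))
  }
  invisible(x)
}
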