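#' Group localizations into emitters by Bayesian model exploration
#'
#' The package's main fitting function. Splits the field into overlapping
#' subregions, runs the reversible-jump sampler in each (exploring the number
#' of emitters, their positions, optional per-emitter linear drifts, the
#' allocation of localizations to emitters and, unless `lambda` is fixed, the
#' mean number of localizations per emitter), extracts the most-probable-model
#' (MAPN) emitters per subregion, and stitches the cores back together.
#'
#' Grouping n localizations of precision sigma yields an emitter position of
#' precision about sigma/sqrt(n), so with tens of blinking/binding events per
#' emitter the returned coordinates are several-fold more precise than the
#' input localizations.
#'
#' @param set A [localizations] object (already filtered as appropriate; see
#'   [intensity_filter], [nnd_filter]).
#' @param lambda Fixed mean localizations per emitter, or `NULL` (default) to
#'   learn it hierarchically with a Gamma(`xi_prior_eta`, mean
#'   `xi_prior_gamma`) hyperprior.
#' @param count_model `"poisson"` (DNA-PAINT) or `"gamma_poisson"` (dSTORM).
#' @param drift Estimate per-emitter linear drift over the acquisition.
#' @param n_samples,n_burnin Chain lengths per subregion.
#' @param subregion_size Core tile edge in nm; `NULL` picks a size targeting a
#'   few hundred localizations per tile (single tile for small fields).
#' @param overlap Tile overlap margin in nm (see [make_tiling]).
#' @param extent Analysis region `c(xmin, xmax, ymin, ymax)` in nm (see
#'   [make_tiling]); default is the data bounding box.
#' @param xi_prior_eta,xi_prior_gamma Hyperprior shape and mean for the
#'   learned localizations-per-emitter mean (also the per-emitter negative
#'   binomial parameters under `count_model="gamma_poisson"`).
#' @param posterior_pixel Pixel size (nm) of the accumulated posterior image.
#' @param xi_sharing When learning the localizations-per-emitter mean on a
#'   tiled field: `"per_tile"` (default) lets each tile's chain learn its
#'   own mean jointly with the other unknowns; `"global"` learns it once on
#'   a central pilot window and fixes it for every tile.
#' @param seed Integer seed; the whole fit is reproducible given it.
#' @param keep_chains Keep per-tile chains (`TRUE`/`FALSE`/`"auto"`: keep when
#'   at most 16 tiles).
#' @param verbose Print per-tile progress.
#' @param ... Further arguments passed to [sampler_config].
#' @return Object of class `"locfuse"` with components `mapn` (emitter data
#'   frame: `x, y, sigma_x, sigma_y, ax, ay, n_loc, ...`), `posterior`
#'   (image + render spec), `xi` (per-tile posterior means of the
#'   localizations-per-emitter parameter), `tiling`, `accept` (pooled jump
#'   acceptance counts), `data`, and optionally `chains`.
#' @seealso [mapn_extract], [run_chain], [match_emitters]
#' @export
locfuse <- function(set, lambda = NULL,
                    count_model = c("poisson", "gamma_poisson"),
                    drift = FALSE,
                    n_samples = 3000, n_burnin = n_samples,
                    subregion_size = NULL, overlap = NULL, extent = NULL,
                    xi_prior_eta = 1, xi_prior_gamma = 5,
                    posterior_pixel = 2, seed = NULL,
                    xi_sharing = c("per_tile", "global"),
                    keep_chains = "auto", verbose = FALSE, ...) {
  xi_sharing <- match.arg(xi_sharing)
  count_model <- match.arg(count_model)
  set <- validate_localizations(set)
  if (nrow(set) == 0) stop("no localizations to fit")
  if (!is.null(seed)) set.seed(seed)
  cfg <- sampler_config(n_samples = n_samples, n_burnin = n_burnin,
                        lambda = lambda, count_model = count_model,
                        drift = drift, xi_prior_eta = xi_prior_eta,
                        xi_prior_gamma = xi_prior_gamma, ...)
  if (is.null(subregion_size)) {
    ex <- if (is.null(extent)) c(range(set$x), range(set$y))[c(1, 2, 3, 4)]
          else extent
    span <- max(ex[2] - ex[1], ex[4] - ex[3], 1)
    dens <- nrow(set) / ((ex[2] - ex[1]) * (ex[4] - ex[3]) + 1)
    subregion_size <- if (nrow(set) <= 1500) span * 1.01
                      else max(20, min(span * 1.01, sqrt(350 / dens)))
  }
  plan <- make_tiling(set, subregion_size, overlap, extent = extent)
  nt <- nrow(plan$tiles)
  keep <- if (identical(keep_chains, "auto")) nt <= 16 else isTRUE(keep_chains)
  t_range <- range(set$frame)

  # Learn the localizations-per-emitter mean once, on a single large central
  # window (one hierarchical chain, no tiling), then fix it for the tiled
  # pass. Small per-tile hierarchical estimates are biased low by emitters
  # truncated at the window edges -- edge-cluster fragments register as extra
  # emitters -- and the bias scales with the window's perimeter-to-area
  # ratio, so one window holding a few thousand localizations keeps it to a
  # few percent. Fits at a fixed working mean reproduce that mean in their
  # emitter counts (the count model shapes K toward N/lambda), so reading the
  # estimate back off a tiled fit cannot correct it; the single-window chain
  # is the estimator.
  lambda_hat <- NA_real_
  if (is.null(lambda) && count_model == "poisson" && nt > 1 &&
      identical(xi_sharing, "global")) {
    ex <- plan$extent
    dens <- nrow(set) / ((ex[2] - ex[1]) * (ex[4] - ex[3]) + 1)
    side <- min(sqrt(5000 / dens), ex[2] - ex[1], ex[4] - ex[3])
    cx <- (ex[1] + ex[2]) / 2; cy <- (ex[3] + ex[4]) / 2
    win <- c(cx - side / 2, cx + side / 2, cy - side / 2, cy + side / 2)
    idx <- which(set$x >= win[1] & set$x <= win[2] &
                 set$y >= win[3] & set$y <= win[4])
    if (length(idx) >= 30) {
      sub <- set[idx, , drop = FALSE]
      class(sub) <- class(set)
      pm <- 2 * stats::median(c(sub$sigma_x, sub$sigma_y))
      pcfg <- cfg
      pcfg$n_samples <- min(cfg$n_samples, 1500L)
      pcfg$n_burnin <- min(cfg$n_burnin, 1500L)
      ch <- run_chain(sub, pcfg, box = win + pm * c(-1, 1, -1, 1),
                      t_range = t_range)
      if (length(ch$xi) > 0) lambda_hat <- mean(ch$xi)
    }
    if (is.finite(lambda_hat) && lambda_hat > 0)
      cfg$lambda <- lambda_hat
    if (verbose) message(sprintf("pilot window: lambda = %.1f", lambda_hat))
  }

  spec <- render_spec(posterior_pixel, plan$extent)
  g <- render_grid(spec)
  post <- matrix(0, g$ny, g$nx)
  results <- vector("list", nt)
  chains <- if (keep) vector("list", nt) else NULL
  xi_means <- rep(NA_real_, nt)
  acc <- NULL
  for (ti in seq_len(nt)) {
    idx <- plan$members[[ti]]
    tl <- plan$tiles[ti, ]
    if (length(idx) == 0) {
      results[[ti]] <- structure(list(emitters = NULL, K_map = 0L, freq = NA),
                                 class = "mapn_result")
      next
    }
    sub <- set[idx, , drop = FALSE]
    class(sub) <- class(set)
    # position prior extends past the data window so a cluster truncated at
    # the window edge can place its emitter at the (outside) position the
    # data support instead of a biased in-window one; such emitters fall in
    # the overlap and are dropped at stitching
    pm <- 2 * stats::median(c(sub$sigma_x, sub$sigma_y))
    ch <- run_chain(sub, cfg,
                    box = c(tl$ex0 - pm, tl$ex1 + pm, tl$ey0 - pm, tl$ey1 + pm),
                    t_range = t_range)
    results[[ti]] <- mapn_extract(ch)
    if (length(ch$xi) > 0) xi_means[ti] <- mean(ch$xi)
    if (!is.null(ch$accept)) acc <- if (is.null(acc)) ch$accept else acc + ch$accept
    # accumulate posterior mass from this tile's core area
    em <- ch$emitters
    core <- em$x >= tl$cx0 & em$x < tl$cx1 & em$y >= tl$cy0 & em$y < tl$cy1
    if (any(core)) {
      ix <- findInterval(em$x[core], g$xb, rightmost.closed = TRUE)
      iy <- findInterval(em$y[core], g$yb, rightmost.closed = TRUE)
      ok <- ix >= 1 & ix <= g$nx & iy >= 1 & iy <= g$ny
      if (any(ok)) {
        tb <- table(factor(iy[ok], levels = 1:g$ny),
                    factor(ix[ok], levels = 1:g$nx))
        post <- post + unclass(tb) / length(ch$K)
      }
    }
    if (keep) chains[[ti]] <- ch
    if (verbose)
      message(sprintf("tile %d/%d: N=%d K=%d", ti, nt, length(idx),
                      results[[ti]]$K_map))
  }
  mapn <- stitch(results, plan)
  structure(list(call = match.call(), mapn = mapn$emitters,
                 K = nrow(mapn$emitters),
                 posterior = list(image = post, spec = spec),
                 xi = xi_means, lambda_hat = lambda_hat,
                 tiling = plan, accept = acc,
                 config = cfg, data = set, chains = chains, seed = seed),
            class = "locfuse")
}

#' @export
print.locfuse <- function(x, ...) {
  cat("Bayesian grouping of localizations\n")
  cat(sprintf("  %d localizations -> %d emitters (%d subregion%s)\n",
              nrow(x$data), x$K, nrow(x$tiling$tiles),
              if (nrow(x$tiling$tiles) == 1) "" else "s"))
  if (x$K > 0)
    cat(sprintf("  median precision: input %.2f nm -> grouped %.2f nm\n",
                stats::median(c(x$data$sigma_x, x$data$sigma_y)),
                stats::median(c(x$mapn$sigma_x, x$mapn$sigma_y))))
  if (any(is.finite(x$xi)))
    cat(sprintf("  localizations per emitter (learned mean): %.1f\n",
                mean(x$xi, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.locfuse <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$accept)) {
    r <- x$accept[, 2] / pmax(1, x$accept[, 1])
    cat("  acceptance rates: ",
        paste(sprintf("%s %.2f", rownames(x$accept), r), collapse = ", "), "\n")
  }
  if (x$K > 0) {
    cat(sprintf("  localizations per emitter (MAPN mean): %.1f\n",
                mean(x$mapn$n_loc)))
    if (isTRUE(x$config$drift))
      cat(sprintf("  drift magnitude (median): %.2f nm per acquisition\n",
                  stats::median(sqrt(x$mapn$ax^2 + x$mapn$ay^2))))
  }
  invisible(x)
}

#' @export
coef.locfuse <- function(object, ...) {
  as.matrix(object$mapn[, c("x", "y", "sigma_x", "sigma_y")])
}

#' @export
fitted.locfuse <- function(object, ...) object$mapn

#' Residual distances of localizations to their nearest fitted emitter
#'
#' @param object A fitted `"locfuse"` object.
#' @param type `"distance"` (nm) or `"standardized"` (distance divided by the
#'   localization's pooled precision; approximately Rayleigh(1) under the
#'   model).
#' @param ... Unused.
#' @export
residuals.locfuse <- function(object, type = c("distance", "standardized"), ...) {
  type <- match.arg(type)
  if (object$K == 0) return(rep(NA_real_, nrow(object$data)))
  d <- nn_query_cpp(object$data$x, object$data$y,
                    object$mapn$x, object$mapn$y, integer(0))
  if (type == "standardized")
    d <- d / sqrt((object$data$sigma_x^2 + object$data$sigma_y^2) / 2)
  d
}

#' Simulate localization sets from a fitted emitter model
#'
#' Draws new DNA-PAINT-style localization data from the fitted MAPN emitters:
#' Poisson blink counts with the learned (or fixed) mean, exponential photon
#' counts calibrated from the data when available, and Gaussian localization
#' noise sigma_PSF/sqrt(I).
#'
#' @param object A fitted `"locfuse"` object with at least one emitter.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [localizations] objects (length `nsim`).
#' @export
simulate.locfuse <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (object$K == 0) stop("cannot simulate from an empty fit")
  lam <- if (!is.null(object$config$lambda)) object$config$lambda
         else if (any(is.finite(object$xi))) mean(object$xi, na.rm = TRUE)
         else mean(object$mapn$n_loc)
  mp <- if (any(is.finite(object$data$photons)))
    mean(object$data$photons, na.rm = TRUE) else 1800
  scene <- sim_scene(as.matrix(object$mapn[, c("x", "y")]), lambda = lam,
                     mean_photons = mp,
                     n_frames = max(object$data$frame) + 1L)
  out <- lapply(seq_len(nsim), function(i) simulate_blinks(scene)$set)
  if (nsim == 1) out[[1]] else out
}

#' Plot a fitted grouping
#'
#' Shows the accumulated posterior image (log-scaled intensities) with the
#' MAPN emitter coordinates overlaid.
#'
#' @param x A fitted `"locfuse"` object.
#' @param show_mapn Overlay MAPN emitters.
#' @param ... Passed to [graphics::image].
#' @export
plot.locfuse <- function(x, show_mapn = TRUE, ...) {
  img <- x$posterior$image
  ex <- x$posterior$spec$extent
  g <- render_grid(x$posterior$spec)
  graphics::image(x = g$xb, y = g$yb, z = t(log1p(img)),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  xlab = "x (nm)", ylab = "y (nm)", useRaster = TRUE, ...)
  if (show_mapn && x$K > 0)
    graphics::points(x$mapn$x, x$mapn$y, col = "red", pch = 3, cex = 0.6)
  invisible(x)
}
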