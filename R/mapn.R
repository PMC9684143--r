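#' Extract the most-probable-model (MAPN) emitters from a chain
#'
#' Finds the modal number of emitters K in the chain (ties broken toward the
#' smaller K, the parsimonious model), pools the emitter positions of every
#' sample with that K, and clusters them with k-means (k = modal K, best of 10
#' seeded restarts). Cluster means are the MAPN emitter coordinates; the
#' per-axis standard deviations of cluster members are the grouped
#' precisions; cluster means of the drift samples and allocation counts give
#' per-emitter drift estimates and mean localization counts.
#'
#' @param chain A `"locfuse_chain"` from [run_chain].
#' @param max_pool Cap on pooled position rows fed to k-means; longer chains
#'   are thinned by whole samples (keeps the per-sample structure).
#' @return Object of class `"mapn_result"`: data frame `emitters` with columns
#'   `x, y, sigma_x, sigma_y, ax, ay, n_loc, n_samples`, plus `K_map` and the
#'   chain's modal-K frequency.
#' @export
mapn_extract <- function(chain, max_pool = 10000) {
  stopifnot(inherits(chain, "locfuse_chain"))
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      sigma_x = numeric(0), sigma_y = numeric(0),
                      ax = numeric(0), ay = numeric(0),
                      n_loc = numeric(0), n_samples = integer(0))
  if (length(chain$K) == 0)
    return(structure(list(emitters = empty, K_map = 0L, freq = NA_real_),
                     class = "mapn_result"))
  tab <- table(chain$K)
  best <- max(tab)
  K_map <- min(as.integer(names(tab)[tab == best]))  # parsimony tie-break
  freq <- best / length(chain$K)
  if (K_map == 0)
    return(structure(list(emitters = empty, K_map = 0L, freq = freq),
                     class = "mapn_result"))
  keep_samples <- which(chain$K == K_map)
  em_all <- chain$emitters[chain$emitters$sample %in% keep_samples, , drop = FALSE]
  # initial centers by pooled k-means (thinned for speed), then a sample-aware
  # refinement in which every modal-K sample contributes exactly one member
  # per cluster -- pooled k-means alone can split a wide posterior cluster
  # while merging two tight neighbours
  em <- em_all
  if (nrow(em) > max_pool) {
    stride <- ceiling(length(keep_samples) * K_map / max_pool)
    sel <- keep_samples[seq(1, length(keep_samples), by = stride)]
    em <- chain$emitters[chain$emitters$sample %in% sel, , drop = FALSE]
  }
  pts <- cbind(em$x, em$y)
  centers <- if (K_map == 1) matrix(colMeans(pts), 1, 2) else
    suppressWarnings(stats::kmeans(pts, centers = K_map, nstart = 10,
                                   iter.max = 100))$centers
  starts <- c(0L, cumsum(rle(em_all$sample)$lengths))
  ref <- mapn_refine_cpp(cbind(em_all$x, em_all$y), cbind(em_all$ax, em_all$ay),
                         em_all$n_loc, starts[-length(starts)],
                         diff(starts), unname(centers), 3L)
  out <- data.frame(x = ref$centers[, 1], y = ref$centers[, 2],
                    sigma_x = ref$sd[, 1], sigma_y = ref$sd[, 2],
                    ax = ref$a[, 1], ay = ref$a[, 2],
                    n_loc = ref$n_loc, n_samples = ref$n_members)
  # degenerate single-member clusters: fall back to the median precision
  for (cc in c("sigma_x", "sigma_y")) {
    bad <- !is.finite(out[[cc]]) | out[[cc]] <= 0
    if (any(bad)) {
      fb <- stats::median(out[[cc]][!bad])
      if (!is.finite(fb)) fb <- 1e-3
      out[[cc]][bad] <- fb
    }
  }
  structure(list(emitters = out, K_map = K_map, freq = freq),
            class = "mapn_result")
}

#' @export
print.mapn_result <- function(x, ...) {
  cat(sprintf("<mapn_result> K = %d (modal-model frequency %.2f)\n",
              x$K_map, x$freq))
  if (nrow(x$emitters) > 0)
    cat(sprintf("  mean grouped precision: %.3f nm\n",
                mean(c(x$emitters$sigma_x, x$emitters$sigma_y))))
  invisible(x)
}

#' Posterior image of a chain
#'
#' A 2-D histogram of every emitter position stored in the chain (all models
#' pooled), normalized by the number of samples, so the total mass equals the
#' chain's mean K (up to positions falling outside the extent).
#'
#' @param chain A `"locfuse_chain"`.
#' @param spec A [render_spec].
#' @return Intensity matrix (ny rows, nx cols).
#' @export
posterior_image <- function(chain, spec) {
  stopifnot(inherits(chain, "locfuse_chain"), inherits(spec, "render_spec"))
  g <- render_grid(spec)
  img <- matrix(0, g$ny, g$nx)
  em <- chain$emitters
  if (nrow(em) == 0 || length(chain$K) == 0) return(img)
  ix <- findInterval(em$x, g$xb, rightmost.closed = TRUE)
  iy <- findInterval(em$y, g$yb, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= g$nx & iy >= 1 & iy <= g$ny
  tb <- table(factor(iy[ok], levels = 1:g$ny), factor(ix[ok], levels = 1:g$nx))
  img + unclass(tb) / length(chain$K)
}
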