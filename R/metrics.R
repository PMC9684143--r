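#' Optimally match estimated emitters to ground truth
#'
#' One-to-one assignment between true and estimated emitter positions
#' minimizing total distance (Hungarian algorithm), followed by removal of
#' pairs violating the cutoff rule. Two cutoff rules are provided:
#' `"three_mean_precision"` (a global cutoff of 3 x the mean returned
#' precision, the rule used for Jaccard/RMSE sweeps) and `"three_sigma"` (the
#' true position must fall within 3 x that estimate's own precision radius).
#' For large point sets the assignment is computed exactly on the connected
#' components of the within-cutoff candidate graph, which is equivalent to the
#' global cutoff-capped assignment.
#'
#' @param truth Two-column matrix/data frame of true (x, y) in nm.
#' @param est An `"mapn_result"`, its `emitters` data frame, or a matrix with
#'   columns `x, y` (and `sigma_x, sigma_y` for precision-based cutoffs).
#' @param cutoff_rule `"three_mean_precision"` or `"three_sigma"`.
#' @param cutoff Explicit global cutoff in nm, overriding the rule.
#' @return List of class `"match_result"`: data frame `pairs`
#'   (`true, est, distance`), `n_true`, `n_est`, `cutoff`.
#' @export
match_emitters <- function(truth, est,
                           cutoff_rule = c("three_mean_precision", "three_sigma"),
                           cutoff = NULL) {
  cutoff_rule <- match.arg(cutoff_rule)
  if (inherits(est, "mapn_result")) est <- est$emitters
  est <- as.data.frame(est)
  truth <- as.matrix(as.data.frame(truth)[, 1:2, drop = FALSE])
  nt <- nrow(truth); ne <- nrow(est)
  empty <- data.frame(true = integer(0), est = integer(0), distance = numeric(0))
  prec <- if (all(c("sigma_x", "sigma_y") %in% names(est)) && ne > 0)
    (est$sigma_x + est$sigma_y) / 2 else NULL
  if (is.null(cutoff)) {
    if (is.null(prec))
      stop("est has no precisions; give an explicit cutoff")
    cutoff <- 3 * mean(prec)
  }
  pair_ok <- function(ti, ei, d) {
    if (cutoff_rule == "three_sigma" && !is.null(prec)) d <= 3 * prec[ei]
    else d <= cutoff
  }
  radius <- if (cutoff_rule == "three_sigma" && !is.null(prec))
    max(cutoff, 3 * max(prec)) else cutoff
  if (nt == 0 || ne == 0)
    return(structure(list(pairs = empty, n_true = nt, n_est = ne,
                          cutoff = cutoff), class = "match_result"))
  # candidate edges within the matching radius
  elist <- vector("list", nt)
  for (ti in seq_len(nt)) {
    d <- sqrt((est$x - truth[ti, 1])^2 + (est$y - truth[ti, 2])^2)
    hit <- which(d <= radius)
    if (length(hit) > 0) elist[[ti]] <- cbind(ti, hit, d[hit])
  }
  edges <- do.call(rbind, elist)
  if (is.null(edges))
    return(structure(list(pairs = empty, n_true = nt, n_est = ne,
                          cutoff = cutoff), class = "match_result"))
  # connected components over the candidate graph (union-find)
  parent <- seq_len(nt + ne)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(nt + edges[r, 2])
    if (a != b) parent[a] <- b
  }
  comp_t <- vapply(seq_len(nt), find, numeric(1))
  comp_e <- vapply(nt + seq_len(ne), find, numeric(1))
  plist <- list()
  for (cp in unique(comp_t[edges[, 1]])) {
    tt <- which(comp_t == cp); ee <- which(comp_e == cp)
    if (length(tt) == 0 || length(ee) == 0) next
    # pad columns with dummies at the cutoff so unmatched stays unmatched
    npad <- length(tt)
    cost <- matrix(radius * 1.0001, length(tt), length(ee) + npad)
    for (a in seq_along(tt)) {
      d <- sqrt((est$x[ee] - truth[tt[a], 1])^2 + (est$y[ee] - truth[tt[a], 2])^2)
      cost[a, seq_along(ee)] <- pmin(d, radius * 1.0001)
    }
    transposed <- FALSE
    if (nrow(cost) > ncol(cost)) { cost <- t(cost); transposed <- TRUE }
    asg <- hungarian_cpp(cost)
    for (a in seq_along(asg)) {
      ri <- if (transposed) asg[a] else a
      ci <- if (transposed) a else asg[a]
      if (ri > length(tt) || ci > length(ee)) next
      ti <- tt[ri]; ei <- ee[ci]
      d <- sqrt((est$x[ei] - truth[ti, 1])^2 + (est$y[ei] - truth[ti, 2])^2)
      if (d <= radius && pair_ok(ti, ei, d))
        plist[[length(plist) + 1]] <- data.frame(true = ti, est = ei, distance = d)
    }
  }
  pairs <- if (length(plist) > 0) do.call(rbind, plist) else empty
  structure(list(pairs = pairs, n_true = nt, n_est = ne, cutoff = cutoff),
            class = "match_result")
}

#' Jaccard index of a matching
#'
#' JAC = TP / (TP + FP + FN): matched pairs over matched pairs plus unmatched
#' estimates plus unmatched truths. Two empty sets give 1 (vacuously perfect).
#'
#' @param match A `"match_result"`.
#' @return Fraction in \[0, 1\].
#' @export
jaccard <- function(match) {
  stopifnot(inherits(match, "match_result"))
  tp <- nrow(match$pairs)
  fp <- match$n_est - tp
  fn <- match$n_true - tp
  if (tp + fp + fn == 0) return(1)
  tp / (tp + fp + fn)
}

#' Position error of matched pairs
#'
#' `method = "rms"` returns the root of the mean squared Euclidean pair
#' distance; `method = "mean"` returns the mean pair distance, which is how
#' the benchmark literature computes the value it prints under the RMSE
#' label. `NA` when nothing matched.
#'
#' @param match A `"match_result"`.
#' @param method `"rms"` (default) or `"mean"`.
#' @return Error in nm, or `NA_real_`.
#' @export
rmse <- function(match, method = c("rms", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(match, "match_result"))
  if (nrow(match$pairs) == 0) return(NA_real_)
  if (method == "mean") mean(match$pairs$distance)
  else sqrt(mean(match$pairs$distance^2))
}

#' Predicted accuracy distribution f(r) against observed distances
#'
#' The radial error of a 2-D Gaussian estimate of width sigma follows the
#' Rayleigh density f(r) = r/sigma^2 exp(-r^2/(2 sigma^2)). Returns the
#' observed histogram and the predicted curve scaled to the same area over the
#' displayed range.
#'
#' @param distances Observed true-to-estimate distances (nm).
#' @param sigma Precision parameter of the prediction (nm).
#' @param breaks Passed to [graphics::hist] (computed, not plotted).
#' @return List with `hist` (histogram object), `r` (grid), `curve` (scaled
#'   density on the grid).
#' @export
accuracy_distribution <- function(distances, sigma, breaks = "Sturges") {
  stopifnot(sigma > 0)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  r <- seq(min(h$breaks), max(h$breaks), length.out = 256)
  f <- r / sigma^2 * exp(-r^2 / (2 * sigma^2))
  area_obs <- sum(h$counts) * mean(diff(h$breaks))
  area_f <- sum(f) * mean(diff(r))
  list(hist = h, r = r, curve = if (area_f > 0) f * area_obs / area_f else f)
}

#' Nearest-neighbor distances of a point set
#'
#' @param points Two-column matrix of (x, y).
#' @return Per-point distance to its nearest other point.
#' @export
nnd_distribution <- function(points) {
  p <- as.matrix(as.data.frame(points)[, 1:2])
  if (nrow(p) < 2) stop("need at least two points")
  nn_query_cpp(p[, 1], p[, 2], p[, 1], p[, 2], seq_len(nrow(p)))
}

#' Hopkins' statistic of spatial clustering
#'
#' Per iteration, samples `m` data points and `m` uniform locations in the
#' bounding box; with u = nearest-data distances from the random locations
#' and w = nearest-other-data distances from the sampled points,
#' H = sum(u^2) / (sum(u^2) + sum(w^2)) (squared distances, dimension 2).
#' H ~ 0.5 for complete spatial randomness (Beta(m, m) exactly, up to edge
#' effects), near 1 for clustered and below 0.5 for regular patterns.
#'
#' @param points Two-column matrix of (x, y).
#' @param m Probes per iteration (< number of points).
#' @param iters Number of H draws.
#' @return Numeric vector of `iters` H values.
#' @export
hopkins <- function(points, m = 10, iters = 1000) {
  p <- as.matrix(as.data.frame(points)[, 1:2])
  n <- nrow(p)
  stopifnot(m < n, m >= 1, iters >= 1)
  bb <- c(range(p[, 1]), range(p[, 2]))
  vapply(seq_len(iters), function(i) {
    ii <- sample.int(n, m)
    w <- nn_query_cpp(p[ii, 1], p[ii, 2], p[, 1], p[, 2], ii)
    qx <- stats::runif(m, bb[1], bb[2])
    qy <- stats::runif(m, bb[3], bb[4])
    u <- nn_query_cpp(qx, qy, p[, 1], p[, 2], integer(0))
    sum(u^2) / (sum(u^2) + sum(w^2))
  }, numeric(1))
}
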