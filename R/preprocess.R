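#' Intensity (photon-count) outlier filter
#'
#' Removes localizations whose photon count exceeds a cutoff: unusually bright
#' events typically come from overlapping emitters fitted as one and carry
#' incorrect, over-confident precisions. In relative mode the cutoff is
#' `factor` times the mean intensity (the usual choice is ~2x the mean); in
#' absolute mode it is a fixed photon count.
#'
#' @param set A [localizations] object with photon counts.
#' @param mode `"relative"` or `"absolute"`.
#' @param factor Relative-mode multiplier of the mean intensity (> 0).
#' @param cutoff Absolute-mode photon cutoff (> 0).
#' @return The filtered set; the number of removed records is attached as
#'   `attr(,"removed")`.
#' @export
intensity_filter <- function(set, mode = c("relative", "absolute"),
                             factor = 2, cutoff = NULL) {
  mode <- match.arg(mode)
  set <- validate_localizations(set)
  if (all(is.na(set$photons)))
    stop("intensity_filter needs a photons column with values")
  lim <- if (mode == "relative") {
    stopifnot(factor > 0)
    factor * mean(set$photons, na.rm = TRUE)
  } else {
    stopifnot(!is.null(cutoff), cutoff > 0)
    cutoff
  }
  keep <- is.na(set$photons) | set$photons <= lim
  out <- set[keep, , drop = FALSE]
  class(out) <- class(set)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Neighbor counts within three median precisions
#'
#' For every localization, counts the other localizations within a radius of
#' three times the median of all reported precisions (both axes pooled). This
#' count, psi, separates localizations belonging to repeatedly sampled
#' emitters (large psi) from sparse spurious events (small psi).
#'
#' @param set A [localizations] object (N >= 1).
#' @return List of class `"nnd_filter_report"` with `psi` (integer counts),
#'   `radius` (nm), and placeholders for `threshold`/`kept_mask` filled by
#'   [nnd_filter].
#' @export
compute_psi <- function(set) {
  set <- validate_localizations(set)
  if (nrow(set) < 1) stop("compute_psi needs at least one localization")
  radius <- 3 * stats::median(c(set$sigma_x, set$sigma_y))
  psi <- count_within_cpp(set$x, set$y, radius)
  structure(list(psi = as.integer(psi), radius = radius,
                 threshold = NA_integer_, kept_mask = NULL),
            class = "nnd_filter_report")
}

#' Valley threshold of a neighbor-count histogram
#'
#' Histograms psi on integer bins, smooths with a 3-bin moving average, and
#' returns the location of the first local minimum between the first two local
#' maxima (the valley separating the spurious-event mode from the real-emitter
#' mode). A unimodal histogram yields 0 with a warning, i.e. the filter is
#' disabled.
#'
#' @param psi Integer neighbor counts from [compute_psi].
#' @return Integer threshold (0 means no filtering).
#' @export
find_valley_threshold <- function(psi) {
  stopifnot(length(psi) > 0)
  h <- tabulate(psi + 1L, nbins = max(psi) + 1L)  # bins 0..max
  if (length(h) < 3) return(0L)
  s <- stats::filter(h, rep(1 / 3, 3), sides = 2)
  s[1] <- mean(h[1:2]); s[length(h)] <- mean(h[(length(h) - 1):length(h)])
  s <- as.numeric(s)
  n <- length(s)
  # local maxima tall enough to count as modes (noise guard: >= 5% of the
  # tallest bin); the valley must dip at least 30% below the lower mode
  is_max <- vapply(seq_len(n), function(i) {
    lo <- if (i > 1) s[i - 1] else -Inf
    hi <- if (i < n) s[i + 1] else -Inf
    s[i] > lo && s[i] >= hi
  }, logical(1))
  mx <- which(is_max & s >= 0.05 * max(s))
  if (length(mx) >= 2) {
    first <- mx[1]
    for (j in mx[-1]) {
      seg <- s[(first + 1):(j - 1)]
      if (length(seg) > 0 && min(seg) <= 0.7 * min(s[first], s[j])) {
        valley <- first + which.min(seg)
        return(as.integer(valley - 1L))  # bin index -> psi value
      }
    }
  }
  warning("psi histogram has no interior valley; NND filter disabled")
  0L
}

#' Nearest-neighbor-density (NND) outlier filter
#'
#' Removes localizations whose neighbor count psi falls below a threshold,
#' found automatically at the valley of the psi histogram unless overridden.
#' Intended for DNA-PAINT-type data where every real emitter generates many
#' localizations; it must not be applied to dSTORM data, where a single
#' localization per emitter is possible.
#'
#' @param set A [localizations] object.
#' @param threshold_override Integer threshold to use instead of the valley.
#' @return List with `set` (filtered localizations) and `report`
#'   (an `"nnd_filter_report"` with psi, radius, threshold, kept_mask).
#' @export
nnd_filter <- function(set, threshold_override = NULL) {
  rep0 <- compute_psi(set)
  thr <- if (!is.null(threshold_override)) as.integer(threshold_override)
         else find_valley_threshold(rep0$psi)
  keep <- rep0$psi >= thr
  if (!any(keep)) warning("NND filter removed every localization")
  out <- set[keep, , drop = FALSE]
  class(out) <- class(set)
  rep0$threshold <- thr
  rep0$kept_mask <- keep
  list(set = out, report = rep0)
}

#' Simple frame connection
#'
#' Greedy single-link merging of localizations that appear in nearby frames at
#' the same position: records within `max_gap` frames and within
#' `max_dist_sigma` combined precisions are fused by inverse-variance
#' weighting, so the merged precision obeys 1/sigma'^2 = sum(1/sigma_i^2).
#' This is deliberately minimal plumbing (off by default in the pipeline), not
#' a hypothesis-test frame connector.
#'
#' @param set A [localizations] object with frames.
#' @param max_gap Maximum frame gap within a connection (default 1).
#' @param max_dist_sigma Distance gate in units of combined precision
#'   (default 3).
#' @param drop_singletons Drop records that connect to nothing.
#' @return Merged [localizations]; `frame` of a merged record is its first
#'   frame, photons are summed.
#' @export
frame_connect <- function(set, max_gap = 1L, max_dist_sigma = 3,
                          drop_singletons = FALSE) {
  set <- validate_localizations(set)
  n <- nrow(set)
  if (n == 0) return(set)
  ord <- order(set$frame)
  d <- as.data.frame(set)[ord, ]
  grp <- integer(n); grp[1] <- 1L; ng <- 1L
  # open tracks: last position/frame and accumulated inverse variances
  tr_x <- d$x[1] / d$sigma_x[1]^2; tr_wx <- 1 / d$sigma_x[1]^2
  tr_y <- d$y[1] / d$sigma_y[1]^2; tr_wy <- 1 / d$sigma_y[1]^2
  tracks <- data.frame(id = 1L, lastframe = d$frame[1],
                       sx = tr_x, wx = tr_wx, sy = tr_y, wy = tr_wy)
  for (i in 2:n) if (n >= 2) {
    tracks <- tracks[d$frame[i] - tracks$lastframe <= max_gap, , drop = FALSE]
    px <- tracks$sx / tracks$wx; py <- tracks$sy / tracks$wy
    comb <- sqrt(1 / tracks$wx + d$sigma_x[i]^2 + 1 / tracks$wy + d$sigma_y[i]^2)
    dist <- sqrt((px - d$x[i])^2 + (py - d$y[i])^2)
    hit <- which(dist <= max_dist_sigma * comb & d$frame[i] > tracks$lastframe)
    if (length(hit) > 0) {
      j <- hit[which.min(dist[hit])]
      grp[i] <- tracks$id[j]
      tracks$sx[j] <- tracks$sx[j] + d$x[i] / d$sigma_x[i]^2
      tracks$wx[j] <- tracks$wx[j] + 1 / d$sigma_x[i]^2
      tracks$sy[j] <- tracks$sy[j] + d$y[i] / d$sigma_y[i]^2
      tracks$wy[j] <- tracks$wy[j] + 1 / d$sigma_y[i]^2
      tracks$lastframe[j] <- d$frame[i]
    } else {
      ng <- ng + 1L; grp[i] <- ng
      tracks <- rbind(tracks, data.frame(
        id = ng, lastframe = d$frame[i],
        sx = d$x[i] / d$sigma_x[i]^2, wx = 1 / d$sigma_x[i]^2,
        sy = d$y[i] / d$sigma_y[i]^2, wy = 1 / d$sigma_y[i]^2))
    }
  }
  agg <- lapply(split(seq_len(n), grp), function(ii) {
    wxs <- 1 / d$sigma_x[ii]^2; wys <- 1 / d$sigma_y[ii]^2
    data.frame(x = sum(d$x[ii] * wxs) / sum(wxs),
               y = sum(d$y[ii] * wys) / sum(wys),
               sigma_x = 1 / sqrt(sum(wxs)), sigma_y = 1 / sqrt(sum(wys)),
               frame = min(d$frame[ii]),
               photons = if (all(is.na(d$photons[ii]))) NA_real_
                         else sum(d$photons[ii], na.rm = TRUE),
               nmerged = length(ii))
  })
  out <- do.call(rbind, agg)
  if (drop_singletons) out <- out[out$nmerged > 1, , drop = FALSE]
  res <- localizations(out$x, out$y, out$sigma_x, out$sigma_y,
                       frame = out$frame, photons = out$photons)
  attr(res, "nmerged") <- out$nmerged
  res
}
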