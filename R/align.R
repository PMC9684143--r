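#' Monte-Carlo rigid alignment of a structure to a template
#'
#' Aligns a recovered structure (e.g. MAPN coordinates of one particle) to a
#' template by rigid rotation + translation: the structure is first shifted so
#' the centers of mass coincide, then iteratively perturbed by random
#' rotations and translations, keeping a proposal whenever it lowers the sum
#' of nearest-neighbor distances to the template (contributions beyond
#' `cutoff` are capped at `cutoff`). The chain has 3000 iterations; the first
#' half uses coarse jumps (1 rad, 0.5 nm), the second half fine jumps
#' (0.1 rad, 0.05 nm), and the reported transform is the best one visited in
#' the second half.
#'
#' @param structure Two-column matrix of (x, y) positions (>= 2 points).
#' @param template Two-column matrix of template vertices (>= 2 points).
#' @param cutoff Distance cap in nm for each point's NN contribution
#'   (default 6).
#' @param n_iter Chain length (default 3000).
#' @param jump_sizes List with `rot` and `trans`, each length 2 (coarse, fine
#'   phase).
#' @return List of class `"rigid_transform"`: `rotation` (radians),
#'   `translation` (nm, applied after rotation about the structure's center of
#'   mass), `score` (capped NN-distance sum), and `aligned` (transformed
#'   structure).
#' @export
align_to_template <- function(structure, template, cutoff = 6,
                              n_iter = 3000,
                              jump_sizes = list(rot = c(1, 0.1),
                                                trans = c(0.5, 0.05))) {
  S <- as.matrix(as.data.frame(structure)[, 1:2])
  Tm <- as.matrix(as.data.frame(template)[, 1:2])
  stopifnot(nrow(S) >= 2, nrow(Tm) >= 2, cutoff > 0)
  if (max(stats::dist(S)) < 1e-12) stop("degenerate structure: all points coincide")
  com_s <- colMeans(S); com_t <- colMeans(Tm)
  score_of <- function(theta, shift) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    P <- sweep(S, 2, com_s) %*% t(R)
    P <- sweep(P, 2, com_t + shift, FUN = "+")
    d <- nn_query_cpp(P[, 1], P[, 2], Tm[, 1], Tm[, 2], integer(0))
    sum(pmin(d, cutoff))
  }
  theta <- 0; shift <- c(0, 0)
  cur <- score_of(theta, shift)
  best <- list(theta = theta, shift = shift, score = cur)
  half <- floor(n_iter / 2)
  for (it in seq_len(n_iter)) {
    phase <- if (it <= half) 1 else 2
    th2 <- theta + stats::rnorm(1, 0, jump_sizes$rot[phase])
    sh2 <- shift + stats::rnorm(2, 0, jump_sizes$trans[phase])
    sc2 <- score_of(th2, sh2)
    # non-strict acceptance lets the search diffuse across the flat plateaus
    # created by the distance cap instead of freezing on them
    if (sc2 <= cur) { theta <- th2; shift <- sh2; cur <- sc2 }
    if (it > half && cur < best$score)
      best <- list(theta = theta, shift = shift, score = cur)
  }
  R <- matrix(c(cos(best$theta), sin(best$theta),
                -sin(best$theta), cos(best$theta)), 2, 2)
  aligned <- sweep(sweep(S, 2, com_s) %*% t(R), 2, com_t + best$shift, FUN = "+")
  structure(list(rotation = best$theta,
                 translation = com_t + best$shift - com_s,
                 score = best$score, aligned = aligned,
                 com_structure = com_s, com_template = com_t),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation %.4f rad, score %.3f nm\n",
              x$rotation, x$score))
  invisible(x)
}

#' Reject malformed aligned structures
#'
#' Keeps only aligned structures whose sum of nearest-neighbor distances to
#' the template is at most `max_sum_nnd` (default 6 nm), discarding
#' incompletely formed particles before averaging.
#'
#' @param aligned List of aligned structures (two-column matrices) or of
#'   `"rigid_transform"` objects.
#' @param template Template vertices.
#' @param max_sum_nnd Acceptance threshold in nm.
#' @return List with `kept` (the surviving structures), `keep` (logical mask)
#'   and `sum_nnd` (per-structure scores).
#' @export
filter_malformed <- function(aligned, template, max_sum_nnd = 6) {
  Tm <- as.matrix(as.data.frame(template)[, 1:2])
  pts <- lapply(aligned, function(a)
    if (inherits(a, "rigid_transform")) a$aligned
    else as.matrix(as.data.frame(a)[, 1:2]))
  s <- vapply(pts, function(P)
    sum(nn_query_cpp(P[, 1], P[, 2], Tm[, 1], Tm[, 2], integer(0))),
    numeric(1))
  keep <- s <= max_sum_nnd
  list(kept = pts[keep], keep = keep, sum_nnd = s)
}

#' Re-group pooled aligned coordinates
#'
#' Treats the pooled emitter coordinates and precisions of many aligned
#' structures as if they were localizations and runs the grouping sampler on
#' them with a fixed mean equal to the number of aligned structures,
#' producing a consensus particle whose site precisions improve roughly as
#' 1/sqrt(number of structures).
#'
#' @param pooled A [localizations] object of pooled aligned coordinates (use
#'   the per-structure precisions as the "localization" precisions).
#' @param n_structures Number of aligned structures contributing (sets the
#'   fixed mean localizations per site).
#' @param ... Passed to [locfuse] (e.g. `n_samples`, `seed`).
#' @return A fitted `"locfuse"` object for the consensus structure.
#' @export
regroup_pooled <- function(pooled, n_structures, ...) {
  stopifnot(n_structures >= 1)
  locfuse(pooled, lambda = n_structures, ...)
}
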