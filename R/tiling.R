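#' Split a field into overlapping subregions
#'
#' Lays a grid of square core boxes over the data extent and extends each by
#' an overlap margin; every localization is assigned to each box whose
#' extended bounds contain it, so emitters near box edges see all their
#' localizations. Core boxes are half-open (\[x0, x1)) and partition the
#' field, which makes stitching deterministic.
#'
#' @param set A [localizations] object.
#' @param subregion_size Core box edge in nm.
#' @param overlap Margin in nm added on every side of a core box; must satisfy
#'   `subregion_size > 2*overlap`. Default: 3 x median precision, clamped to
#'   0.45 x `subregion_size` (the precision distribution is heavy-tailed, so a
#'   high quantile would exceed small boxes).
#' @param extent Analysis region `c(xmin, xmax, ymin, ymax)` in nm; default is
#'   the data bounding box. Tiles cover this region; localizations outside
#'   every extended tile are not analysed (with exponentially distributed
#'   photon counts a small fraction of localizations has very poor precision
#'   and lands far outside the imaged field -- restricting the analysis to the
#'   field keeps them from seeding spurious emitters in otherwise empty
#'   space, while strays inside the field are simply absorbed by nearby
#'   emitters).
#' @return List of class `"tiling_plan"`: data frame `tiles` with core and
#'   extended bounds, list `members` of localization indices per tile, and the
#'   overall extent.
#' @export
make_tiling <- function(set, subregion_size, overlap = NULL, extent = NULL) {
  set <- validate_localizations(set)
  stopifnot(nrow(set) > 0, subregion_size > 0)
  if (is.null(overlap))
    overlap <- min(3 * stats::median(c(set$sigma_x, set$sigma_y)),
                   0.45 * subregion_size)
  stopifnot(subregion_size > 2 * overlap)
  if (is.null(extent))
    extent <- c(min(set$x), max(set$x), min(set$y), max(set$y))
  x0 <- extent[1]; y0 <- extent[3]
  nbx <- max(1L, ceiling((extent[2] - x0 - 1e-9) / subregion_size))
  nby <- max(1L, ceiling((extent[4] - y0 - 1e-9) / subregion_size))
  tiles <- expand.grid(ix = seq_len(nbx) - 1L, iy = seq_len(nby) - 1L)
  tiles$cx0 <- x0 + tiles$ix * subregion_size
  tiles$cx1 <- tiles$cx0 + subregion_size
  tiles$cy0 <- y0 + tiles$iy * subregion_size
  tiles$cy1 <- tiles$cy0 + subregion_size
  tiles$ex0 <- tiles$cx0 - overlap; tiles$ex1 <- tiles$cx1 + overlap
  tiles$ey0 <- tiles$cy0 - overlap; tiles$ey1 <- tiles$cy1 + overlap
  members <- vector("list", nrow(tiles))
  ox <- order(set$x)
  xs <- set$x[ox]
  for (ti in seq_len(nrow(tiles))) {
    lo <- findInterval(tiles$ex0[ti], xs) + 1L
    hi <- findInterval(tiles$ex1[ti], xs)
    if (hi < lo) { members[[ti]] <- integer(0); next }
    cand <- ox[lo:hi]
    members[[ti]] <- cand[set$y[cand] >= tiles$ey0[ti] & set$y[cand] <= tiles$ey1[ti]]
  }
  nmax <- max(vapply(members, length, integer(1)))
  if (nmax > 5000)
    warning("a subregion holds ", nmax,
            " localizations; consider a smaller subregion_size")
  structure(list(tiles = tiles, members = members, overlap = overlap,
                 subregion_size = subregion_size,
                 extent = c(x0, x0 + nbx * subregion_size,
                            y0, y0 + nby * subregion_size)),
            class = "tiling_plan")
}

#' Stitch per-tile MAPN results
#'
#' Keeps, from each tile, only the MAPN emitters whose positions fall in the
#' tile's half-open core area (emitters in the overlap strips are the
#' neighbouring tile's responsibility), and concatenates them, so each emitter
#' appears exactly once.
#'
#' @param results List of `"mapn_result"` objects, one per tile of `plan`.
#' @param plan The `"tiling_plan"` used to produce them.
#' @return Combined `"mapn_result"` (with a `tile` column).
#' @export
stitch <- function(results, plan) {
  stopifnot(inherits(plan, "tiling_plan"), length(results) == nrow(plan$tiles))
  parts <- lapply(seq_along(results), function(ti) {
    em <- results[[ti]]$emitters
    if (is.null(em) || nrow(em) == 0) return(NULL)
    tl <- plan$tiles[ti, ]
    # half-open cores; boundary tiles own everything out to their extended
    # bounds (an emitter estimated just outside the field edge has no other
    # tile to claim it)
    xlo <- if (tl$ix == 0) tl$ex0 else tl$cx0
    ylo <- if (tl$iy == 0) tl$ey0 else tl$cy0
    xhi_b <- tl$cx1 >= plan$extent[2]
    yhi_b <- tl$cy1 >= plan$extent[4]
    xhi <- if (xhi_b) em$x <= tl$ex1 else em$x < tl$cx1
    yhi <- if (yhi_b) em$y <= tl$ey1 else em$y < tl$cy1
    keep <- em$x >= xlo & xhi & em$y >= ylo & yhi
    if (!any(keep)) return(NULL)
    cbind(em[keep, , drop = FALSE], tile = ti)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  em <- if (length(parts) > 0) do.call(rbind, parts) else
    data.frame(x = numeric(0), y = numeric(0), sigma_x = numeric(0),
               sigma_y = numeric(0), ax = numeric(0), ay = numeric(0),
               n_loc = numeric(0), n_samples = integer(0), tile = integer(0))
  rownames(em) <- NULL
  structure(list(emitters = em, K_map = nrow(em), freq = NA_real_),
            class = "mapn_result")
}
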