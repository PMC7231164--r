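#' Two-dimensional kernel density on a regular lattice
#'
#' Product-Gaussian kernel density estimate (via [MASS::kde2d()]) on a
#' `grid_n` x `grid_n` lattice. Bandwidths default to the normal reference
#' rule per axis; the lattice spans the coordinate range padded by one
#' bandwidth so the density mass is captured.
#'
#' @param points two-column matrix (or data frame) of coordinates.
#' @param grid_n lattice points per axis (default 100).
#' @param bandwidth numeric of length 1 or 2; default normal reference rule
#'   ([MASS::bandwidth.nrd()]) per axis.
#' @param lims optional `c(xmin, xmax, ymin, ymax)` overriding the padded
#'   range (used to place several densities on a shared lattice).
#' @return A list of class `kde2d_grid`: `x`, `y` (lattice coordinates),
#'   `z` (density matrix, `z[i, j]` at `(x[i], y[j])`), `bandwidth`.
#' @export
kde2d_grid <- function(points, grid_n = 100, bandwidth = NULL, lims = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2)
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(points[, 1]),
                   MASS::bandwidth.nrd(points[, 2]))
  }
  bandwidth <- rep_len(bandwidth, 2)
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0)) {
    stop("zero variance on an axis: bandwidth undefined")
  }
  if (is.null(lims)) {
    lims <- c(range(points[, 1]) + c(-1, 1) * bandwidth[1],
              range(points[, 2]) + c(-1, 1) * bandwidth[2])
  }
  d <- MASS::kde2d(points[, 1], points[, 2], h = bandwidth, n = grid_n,
                   lims = lims)
  structure(list(x = d$x, y = d$y, z = d$z, bandwidth = bandwidth),
            class = "kde2d_grid")
}

#' Trapezoid-rule integral of a lattice density
#'
#' @param grid a `kde2d_grid` or any list with `x`, `y`, `z`.
#' @return Scalar integral over the lattice.
#' @export
lattice_integral <- function(grid) {
  # trapezoid rule along x for each y, then along y
  inner <- apply(grid$z, 2, function(col) pracma::trapz(grid$x, col))
  pracma::trapz(grid$y, inner)
}

#' Relative survival-probability surface over genotype space
#'
#' Difference between the post-selection (juvenile) and pre-selection
#' (larval) kernel densities of individual coordinates in the plane of the
#' two leading genotype PCs. Positive values mark multilocus genotypes
#' enriched among survivors; negative values mark depleted genotypes. Both
#' densities share one lattice and one bandwidth (normal reference rule on
#' the pooled coordinates) so the difference is not confounded by smoothing.
#'
#' @param coords_post two-column coordinates of the post-selection group.
#' @param coords_pre two-column coordinates of the pre-selection baseline.
#' @param grid_n lattice points per axis (default 100).
#' @param bandwidth optional shared bandwidth (length 1 or 2); default
#'   normal reference rule on the pooled coordinates.
#' @return A list of class `survival_surface`: `x`, `y`, `z`
#'   (post minus pre density), `dens_post`, `dens_pre` (the two
#'   `kde2d_grid`s), `bandwidth`.
#' @export
survival_surface <- function(coords_post, coords_pre, grid_n = 100,
                             bandwidth = NULL) {
  coords_post <- as.matrix(coords_post)
  coords_pre <- as.matrix(coords_pre)
  stopifnot(nrow(coords_post) >= 2, nrow(coords_pre) >= 2,
            ncol(coords_post) == 2, ncol(coords_pre) == 2)
  pooled <- rbind(coords_post, coords_pre)
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(pooled[, 1]),
                   MASS::bandwidth.nrd(pooled[, 2]))
  }
  bandwidth <- rep_len(bandwidth, 2)
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0)) {
    stop("zero variance on an axis: bandwidth undefined")
  }
  lims <- c(range(pooled[, 1]) + c(-1, 1) * bandwidth[1],
            range(pooled[, 2]) + c(-1, 1) * bandwidth[2])
  d_post <- kde2d_grid(coords_post, grid_n, bandwidth, lims)
  d_pre <- kde2d_grid(coords_pre, grid_n, bandwidth, lims)
  structure(
    list(x = d_post$x, y = d_post$y, z = d_post$z - d_pre$z,
         dens_post = d_post, dens_pre = d_pre, bandwidth = bandwidth),
    class = "survival_surface"
  )
}

#' Project individuals onto a survival surface
#'
#' Bilinear interpolation of the surface value at each individual's
#' coordinates, giving per-individual relative survival scores. Points
#' outside the lattice hull are clipped to its edge and flagged.
#'
#' @param coords two-column matrix of individual coordinates (row names are
#'   kept as score names).
#' @param surface a [survival_surface()] (or `kde2d_grid`).
#' @return Numeric vector of scores with attributes `"clipped"` (logical
#'   vector) and `"positive_fraction"` (share of scores > 0).
#' @export
project_survival_scores <- function(coords, surface) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  xp <- pmin(pmax(coords[, 1], min(surface$x)), max(surface$x))
  yp <- pmin(pmax(coords[, 2], min(surface$y)), max(surface$y))
  clipped <- xp != coords[, 1] | yp != coords[, 2]
  # interp2 expects length(x) == ncol(Z): transpose the x-by-y lattice
  scores <- pracma::interp2(surface$x, surface$y, t(surface$z), xp, yp,
                            method = "linear")
  names(scores) <- rownames(coords)
  attr(scores, "clipped") <- clipped
  attr(scores, "positive_fraction") <- mean(scores > 0)
  scores
}

#' Survival-score trade-off ANCOVA
#'
#' Tests whether the polygenic score of alleles favored in one habitat
#' predicts relative survival with opposite slopes in the two habitats:
#' `survival_score ~ habitat * polygenic_score` via [ancova_interaction()].
#'
#' @param survival_score named numeric vector, each individual's survival
#'   score on its own habitat's surface.
#' @param polygenic_score named numeric vector (e.g. `score_a`).
#' @param habitat named habitat labels.
#' @return An `ancova_fit`.
#' @export
survival_tradeoff_ancova <- function(survival_score, polygenic_score,
                                     habitat) {
  ids <- Reduce(intersect, list(names(survival_score),
                                names(polygenic_score), names(habitat)))
  if (length(ids) < 10) stop("too few individuals shared across inputs")
  ancova_interaction(survival_score[ids], polygenic_score[ids], habitat[ids])
}

#' Write a surface lattice to TSV (long format)
#'
#' @param surface a `survival_surface` or `kde2d_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surface, path) {
  df <- expand.grid(x = surface$x, y = surface$y)
  df$z <- as.vector(surface$z)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
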