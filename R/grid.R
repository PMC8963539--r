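#' Regular discretization of a latent space
#'
#' Builds a uniform grid over a 1- or 2-dimensional latent space. All
#' probability-mass vectors in the package (priors, posteriors, likelihood
#' fields) live on such a grid, one entry per cell, following the convention
#' mass = density x cell measure so that normalized fields sum to exactly 1.
#'
#' @param n_dims Number of latent dimensions, 1 or 2.
#' @param bounds Numeric length-2 vector, the closed interval covered by each
#'   dimension (the same interval is used for every dimension).
#' @param bins_per_dim Number of cells per dimension.
#' @return An object of class \code{latent_grid} with elements
#'   \code{n_dims}, \code{bounds}, \code{bins_per_dim}, \code{axis} (cell
#'   centers along one dimension), \code{centers} (n_cells x n_dims matrix of
#'   cell-center coordinates), \code{n_cells} and \code{cell_measure}.
#' @examples
#' g <- latent_grid(2, c(-5, 5), 21)
#' g$n_cells       # 441
#' g$cell_measure  # (10/21)^2
#' @export
latent_grid <- function(n_dims = 2L, bounds = c(-5, 5), bins_per_dim = 85L) {
  stopifnot(n_dims %in% c(1L, 2L), length(bounds) == 2L, bounds[2] > bounds[1],
            bins_per_dim >= 2L)
  width <- (bounds[2] - bounds[1]) / bins_per_dim
  axis <- bounds[1] + width * (seq_len(bins_per_dim) - 0.5)
  if (n_dims == 1L) {
    centers <- matrix(axis, ncol = 1L)
  } else {
    # column-major: first coordinate varies fastest
    centers <- as.matrix(expand.grid(x = axis, y = axis, KEEP.OUT.ATTRS = FALSE))
  }
  structure(list(n_dims = as.integer(n_dims), bounds = as.numeric(bounds),
                 bins_per_dim = as.integer(bins_per_dim), axis = axis,
                 centers = unname(centers),
                 n_cells = as.integer(bins_per_dim^n_dims),
                 cell_measure = width^n_dims),
            class = "latent_grid")
}

#' @export
print.latent_grid <- function(x, ...) {
  cat(sprintf("latent_grid: %dD, [%g, %g], %d bins/dim (%d cells, cell measure %.4g)\n",
              x$n_dims, x$bounds[1], x$bounds[2], x$bins_per_dim, x$n_cells,
              x$cell_measure))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n_dims == b$n_dims && a$bins_per_dim == b$bins_per_dim &&
    isTRUE(all.equal(a$bounds, b$bounds))
}

#' Probability mass field on a latent grid
#'
#' A nonnegative mass vector with one entry per grid cell. Normalized fields
#' (priors, posteriors) sum to 1; unnormalized fields are used for likelihood
#' evaluations over the grid.
#'
#' @param grid A \code{latent_grid}.
#' @param mass Nonnegative numeric vector, one value per cell.
#' @param normalized Logical; if \code{TRUE} the mass is rescaled to sum to 1.
#' @return An object of class \code{probability_field}.
#' @export
probability_field <- function(grid, mass, normalized = TRUE) {
  stopifnot(inherits(grid, "latent_grid"), length(mass) == grid$n_cells)
  if (any(!is.finite(mass)) || any(mass < 0))
    stop("mass must be finite and nonnegative")
  if (normalized) {
    tot <- sum(mass)
    if (tot <= 0) stop("cannot normalize an all-zero field")
    mass <- mass / tot
  }
  structure(list(grid = grid, mass = as.numeric(mass), normalized = normalized),
            class = "probability_field")
}

#' @export
print.probability_field <- function(x, ...) {
  cat(sprintf("probability_field on %d cells (%s, total mass %.6g)\n",
              x$grid$n_cells, if (x$normalized) "normalized" else "unnormalized",
              sum(x$mass)))
  invisible(x)
}

#' @export
plot.probability_field <- function(x, ...) {
  g <- x$grid
  if (g$n_dims == 1L) {
    graphics::plot(g$axis, x$mass, type = "l", xlab = "x", ylab = "mass", ...)
  } else {
    z <- matrix(x$mass, g$bins_per_dim, g$bins_per_dim)
    graphics::image(g$axis, g$axis, z, xlab = "x", ylab = "y", ...)
  }
  invisible(x)
}

#' Uniform field on a grid
#' @param grid A \code{latent_grid}.
#' @return A normalized \code{probability_field} with equal mass in all cells.
#' @export
uniform_field <- function(grid) {
  probability_field(grid, rep(1, grid$n_cells), normalized = TRUE)
}

#' Entropy of a probability field (mass convention)
#'
#' Shannon entropy \code{-sum(m * log m)} of the mass vector itself, so the
#' uniform field on n cells has entropy log(n). Zero-mass cells contribute 0.
#' @param field A normalized \code{probability_field}.
#' @return Scalar entropy in nats.
#' @export
field_entropy <- function(field) {
  m <- field$mass
  pos <- m > 0
  -sum(m[pos] * log(m[pos]))
}

#' Total-variation distance between two fields on the same grid
#' @param a,b Normalized \code{probability_field}s on a shared grid.
#' @return Scalar in [0, 1].
#' @export
field_tv <- function(a, b) {
  stopifnot(same_grid(a$grid, b$grid))
  0.5 * sum(abs(a$mass - b$mass))
}
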