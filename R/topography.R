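#' Surface topography maps
#'
#' Per-chain profiles (height, RMSF, hydration) become 2D surface maps:
#' each chain's value is placed at its lattice cell, every cavity between
#' a 2x2 chain neighbourhood takes the mean of its four surrounding
#' chains — using periodic neighbours at the grid edges — and the matrix
#' is bilinearly interpolated (5 pixels per cell interval) and smoothed
#' (5 passes of a 5-point moving average) into the final map.
#'
#' @name topography
NULL

#' Build the chain/cavity surface matrix from a chain profile
#'
#' The expanded matrix has chain cells at odd (row, column) positions in
#' lattice order and cavity cells between them; a cavity surrounded by
#' chains k, m, n, o takes their arithmetic mean, with wrap-around
#' neighbours across the periodic edges. Cells between two adjacent
#' chains along one axis take the mean of those two (the degenerate 2x2
#' neighbourhood). Chain cells preserve the profile values bit-exactly.
#'
#' @param profile A `chain_profile` (or data frame with `grid_i`,
#'   `grid_j`, `value`).
#' @param grid The `grafting_grid`.
#' @return A `surface_matrix`: list with `values` (a `2 n_x` by `2 n_y`
#'   matrix; rows follow x), `grid`, and `extent` in Angstrom.
#' @export
build_matrix <- function(profile, grid) {
  stopifnot(inherits(grid, "grafting_grid"))
  if (nrow(profile) != n_chains(grid))
    stop(sprintf("profile has %d values for %d grid chains",
                 nrow(profile), n_chains(grid)))
  nx <- grid$n_x; ny <- grid$n_y
  chain_vals <- matrix(NA_real_, nx, ny)
  chain_vals[cbind(profile$grid_i, profile$grid_j)] <- profile$value
  if (anyNA(chain_vals)) stop("profile does not cover every grid cell")
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  M <- matrix(NA_real_, 2L * nx, 2L * ny)
  for (i in seq_len(nx)) {
    ip <- wrap(i + 1L, nx)
    for (j in seq_len(ny)) {
      jp <- wrap(j + 1L, ny)
      M[2L * i - 1L, 2L * j - 1L] <- chain_vals[i, j]
      M[2L * i, 2L * j - 1L] <- (chain_vals[i, j] + chain_vals[ip, j]) / 2
      M[2L * i - 1L, 2L * j] <- (chain_vals[i, j] + chain_vals[i, jp]) / 2
      M[2L * i, 2L * j] <- (chain_vals[i, j] + chain_vals[ip, j] +
                              chain_vals[i, jp] + chain_vals[ip, jp]) / 4
    }
  }
  out <- list(values = M, grid = grid,
              extent = c(x = grid$box_x, y = grid$box_y))
  class(out) <- "surface_matrix"
  out
}

# Matlab-style span-5 moving average: symmetric shrinking windows at the
# ends (y1 = x1, y2 = mean(x1:x3), interior = mean of 5).
smooth5 <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  cs <- cumsum(c(0, x))
  y <- x
  for (i in seq_len(n)) {
    h <- min(2L, i - 1L, n - i)
    y[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  y
}

#' Interpolate and smooth a surface matrix into a map
#'
#' Bilinear interpolation refines each cell interval into
#' `pixels_per_cell` steps, then `passes` applications of a 5-point
#' moving average are run along each axis (rows, then columns, per
#' pass); edge windows shrink symmetrically so constants are preserved.
#'
#' @param matrix A `surface_matrix`.
#' @param pixels_per_cell Interpolation refinement per interval
#'   (default 5).
#' @param passes Number of smoothing passes (default 5).
#' @return A `surface_map`: list with `values`, `extent`,
#'   `pixels_per_cell`, `passes`.
#' @export
interpolate_and_smooth <- function(matrix, pixels_per_cell = 5L,
                                   passes = 5L) {
  stopifnot(inherits(matrix, "surface_matrix"))
  if (pixels_per_cell < 1L) stop("pixels_per_cell must be >= 1")
  if (passes < 0L) stop("passes must be >= 0")
  M <- matrix$values
  if (nrow(M) < 2L || ncol(M) < 2L) stop("matrix must be at least 2 x 2")
  p <- as.integer(pixels_per_cell)
  interp_vec <- function(v, p) {
    n <- length(v)
    xi <- seq(1, n, by = 1 / p)
    stats::approx(seq_len(n), v, xout = xi)$y
  }
  fine_rows <- t(apply(M, 1, interp_vec, p = p))
  fine <- apply(fine_rows, 2, interp_vec, p = p)
  for (k in seq_len(passes)) {
    fine <- t(apply(fine, 1, smooth5))
    fine <- apply(fine, 2, smooth5)
  }
  out <- list(values = fine, extent = matrix$extent,
              pixels_per_cell = p, passes = as.integer(passes))
  class(out) <- "surface_map"
  out
}

#' Render a surface map to a matrix file and a raster image
#'
#' Writes the map values as a tab-delimited numeric matrix (with a
#' provenance header) and, optionally, a PNG raster with a labelled
#' colour scale. Output is deterministic for a fixed map.
#'
#' @param map A `surface_map`.
#' @param path Output path stem; writes `<path>.tsv` and `<path>.png`.
#' @param window_tag One of `"avg_last100ns"`, `"first_converged"`,
#'   `"final"` — recorded in the header.
#' @param metric Metric name for the colour-scale label.
#' @param png Write the raster too (default `TRUE`).
#' @param zlim Colour scale limits (default: data range).
#' @return Invisibly, the matrix file path.
#' @export
render_map <- function(map, path,
                       window_tag = c("avg_last100ns", "first_converged",
                                      "final"),
                       metric = "value", png = TRUE, zlim = NULL) {
  stopifnot(inherits(map, "surface_map"))
  window_tag <- match.arg(window_tag)
  tsv <- paste0(path, ".tsv")
  dir.create(dirname(tsv), recursive = TRUE, showWarnings = FALSE)
  con <- try(file(tsv, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", tsv)
  writeLines(sprintf("# surface_map\t%s\t%s\textent\t%.6f\t%.6f\tpixels_per_cell\t%d\tpasses\t%d",
                     metric, window_tag, map$extent[1], map$extent[2],
                     map$pixels_per_cell, map$passes), con)
  utils::write.table(format(map$values, digits = 12, trim = TRUE),
                     con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  close(con)
  if (png) {
    grDevices::png(paste0(path, ".png"), width = 640, height = 560)
    on.exit(grDevices::dev.off())
    if (is.null(zlim)) zlim <- range(map$values)
    if (diff(zlim) == 0) zlim <- zlim + c(-0.5, 0.5)
    nr <- nrow(map$values); nc <- ncol(map$values)
    graphics::layout(matrix(1:2, 1), widths = c(4, 1))
    graphics::par(mar = c(4, 4, 3, 1))
    graphics::image(x = seq(0, map$extent[1], length.out = nr),
                    y = seq(0, map$extent[2], length.out = nc),
                    z = map$values, zlim = zlim,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "x (A)", ylab = "y (A)",
                    main = sprintf("%s (%s)", metric, window_tag))
    graphics::par(mar = c(4, 1, 3, 3))
    scale_vals <- seq(zlim[1], zlim[2], length.out = 64)
    graphics::image(x = 1, y = scale_vals,
                    z = matrix(scale_vals, 1), zlim = zlim,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xaxt = "n", xlab = "", ylab = "")
  }
  invisible(tsv)
}
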