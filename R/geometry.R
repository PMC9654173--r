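#' Minimum-image distance under slab periodicity
#'
#' Euclidean distance between two points after wrapping the periodic
#' components into `[-L/2, L/2]`. The surface is periodic in x and y only;
#' z (the surface normal) is never wrapped: the box has bulk solvent above
#' the brush and a grafting plane below.
#'
#' @param p1,p2 Numeric vectors of length 3, or matrices with 3 columns
#'   (rows are paired; one may be a single point).
#' @param box Numeric vector of box lengths (x, y, z) in Angstrom. Only the
#'   periodic components are used.
#' @param periodic Logical vector of length 3; defaults to xy-periodic.
#' @return Numeric vector of distances in Angstrom.
#' @examples
#' min_image_distance(c(1, 0, 0), c(99, 0, 0), box = c(100, 100, 100)) # 2
#' @export
min_image_distance <- function(p1, p2, box,
                               periodic = c(TRUE, TRUE, FALSE)) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 3L)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 3L)
  if (any(periodic & box[seq_len(3)] <= 0))
    stop("box lengths must be positive on periodic axes")
  d <- wrap_deltas(
    p1[rep_len(seq_len(nrow(p1)), max(nrow(p1), nrow(p2))), , drop = FALSE] -
      p2[rep_len(seq_len(nrow(p2)), max(nrow(p1), nrow(p2))), , drop = FALSE],
    box, periodic)
  sqrt(rowSums(d * d))
}

# Wrap a displacement matrix (n x 3) into the minimum image.
wrap_deltas <- function(d, box, periodic = c(TRUE, TRUE, FALSE)) {
  for (ax in which(periodic)) {
    L <- box[ax]
    d[, ax] <- d[, ax] - L * round(d[, ax] / L)
  }
  d
}

# All minimum-image distances between two coordinate sets (n x 3, m x 3)
# at a single frame; returns an n x m matrix.
min_image_cross <- function(a, b, box, periodic = c(TRUE, TRUE, FALSE)) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d <- wrap_deltas(a - matrix(b[j, ], n, 3, byrow = TRUE), box, periodic)
    out[, j] <- sqrt(rowSums(d * d))
  }
  out
}

# Elementary rotation matrices (angles in degrees).
rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
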