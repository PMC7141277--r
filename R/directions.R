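#' Hemispherical direction sets from icosahedral tessellation
#'
#' The orientation distribution function is evaluated on the vertices of a
#' k-times-subdivided icosahedron projected to the unit sphere. Because an
#' ODF is antipodally symmetric, only one hemisphere is kept (z > 0, ties
#' broken by y then x), giving (10 * 4^k + 2) / 2 directions.
#'
#' @param order subdivision order k (>= 0); k = 3 (321 directions) is the
#'   reconstruction default.
#' @return an object of class `direction_set`: an n x 3 matrix of unit row
#'   vectors with attribute `order`.
#' @examples
#' nrow(make_direction_set(0))  # 6
#' nrow(make_direction_set(3))  # 321
#' @export
make_direction_set <- function(order = 3) {
  if (length(order) != 1 || is.na(order) || order < 0)
    stop_invalid("order must be a single integer >= 0")
  order <- as.integer(order)
  ico <- icosahedron()
  verts <- ico$verts
  faces <- ico$faces
  k <- 0
  while (k < order) {
    s <- subdivide_once(verts, faces)
    verts <- s$verts
    faces <- s$faces
    k <- k + 1
  }
  hemi <- hemisphere_select(verts)
  structure(hemi, order = order, class = c("direction_set", "matrix", "array"))
}

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(verts = v, faces = f)
}

# Split each triangle into four; shared edge midpoints are created once
# (cache keyed on the vertex index pair) so meshes stay watertight and
# vertex coordinates coincide exactly across neighbouring faces.
subdivide_once <- function(verts, faces) {
  cache <- new.env(hash = TRUE)
  vlist <- asplit(verts, 1)
  midpoint <- function(i, j) {
    key <- paste0(min(i, j), "_", max(i, j))
    idx <- cache[[key]]
    if (!is.null(idx)) return(idx)
    m <- vlist[[i]] + vlist[[j]]
    m <- m / sqrt(sum(m^2))
    vlist[[length(vlist) + 1]] <<- m
    idx <- length(vlist)
    cache[[key]] <- idx
    idx
  }
  newf <- matrix(0L, nrow(faces) * 4, 3)
  r <- 1
  for (fi in seq_len(nrow(faces))) {
    a <- faces[fi, 1]; b <- faces[fi, 2]; c3 <- faces[fi, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
    newf[r, ] <- c(a, ab, ca)
    newf[r + 1, ] <- c(b, bc, ab)
    newf[r + 2, ] <- c(c3, ca, bc)
    newf[r + 3, ] <- c(ab, bc, ca)
    r <- r + 4
  }
  list(verts = do.call(rbind, vlist), faces = newf)
}

hemisphere_select <- function(verts, tol = 1e-9) {
  z <- verts[, 3]; y <- verts[, 2]; x <- verts[, 1]
  keep <- z > tol |
    (abs(z) <= tol & (y > tol | (abs(y) <= tol & x > tol)))
  unname(verts[keep, , drop = FALSE])
}

#' Nearest-neighbour angular spacing of a direction set
#'
#' For each direction, the smallest angle to any other direction under the
#' axial metric `acos(|u . v|)` (fiber orientations are sign-free). The
#' maximum of these per-direction minima bounds the worst-case error of
#' assigning an arbitrary axis to its closest sampled direction.
#'
#' @param dirs a `direction_set` (or any n x 3 matrix of unit rows).
#' @return the maximum nearest-neighbour angle, in radians.
#' @export
nn_angular_spacing <- function(dirs) {
  d <- abs(dirs %*% t(dirs))
  diag(d) <- 0
  max(acos(pmin(1, apply(d, 1, max))))
}

#' Angle between two axes (sign-free), in radians
#' @param u,v unit 3-vectors.
#' @return angle in [0, pi/2].
#' @export
axis_angle <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))))
}
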