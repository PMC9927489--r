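#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation plus a translation, the currency of
#' every superposition and transfer step in the package. Coordinates are in
#' Angstrom in a right-handed frame; a transform acts as \eqn{x \mapsto Rx + t}.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation numeric 3-vector, Angstrom.
#' @return An object of class \code{rigid_transform} with elements
#'   \code{rotation} and \code{translation}.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 2, 3))
#' apply_transform(t1, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal (R'R != I within 1e-8)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation determinant is ", format(det(rotation)),
         ", not +1: improper rotation (reflection) rejected")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (x -> R x + t)\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (A): ", paste(round(x$translation, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to coordinates, an atom table, or a structure
#'
#' Every coordinate is mapped as \eqn{x \mapsto Rx + t}; all non-coordinate
#' fields are preserved.
#'
#' @param transform a \code{\link{rigid_transform}}.
#' @param x an n x 3 coordinate matrix, an atom \code{data.frame} with
#'   \code{x}, \code{y}, \code{z} columns, or a \code{\link{structure3d}}.
#' @return The same kind of object with transformed coordinates.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "structure3d")) {
    x$atoms <- apply_transform(transform, x$atoms)
    return(x)
  }
  if (is.data.frame(x)) {
    xyz <- apply_transform(transform, as.matrix(x[, c("x", "y", "z")]))
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    return(x)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  sweep(x %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose and invert rigid transforms
#'
#' \code{compose_transform(t2, t1)} returns the transform equivalent to
#' applying \code{t1} first and then \code{t2}; successive superpositions in
#' the binder-transfer procedure compose into a single placement this way.
#'
#' @param t1,t2,transform \code{\link{rigid_transform}} objects.
#' @return A \code{rigid_transform}.
#' @export
compose_transform <- function(t2, t1) {
  stopifnot(inherits(t1, "rigid_transform"), inherits(t2, "rigid_transform"))
  rot <- t2$rotation %*% t1$rotation
  # re-orthonormalise to keep the invariant under accumulated rounding
  sv <- svd(rot)
  rot <- sv$u %*% t(sv$v)
  rigid_transform(rot, as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rt <- t(transform$rotation)
  rigid_transform(rt, as.numeric(-rt %*% transform$translation))
}

#' Rotation about a coordinate axis (convenience constructor)
#'
#' @param axis one of "x", "y", "z".
#' @param angle rotation angle in degrees.
#' @param translation optional translation, Angstrom.
#' @return A \code{\link{rigid_transform}}.
#' @export
axis_rotation <- function(axis = c("z", "x", "y"), angle, translation = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  rot <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca)),
    y = rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca)),
    z = rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)))
  rigid_transform(rot, translation)
}

#' Random rigid transform (uniform rotation)
#'
#' Draws a rotation uniformly over SO(3) (via a normalised random quaternion)
#' and a translation with independent normal components. Used by the
#' synthetic-structure generator and by property tests.
#'
#' @param translation_sd standard deviation of each translation component, Angstrom.
#' @return A \code{\link{rigid_transform}}.
#' @export
random_transform <- function(translation_sd = 10) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  rigid_transform(rot, stats::rnorm(3, sd = translation_sd))
}
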