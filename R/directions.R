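#' Near-uniform axial direction set on the upper hemisphere
#'
#' Generates `n` unit vectors by the spherical Fibonacci construction,
#' restricted to the upper hemisphere (all Z components > 0).  Directions
#' are axial: v and -v denote the same sampling direction, so one
#' hemisphere suffices.  The construction is deterministic; `seed` is
#' accepted for interface stability but unused by the default scheme.
#'
#' @param n Number of directions (>= 6; a fabric fit needs at least six
#'   independent directions).
#' @param seed Ignored by the deterministic default scheme.
#' @return A `direction_set`: an `n x 3` matrix of unit row vectors.
#' @examples
#' d <- sample_directions(32)
#' range(rowSums(d^2)) # all 1
#' @export
sample_directions <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 6 || n != round(n))
    stop("n must be an integer >= 6 (fabric fit needs >= 6 directions)",
         call. = FALSE)
  n <- as.integer(n)
  i <- seq_len(n)
  z <- (i - 0.5) / n                      # uniform in z over (0, 1)
  golden <- (1 + sqrt(5)) / 2
  phi <- 2 * pi * i / golden
  r <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(r * cos(phi), r * sin(phi), z)
  d <- d / sqrt(rowSums(d^2))             # renormalize to 1e-12
  dimnames(d) <- list(NULL, c("dx", "dy", "dz"))
  structure(d, class = c("direction_set", "matrix", "array"))
}

#' Canonical sign for an axial unit vector
#'
#' Fiber orientations are axial (v and -v are the same fiber).  The
#' canonical representative has a positive component along the axis of
#' largest magnitude; ties are broken by the first axis in X, Y, Z order
#' among the tied maxima.
#'
#' @param v Unit 3-vector (or a matrix of row vectors).
#' @return `v` or `-v` (rowwise for matrices).
#' @examples
#' canonicalize_axial(c(-0.9, 0.3, 0.1))
#' @export
canonicalize_axial <- function(v) {
  if (is.matrix(v)) {
    return(t(apply(v, 1, canonicalize_axial)))
  }
  if (length(v) != 3L)
    stop("v must be a 3-vector", call. = FALSE)
  nv <- sqrt(sum(v^2))
  if (nv == 0)
    stop("cannot canonicalize a zero vector", call. = FALSE)
  a <- abs(v)
  mx <- max(a)
  k <- which(a >= mx * (1 - 1e-12))[1]    # first of X, Y, Z among ties
  if (v[k] < 0) -v else v
}
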