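#' Fit an MIL fabric tensor to a directional MIL profile
#'
#' Fits the classic MIL ellipsoid `1 / MIL(n)^2 = n' M n` by least
#' squares over the directions with at least one intercept.  The
#' symmetric matrix `M` (units um^-2) is the ellipsoid form of the
#' fabric; the length-scale eigenvalues reported are `lambda_i =
#' 1/sqrt(mu_i)` for the eigenvalues `mu_i` of `M`, sorted so that
#' `lambda_1 >= lambda_2 >= lambda_3 > 0`.  Eigenvector column `i` is
#' paired with `lambda_i` and sign-canonicalized with
#' [canonicalize_axial()]; the first column is the primary direction of
#' the material (the long axis of the MIL ellipsoid).
#'
#' Directions with zero intercepts are dropped from the fit, not
#' imputed.  Fewer than six usable directions, a rank-deficient design,
#' or a fitted `M` that is not positive definite raise errors; the
#' degenerate case signals a condition of class
#' `fibrefab_degenerate_fabric` carrying the fitted matrix in its
#' `tensor` field.
#'
#' @param profile A `mil_profile` from [compute_mil()].
#' @return A `fabric_tensor`: list with `tensor` (3x3, um^-2),
#'   `eigenvalues_um` (descending), `eigenvectors` (orthonormal columns,
#'   canonicalized), `n_directions_used`.
#' @export
fit_fabric_tensor <- function(profile) {
  if (!inherits(profile, "mil_profile"))
    stop("profile must be a mil_profile from compute_mil()", call. = FALSE)
  ok <- profile$intercept_count > 0 & is.finite(profile$mil_um)
  if (sum(ok) < 6)
    stop("fabric fit needs >= 6 directions with defined MIL (got ",
         sum(ok), ")", call. = FALSE)
  d <- as.matrix(profile[ok, c("dx", "dy", "dz")])
  y <- 1 / profile$mil_um[ok]^2
  D <- cbind(d[, 1]^2, d[, 2]^2, d[, 3]^2,
             2 * d[, 1] * d[, 2], 2 * d[, 1] * d[, 3], 2 * d[, 2] * d[, 3])
  qrD <- qr(D)
  if (qrD$rank < 6)
    stop("fabric fit design is rank deficient: directions do not span 3D",
         call. = FALSE)
  cf <- qr.coef(qrD, y)
  M <- matrix(c(cf[1], cf[4], cf[5],
                cf[4], cf[2], cf[6],
                cf[5], cf[6], cf[3]), 3, 3)
  eg <- eigen(M, symmetric = TRUE)        # values in decreasing order
  if (any(eg$values <= 0)) {
    stop(errorCondition(
      "fitted fabric is degenerate (ellipsoid form not positive definite)",
      class = c("fibrefab_degenerate_fabric", "fibrefab_fit_error"),
      tensor = M))
  }
  # small mu (long MIL) = long material axis, so reverse to descending lambda
  lambda <- 1 / sqrt(eg$values[3:1])
  vec <- eg$vectors[, 3:1, drop = FALSE]
  for (i in 1:3) vec[, i] <- canonicalize_axial(vec[, i])
  dimnames(vec) <- NULL
  structure(list(tensor = M, eigenvalues_um = lambda, eigenvectors = vec,
                 n_directions_used = sum(ok)),
            class = "fabric_tensor")
}

#' Degree of anisotropy of a fabric tensor
#'
#' The anisotropy index is `1 - lambda_3 / lambda_1` on the length-scale
#' eigenvalues: 0 for an isotropic fabric (all eigenvalues equal) and
#' approaching 1 for extreme alignment (`lambda_3 / lambda_1 -> 0`).  It
#' is invariant under uniform eigenvalue scaling, hence under voxel
#' rescaling.
#'
#' @param tensor A `fabric_tensor` from [fit_fabric_tensor()], or a
#'   numeric vector of length-scale eigenvalues sorted descending.
#' @return A number in `[0, 1]`.
#' @examples
#' anisotropy_index(c(10, 5, 2)) # 0.8
#' @export
anisotropy_index <- function(tensor) {
  lambda <- if (inherits(tensor, "fabric_tensor")) tensor$eigenvalues_um
            else tensor
  if (!is.numeric(lambda) || length(lambda) != 3L || any(lambda <= 0))
    stop("need three positive eigenvalues", call. = FALSE)
  if (is.unsorted(rev(lambda)))
    stop("eigenvalues must be sorted descending", call. = FALSE)
  1 - lambda[3] / lambda[1]
}

#' @export
print.fabric_tensor <- function(x, ...) {
  cat("<fabric_tensor> eigenvalues (um):",
      paste(signif(x$eigenvalues_um, 6), collapse = ", "),
      "| DA:", signif(anisotropy_index(x), 4),
      "| primary axis:",
      paste(signif(x$eigenvectors[, 1], 4), collapse = " "), "\n")
  invisible(x)
}
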