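#' Spiky kernel weight
#'
#' Cubic ("Spiky") SPH kernel in two dimensions,
#' \eqn{\xi(R) = 10 (h - R)^3 / (\pi h^5)} for \eqn{R < h} and 0 otherwise,
#' normalized so that \eqn{\int \xi \, dA = 1} over the support disk.
#'
#' @param distance reference inter-particle distance(s), micrometres.
#' @param support kernel support radius `h`, micrometres.
#' @return kernel weight(s), units 1/area.
#' @export
kernel_weight <- function(distance, support) {
  if (any(distance < 0)) stop("kernel_weight: negative distance")
  if (!is.numeric(support) || length(support) != 1L || support <= 0)
    stop("kernel_weight: support must be a positive scalar")
  cpp_kernel_weight(as.numeric(distance), support)
}

#' Spiky kernel gradient
#'
#' Referential gradient of the kernel,
#' \eqn{\nabla_X \xi = (\partial\xi/\partial R) R_j / R_j}: magnitude
#' \eqn{30 (h-R)^2/(\pi h^5)}, directed opposite the offset (the kernel
#' decreases away from the particle).  Offsets at or beyond the support give
#' a zero vector; a zero offset is defined as the zero vector (a particle is
#' never its own neighbour).
#'
#' @param offset reference offset vector(s): length-2 vector or n x 2 matrix.
#' @param support kernel support radius `h`.
#' @return n x 2 matrix of gradient vectors.
#' @export
kernel_gradient <- function(offset, support) {
  if (!is.matrix(offset)) offset <- matrix(offset, ncol = 2)
  if (support <= 0) stop("kernel_gradient: support must be positive")
  cpp_kernel_gradient(offset, support)
}

#' Smoothed field approximation
#'
#' Kernel-weighted approximation of a per-particle field,
#' \eqn{\hat g(X_i) = \sum_j g(X_j) V_j \xi(R_j)}, where the sum runs over
#' the particle's neighbour set plus its own (self) contribution
#' \eqn{g(X_i) V_i \xi(0)}, so that a constant field is reproduced up to the
#' discrete partition-of-unity defect of the lattice.
#'
#' @param values numeric vector, one value per particle.
#' @param model an [sph_model] with a built neighbour table.
#' @return numeric vector of smoothed values.
#' @export
approximate_field <- function(values, model) {
  nb <- model$nbr
  n <- nrow(model$X)
  stopifnot(length(values) == n)
  out <- values * model$V * kernel_weight(0, nb$h)  # self term
  ptr <- nb$ptr
  for (i in seq_len(n)) {
    e <- seq.int(ptr[i] + 1L, length.out = ptr[i + 1L] - ptr[i])
    e <- e[nb$alive[e]]
    if (!length(e)) next
    j <- nb$idx[e] + 1L
    out[i] <- out[i] + sum(values[j] * model$V[j] * nb$w[e])
  }
  out
}

#' Discrete partition of unity
#'
#' Returns \eqn{\sum_j V_j \xi(R_j)} (including the self term) for every
#' particle; interior particles of a uniform lattice should be within a few
#' percent of 1.
#'
#' @param model an [sph_model].
#' @return numeric vector.
#' @export
partition_of_unity <- function(model) {
  approximate_field(rep(1, nrow(model$X)), model)
}

#' Kernel-gradient correction matrices
#'
#' Returns the per-particle correction matrices
#' \eqn{A_i = \sum_j V_j \nabla_X \xi(R_j) \otimes R_j}, their inverses and
#' condition numbers.  Corrected gradients
#' \eqn{\tilde\nabla_X \xi = A_i^{-1} \nabla_X \xi} restore first-order
#' completeness of the discrete gradient operator, so affine deformations are
#' reproduced exactly even near boundaries.
#'
#' @param model an [sph_model].
#' @return list with `A` (n x 4 row-major 2x2), `Ainv`, `cond`.
#' @export
correction_matrix <- function(model) {
  nb <- model$nbr
  list(A = nb$A, Ainv = nb$Ainv, cond = nb$cond)
}

#' Per-particle deformation gradients
#'
#' Computes \eqn{F_i = \sum_j r_j \otimes V_j \tilde\nabla_X \xi(R_j)} from
#' current positions and the corrected-gradient neighbour table, appends the
#' fixed axial stretch, and returns the in-plane blocks together with
#' \eqn{J = \det(F_{2D}) \lambda_z}.
#'
#' @param model an [sph_model].
#' @param x current positions (n x 2); defaults to the model's current state.
#' @return list with `F` (n x 4, rows are `F11 F12 F21 F22`) and `J`.
#' @export
deformation_gradient <- function(model, x = model$state$x) {
  nb <- model$nbr
  out <- cpp_deformation(x, model$V, nb$ptr, nb$idx, nb$rot, nb$alive,
                         nb$cgrad, model$geom$sector, model$control$lambda_z)
  live <- model$mp[, 1] != 0
  if (any(out$J[live] <= 0))
    stop("deformation_gradient: element inversion (J <= 0) at particle(s) ",
         paste(head(which(live & out$J <= 0), 5), collapse = ", "))
  out
}
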