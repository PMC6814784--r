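#' Assemble an SPH model from a particle lattice
#'
#' Builds the neighbour table (with rotational-periodic sector images),
#' computes kernel weights, correction matrices and corrected gradients, and
#' initializes the kinematic state at the reference configuration.
#'
#' @param wall an [build_wall()] lattice.
#' @param support kernel support radius `h` in micrometres; defaults to
#'   3 x the nominal particle spacing, giving roughly 20-30 neighbours per
#'   interior particle in 2D.
#' @param control a [stabilization_params()] list.
#' @param cond_limit condition-number threshold above which a correction
#'   matrix is considered rank-deficient (boundary/neighbourhood defect).
#' @param periodic include rotational-periodic images across the sector
#'   edges (the physical setting; `FALSE` gives a free-edged sector, useful
#'   for operator verification).
#' @return object of class `sph_model` (inherits the lattice fields).
#' @export
sph_model <- function(wall, support = NULL,
                      control = stabilization_params(),
                      cond_limit = 1e8, periodic = TRUE) {
  if (is.null(support)) support <- 3 * wall$spacing
  if (support <= 0) stop("sph_model: support must be positive")
  model <- wall
  edges <- cpp_build_edges(wall$X, support, wall$geom$sector, periodic)
  nn <- diff(edges$ptr)
  if (any(nn == 0))
    stop("sph_model: isolated particle(s) ", paste(head(which(nn == 0), 5),
         collapse = ", "), " (support too small for the lattice)")
  model$nbr <- list(ptr = edges$ptr, idx = edges$idx, rot = edges$rot,
                    alive = rep(TRUE, length(edges$idx)), h = support)
  model$control <- control
  model$m <- control$rho * wall$V
  model$state <- list(x = wall$X, v = matrix(0, nrow(wall$X), 2),
                      act = 0, frozen = rep(FALSE, nrow(wall$X)))
  model$damage <- list()
  model$pools <- list()
  model$log <- list()
  class(model) <- c("sph_model", "aorta_wall")
  model <- refresh_corrections(model, cond_limit)
  model
}

#' Recompute correction matrices and corrected gradients
#'
#' Called after neighbour-list surgery (severed pairs, removed particles).
#' Disrupted (group 0) particles are exempt from the conditioning check:
#' they no longer participate in any sum.
#'
#' @param model an `sph_model`.
#' @param cond_limit conditioning threshold for the correction matrices.
#' @return the updated model.
#' @export
refresh_corrections <- function(model, cond_limit = 1e8) {
  nb <- model$nbr
  cor <- cpp_correct(model$X, model$V, nb$ptr, nb$idx, nb$rot, nb$alive,
                     nb$h, model$geom$sector)
  live <- model$mp[, "group"] != 0
  bad <- which(live & (!is.finite(cor$cond) | cor$cond > cond_limit))
  if (length(bad))
    stop("refresh_corrections: rank-deficient correction matrix at ",
         "particle(s) ", paste(head(bad, 5), collapse = ", "),
         " (collinear or insufficient neighbourhood)")
  model$nbr[c("Rj", "w", "cgrad", "cback", "A", "Ainv", "cond")] <-
    cor[c("Rj", "w", "cgrad", "cback", "A", "Ainv", "cond")]
  model
}

#' Neighbour counts
#'
#' Number of live neighbours per particle (periodic images included).
#'
#' @param model an `sph_model`.
#' @return integer vector.
#' @export
neighbor_counts <- function(model) {
  nb <- model$nbr
  n <- nrow(model$X)
  vapply(seq_len(n), function(i) {
    e <- seq.int(nb$ptr[i] + 1L, length.out = nb$ptr[i + 1L] - nb$ptr[i])
    sum(nb$alive[e])
  }, integer(1))
}

# Sever all directed edges between particles in sets `a` and `b` (0/1-based
# bookkeeping handled here; a and b are 1-based particle indices).  The
# severance is symmetric: both directions of every (a, b) pair die.
sever_pairs <- function(model, a, b) {
  nb <- model$nbr
  ina <- logical(nrow(model$X)); ina[a] <- TRUE
  inb <- logical(nrow(model$X)); inb[b] <- TRUE
  src <- rep.int(seq_len(nrow(model$X)), diff(nb$ptr))
  tgt <- nb$idx + 1L
  kill <- (ina[src] & inb[tgt]) | (inb[src] & ina[tgt])
  model$nbr$alive <- nb$alive & !kill
  model
}

# Sever every edge touching the given particles (both directions).
sever_all <- function(model, who) {
  nb <- model$nbr
  inw <- logical(nrow(model$X)); inw[who] <- TRUE
  src <- rep.int(seq_len(nrow(model$X)), diff(nb$ptr))
  tgt <- nb$idx + 1L
  model$nbr$alive <- nb$alive & !(inw[src] | inw[tgt])
  model
}

#' @export
print.sph_model <- function(x, ...) {
  NextMethod()
  nn <- diff(x$nbr$ptr)
  cat("  neighbours: h = ", signif(x$nbr$h, 4), " um, ",
      round(mean(nn), 1), " per particle (mean), ",
      sum(!x$nbr$alive), " severed edge(s)\n", sep = "")
  if (!is.null(x$record))
    cat("  last equilibrium: P = ", signif(x$record$pressure_mmHg, 4),
        " mmHg, outer diameter ", signif(x$record$outer_diameter, 5),
        " um [", x$record$status, "]\n", sep = "")
  invisible(x)
}
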