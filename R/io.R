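# File output: legacy-VTK particle fields, CSV tables with header metadata,
# state checkpoints, convergence logs.

# small stable hash of a configuration list (polynomial roll over its
# deparse; stays within double-precision integer range)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write particle fields to a legacy VTK file
#'
#' ASCII legacy-VTK polydata with the particle positions as points and
#' named point-data arrays: group, lamella/layer indices, damage flag,
#' circumferential and radial Cauchy stress, volume ratio.
#'
#' @param model an `sph_model`.
#' @param path output file path (`.vtk`).
#' @return the path, invisibly.
#' @export
write_vtk <- function(model, path) {
  n <- nrow(model$X)
  x <- if (!is.null(model$state)) model$state$x else model$X
  has_stress <- !is.null(model$state$sigma)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("aortasph particle state")
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl("POINTS ", n, " float")
  writeLines(paste(format(x[, 1], trim = TRUE), format(x[, 2], trim = TRUE),
                   "0"), con)
  wl("VERTICES ", n, " ", 2 * n)
  writeLines(paste(1, seq_len(n) - 1L), con)
  wl("POINT_DATA ", n)
  scal <- function(name, v, type = "float") {
    wl("SCALARS ", name, " ", type, " 1")
    wl("LOOKUP_TABLE default")
    writeLines(format(v, trim = TRUE), con)
  }
  scal("group", as.integer(model$mp[, "group"]), "int")
  scal("lamella", model$lamella, "int")
  scal("layer", model$layer, "int")
  scal("damaged", as.integer(model$mp[, "group"] == 0), "int")
  if (has_stress) {
    scal("sigma_theta", sigma_theta(model))
    scal("sigma_radial", sigma_radial(model))
    scal("J", model$state$J)
  }
  invisible(path)
}

#' Write the particle table as CSV with header metadata
#'
#' Commented header lines carry the package version and a hash of the
#' geometry/material configuration, so result files are self-identifying;
#' the column schema is stable across runs.
#'
#' @param model an `sph_model`.
#' @param path output file path (`.csv`).
#' @return the path, invisibly.
#' @export
write_particles_csv <- function(model, path) {
  x <- if (!is.null(model$state)) model$state$x else model$X
  df <- data.frame(
    id = seq_len(nrow(model$X)),
    X_ref = model$X[, 1], Y_ref = model$X[, 2],
    x = x[, 1], y = x[, 2],
    V = model$V,
    group = as.integer(model$mp[, "group"]),
    lamella = model$lamella, layer = model$layer,
    damaged = as.integer(model$mp[, "group"] == 0))
  if (!is.null(model$state$sigma)) {
    df$sigma_theta <- sigma_theta(model)
    df$sigma_radial <- sigma_radial(model)
    df$J <- model$state$J
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# aortasph ", as.character(utils::packageVersion("aortasph"))),
    paste0("# config_hash ", config_hash(list(model$geom, model$mat,
                                              model$density))),
    paste0("# written ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a relaxation convergence log
#'
#' One row per relaxation call: step count, status, time step, peak
#' kinetic energy, final residual.
#'
#' @param model an `sph_model`.
#' @param path output `.csv` path.
#' @return the path, invisibly.
#' @export
write_convergence_log <- function(model, path) {
  if (!length(model$log)) stop("write_convergence_log: no relaxations yet")
  df <- do.call(rbind, lapply(seq_along(model$log), function(i) {
    l <- model$log[[i]]
    data.frame(call = i, steps = l$steps, status = l$status, dt = l$dt,
               ke_peak = l$ke_peak, maxf = l$maxf, fscale = l$fscale,
               act = l$act, r_rim = l$r_rim)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Checkpoint a model to disk
#'
#' Full-state serialization (positions, velocities, neighbour table,
#' damage registry); [read_checkpoint()] restores it bit-exactly.
#'
#' @param model an `sph_model`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @param path checkpoint file written by [write_checkpoint()].
#' @return the restored `sph_model`.
#' @export
read_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sph_model"))
    stop("read_checkpoint: not an sph_model checkpoint")
  m
}
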