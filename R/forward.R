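# Linear FEM forward solver for the 2D conductivity equation div(sigma grad u) = 0.
#
# Electrodes follow the gap (shunt-free Neumann) model: the injected current
# is spread over the electrode's boundary edges proportionally to edge length
# and enters the weak form as a boundary load; no contact impedance is
# modelled. Uniqueness is fixed by the zero-mean potential convention, which
# keeps the discrete system symmetric, so discrete reciprocity holds exactly
# up to solver tolerance.

#' Assemble the FEM stiffness matrix
#'
#' Standard piecewise-linear Galerkin stiffness for element-wise constant
#' conductivity. The operator is symmetric positive semidefinite with a
#' one-dimensional null space spanned by the constant vector.
#'
#' @param mesh A `torso_mesh`.
#' @param sigma Per-element conductivity in S/m (positive, length = element
#'   count), or a single value recycled to all elements.
#' @return A sparse symmetric `dgCMatrix` of size V x V.
#' @export
assemble_system <- function(mesh, sigma) {
  stopifnot(inherits(mesh, "torso_mesh"))
  ne <- nrow(mesh$elements)
  if (length(sigma) == 1L) sigma <- rep.int(sigma, ne)
  if (length(sigma) != ne) {
    stop("conductivity must have one value per element", call. = FALSE)
  }
  if (!all(is.finite(sigma)) || any(sigma <= 0)) {
    stop("conductivity values must be strictly positive and finite", call. = FALSE)
  }
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[el[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[el[, 3L], , drop = FALSE]
  # Shape-function gradient coefficients: b_i = y_j - y_k, c_i = x_k - x_j.
  b <- cbind(p2[, 2L] - p3[, 2L], p3[, 2L] - p1[, 2L], p1[, 2L] - p2[, 2L])
  cc <- cbind(p3[, 1L] - p2[, 1L], p1[, 1L] - p3[, 1L], p2[, 1L] - p1[, 1L])
  fac <- sigma / (4 * mesh$element_areas)
  ii <- jj <- matrix(0L, ne, 9L)
  xx <- matrix(0, ne, 9L)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1L
    ii[, k] <- el[, i]
    jj[, k] <- el[, j]
    xx[, k] <- fac * (b[, i] * b[, j] + cc[, i] * cc[, j])
  }
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = as.vector(xx),
                       dims = rep(nrow(mesh$nodes), 2L))
}

# Nodal load vector for injecting `current` amperes at electrode `source`
# and extracting at `sink`, spread over each electrode's edges by length.
electrode_load <- function(mesh, source, sink, current) {
  nv <- nrow(mesh$nodes)
  b <- numeric(nv)
  add <- function(elec, amp) {
    edges <- mesh$boundary_edges[mesh$electrodes[[elec]], , drop = FALSE]
    len <- sqrt(rowSums((mesh$nodes[edges[, 1L], , drop = FALSE] -
                         mesh$nodes[edges[, 2L], , drop = FALSE])^2))
    w <- amp * len / sum(len)
    for (r in seq_len(nrow(edges))) {
      b[edges[r, 1L]] <<- b[edges[r, 1L]] + w[r] / 2
      b[edges[r, 2L]] <<- b[edges[r, 2L]] + w[r] / 2
    }
  }
  add(source, current)
  add(sink, -current)
  b
}

# Factor the grounded system once; returns a closure solving K u = b with the
# zero-mean convention.
.system_solver <- function(K) {
  nv <- nrow(K)
  Kg <- K[-1L, -1L]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kg), LDL = FALSE, perm = TRUE)
  function(b) {
    ug <- Matrix::solve(ch, b[-1L], system = "A")
    u <- c(0, as.numeric(ug))
    u <- u - mean(u)
    res <- sqrt(sum((as.numeric(K %*% u) - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
    if (res > 1e-10) {
      stop(sprintf("forward solve failed: relative residual %.3g", res),
           call. = FALSE)
    }
    u
  }
}

#' Solve one current injection
#'
#' Computes the nodal potential for a single injection pair under the gap
#' electrode model, with the zero-mean potential constraint fixing the
#' additive constant.
#'
#' @param mesh A `torso_mesh`.
#' @param sigma Per-element conductivity (S/m).
#' @param source,sink Electrode indices (distinct).
#' @param current Injected current in amperes (default 1 mA).
#' @return Numeric vector of nodal potentials (volts), zero mean.
#' @export
solve_injection <- function(mesh, sigma, source, sink, current = 1e-3) {
  stopifnot(source != sink)
  K <- assemble_system(mesh, sigma)
  solver <- .system_solver(K)
  solver(electrode_load(mesh, source, sink, current))
}

#' Length-weighted mean potential over an electrode's edges
#'
#' The single-ended electrode voltage read out by the measurement model.
#'
#' @param mesh A `torso_mesh`.
#' @param u Nodal potential vector (e.g. from [solve_injection()]).
#' @param elec Electrode index.
#' @return Mean potential over the electrode (volts).
#' @export
electrode_potential <- function(mesh, u, elec) {
  edges <- mesh$boundary_edges[mesh$electrodes[[elec]], , drop = FALSE]
  len <- sqrt(rowSums((mesh$nodes[edges[, 1L], , drop = FALSE] -
                       mesh$nodes[edges[, 2L], , drop = FALSE])^2))
  umid <- (u[edges[, 1L]] + u[edges[, 2L]]) / 2
  sum(umid * len) / sum(len)
}

#' Simulate a measurement frame
#'
#' Solves the forward problem for every injection of the protocol and
#' assembles the frame: entry j is the length-weighted mean potential over
#' the measured electrode's edges under measurement j's injection.
#'
#' @param mesh A `torso_mesh`.
#' @param sigma Per-element conductivity (S/m).
#' @param protocol An `eit_protocol`.
#' @return An `eit_frame`: list with `values` (length m, volts), the
#'   protocol identifier, and an empty noise record.
#' @export
simulate_frame <- function(mesh, sigma, protocol) {
  stopifnot(inherits(protocol, "eit_protocol"))
  if (length(mesh$electrodes) < protocol$electrode_count) {
    stop("protocol addresses more electrodes than the mesh provides", call. = FALSE)
  }
  K <- assemble_system(mesh, sigma)
  solver <- .system_solver(K)
  inj <- protocol$injections
  sols <- lapply(seq_len(nrow(inj)), function(i) {
    solver(electrode_load(mesh, inj$source[i], inj$sink[i], inj$amplitude[i]))
  })
  mm <- protocol$measurements
  values <- vapply(seq_len(nrow(mm)), function(j) {
    electrode_potential(mesh, sols[[mm$injection[j]]], mm$electrode[j])
  }, numeric(1L))
  new_eit_frame(values, protocol)
}

new_eit_frame <- function(values, protocol, noise = NULL) {
  stopifnot(all(is.finite(values)))
  structure(list(values = values,
                 protocol_id = protocol_id(protocol),
                 m = length(values),
                 noise = noise),
            class = "eit_frame")
}

#' Add calibrated Gaussian measurement noise to a frame
#'
#' Adds zero-mean i.i.d. Gaussian noise with variance chosen so that
#' `10 * log10(signal power / noise power) = snr_db`, where signal power is
#' the mean square of the frame. `snr_db = Inf` disables noise and returns
#' the frame unchanged.
#'
#' @param frame An `eit_frame`.
#' @param snr_db Target signal-to-noise ratio in decibels (may be `Inf`).
#' @param seed Integer seed making the draw reproducible.
#' @return An `eit_frame` with the noise record (`model`, `snr_db`, `seed`)
#'   filled in.
#' @export
add_noise <- function(frame, snr_db, seed) {
  stopifnot(inherits(frame, "eit_frame"))
  if (is.infinite(snr_db)) return(frame)
  stopifnot(is.finite(snr_db))
  sig_pow <- mean(frame$values^2)
  sd_noise <- sqrt(sig_pow / 10^(snr_db / 10))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  frame$values <- frame$values + stats::rnorm(length(frame$values), 0, sd_noise)
  frame$noise <- list(model = "additive-gaussian", snr_db = snr_db, seed = seed)
  frame
}

#' @export
print.eit_frame <- function(x, ...) {
  cat(sprintf("<eit_frame> m = %d, range [%.3g, %.3g] V%s\n",
              x$m, min(x$values), max(x$values),
              if (is.null(x$noise)) "" else
                sprintf(", noise %s @ %g dB", x$noise$model, x$noise$snr_db)))
  invisible(x)
}
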