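# Random bladder-like inclusions and labelled dataset generation.
#
# An inclusion is a rotated ellipse whose boundary radius may carry a
# low-order Fourier perturbation, r(theta) = 1 + sum_k a_k cos(k theta) +
# b_k sin(k theta) in the ellipse's own frame. This family spans smooth
# single-blob shapes with 5 (pure ellipse) to 11 (order-3 perturbation)
# degrees of freedom. Labels are per mesh element: 1 iff the element
# centroid lies strictly inside the shape (a centroid exactly on the shape
# boundary counts as outside).

#' Construct an inclusion shape
#'
#' @param center Numeric length-2 center (m).
#' @param semi_axes Numeric length-2, positive semi-axes `(a, b)` in meters.
#' @param rotation Rotation angle in radians.
#' @param fourier Optional 2 x k matrix of radial perturbation coefficients
#'   (row 1 cosine, row 2 sine, column k = harmonic order k).
#' @return An `inclusion_shape` object.
#' @export
inclusion_shape <- function(center, semi_axes, rotation = 0, fourier = NULL) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L, all(semi_axes > 0))
  if (!is.null(fourier)) {
    stopifnot(is.matrix(fourier), nrow(fourier) == 2L)
    # deformed radius must stay positive for all angles
    th <- seq(0, 2 * pi, length.out = 361L)
    if (any(.radial_factor(fourier, th) <= 0)) {
      stop("radial perturbation makes the shape boundary non-positive", call. = FALSE)
    }
  }
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation),
                 fourier = fourier),
            class = "inclusion_shape")
}

.radial_factor <- function(fourier, theta) {
  r <- rep.int(1, length(theta))
  if (is.null(fourier) || ncol(fourier) == 0L) return(r)
  for (k in seq_len(ncol(fourier))) {
    r <- r + fourier[1L, k] * cos(k * theta) + fourier[2L, k] * sin(k * theta)
  }
  r
}

#' Shape boundary polygon
#' @param shape An `inclusion_shape`.
#' @param n Number of boundary points.
#' @return n x 2 matrix of boundary points.
#' @export
shape_boundary <- function(shape, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- .radial_factor(shape$fourier, th)
  x0 <- shape$semi_axes[1L] * r * cos(th)
  y0 <- shape$semi_axes[2L] * r * sin(th)
  cs <- cos(shape$rotation); sn <- sin(shape$rotation)
  cbind(shape$center[1L] + cs * x0 - sn * y0,
        shape$center[2L] + sn * x0 + cs * y0)
}

#' Test points for strict inclusion in a shape
#'
#' @param shape An `inclusion_shape`.
#' @param pts k x 2 matrix of points.
#' @return Logical vector; `TRUE` iff the point is strictly inside (points
#'   exactly on the boundary are outside).
#' @export
point_in_shape <- function(shape, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2L)
  d <- sweep(pts, 2L, shape$center)
  cs <- cos(-shape$rotation); sn <- sin(-shape$rotation)
  xl <- cs * d[, 1L] - sn * d[, 2L]
  yl <- sn * d[, 1L] + cs * d[, 2L]
  xe <- xl / shape$semi_axes[1L]
  ye <- yl / shape$semi_axes[2L]
  rho <- sqrt(xe^2 + ye^2)
  th <- atan2(ye, xe)
  rho < .radial_factor(shape$fourier, th)
}

#' Shape area (by quadrature over the boundary radius)
#' @param shape An `inclusion_shape`.
#' @return Area in m^2.
#' @export
shape_area <- function(shape) {
  n <- 4096L
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- .radial_factor(shape$fourier, th)
  prod(shape$semi_axes) * mean(r^2) * pi
}

#' Default admissible region for inclusion centers
#'
#' The central lower part of the outline's interior with a 15% bottom
#' margin: the bladder is a midline pelvic organ that sits low in the
#' cross-section and cannot touch the torso wall (abdominal tissue lies
#' between), so centers range laterally over 10% of the torso width around
#' the midline and vertically from just above the lowest point up to the
#' centroid height.
#'
#' @param outline Outline polygon (matrix) or superellipse parameter list.
#' @return List with `xlim`, `ylim` in meters.
#' @export
default_inclusion_region <- function(outline = list(a = 0.15, b = 0.10, exponent = 2.5)) {
  if (is.list(outline) && !is.matrix(outline)) {
    outline <- do.call(superellipse_outline, outline)
  }
  ctr <- polygon_centroid(outline)
  xr <- range(outline[, 1L]); yr <- range(outline[, 2L])
  w <- diff(xr); hgt <- diff(yr)
  list(xlim = ctr[1L] + c(-1, 1) * 0.10 * w,
       ylim = c(yr[1L] + 0.15 * hgt, ctr[2L]))
}

#' Draw a random inclusion
#'
#' Center uniform in the admissible region, semi-axes uniform in
#' `size_bounds`, rotation uniform in `[0, pi)`, Fourier perturbation
#' coefficients i.i.d. normal with standard deviation `perturb_scale`.
#' Shapes that leave the domain (outline shrunk by `containment_margin`
#' towards its centroid) are rejected and resampled.
#'
#' @param region List with `xlim` and `ylim` (meters); default
#'   [default_inclusion_region()] of the standard torso outline.
#' @param size_bounds Length-2 semi-axis bounds in meters.
#' @param perturb_order Highest Fourier harmonic (0 = pure ellipse).
#' @param perturb_scale Standard deviation of the perturbation coefficients.
#' @param outline Outline polygon or superellipse parameters the shape must
#'   stay inside.
#' @param containment_margin Fraction by which the outline is shrunk for the
#'   containment test.
#' @param max_tries Resampling budget before giving up.
#' @return An `inclusion_shape`. Uses the current RNG state.
#' @export
sample_inclusion <- function(region = NULL,
                             size_bounds = c(0.015, 0.035),
                             perturb_order = 0L,
                             perturb_scale = 0.08,
                             outline = list(a = 0.15, b = 0.10, exponent = 2.5),
                             containment_margin = 0.05,
                             max_tries = 100L) {
  if (is.list(outline) && !is.matrix(outline)) {
    outline <- do.call(superellipse_outline, outline)
  }
  if (is.null(region)) region <- default_inclusion_region(outline)
  stopifnot(size_bounds[1L] > 0, size_bounds[2L] >= size_bounds[1L])
  ctr <- polygon_centroid(outline)
  shrunk <- sweep(sweep(outline, 2L, ctr) * (1 - containment_margin), 2L, ctr, `+`)
  for (try in seq_len(max_tries)) {
    center <- c(stats::runif(1L, region$xlim[1L], region$xlim[2L]),
                stats::runif(1L, region$ylim[1L], region$ylim[2L]))
    semi_axes <- stats::runif(2L, size_bounds[1L], size_bounds[2L])
    rotation <- stats::runif(1L, 0, pi)
    fourier <- NULL
    if (perturb_order > 0L && perturb_scale > 0) {
      fourier <- matrix(stats::rnorm(2L * perturb_order, 0, perturb_scale),
                        nrow = 2L)
      if (any(.radial_factor(fourier, seq(0, 2 * pi, length.out = 181L)) <= 0.2)) next
    }
    shape <- inclusion_shape(center, semi_axes, rotation, fourier)
    if (all(point_in_polygon(shape_boundary(shape, 90L), shrunk))) return(shape)
  }
  stop("sample_inclusion: resampling budget exhausted; widen the outline or shrink size_bounds",
       call. = FALSE)
}

#' Per-element labels for a shape
#'
#' @param mesh A `torso_mesh`.
#' @param shape An `inclusion_shape`.
#' @return Integer 0/1 vector over elements: 1 iff the element centroid lies
#'   strictly inside the shape.
#' @export
labels_from_shape <- function(mesh, shape) {
  as.integer(point_in_shape(shape, mesh$element_centroids))
}

#' Build a conductivity field from labels
#'
#' @param labels 0/1 element labels.
#' @param background,inclusion Conductivities in S/m. Defaults 0.2 (soft
#'   tissue) and 1.0 (urine; more conductive than the background).
#' @return Per-element conductivity vector.
#' @export
conductivity_from_labels <- function(labels, background = 0.2, inclusion = 1.0) {
  stopifnot(all(labels %in% c(0L, 1L)), background > 0, inclusion > 0)
  ifelse(labels == 1L, inclusion, background)
}

#' Generate a labelled simulation dataset
#'
#' For each sample, draws a random inclusion, labels the mesh elements,
#' builds the two-valued conductivity field, solves the forward problem for
#' every injection of the protocol, and optionally adds calibrated Gaussian
#' noise. Per-sample sub-seeds are derived deterministically from the master
#' seed, so the dataset is reproducible bit-exactly from its metadata.
#'
#' @param mesh A `torso_mesh`.
#' @param protocol An `eit_protocol`.
#' @param n Number of samples (the reference study size is 5000).
#' @param conductivities Named vector `c(background=, inclusion=)` in S/m.
#' @param snr_db Measurement noise level in dB; `Inf` (default) disables noise.
#' @param seed Master seed.
#' @param shape_args List of arguments passed to [sample_inclusion()].
#' @return An `eit_dataset`: list with `X` (n x m frame matrix), `Y` (n x E
#'   0/1 label matrix), `shapes` (per-sample shape parameters, tibble) and
#'   `meta`.
#' @export
generate_dataset <- function(mesh, protocol, n = 5000L,
                             conductivities = c(background = 0.2, inclusion = 1.0),
                             snr_db = Inf, seed = 1L,
                             shape_args = list()) {
  stopifnot(n >= 1L)
  shape_args$outline <- shape_args$outline %||% mesh$outline
  m <- frame_length(protocol)
  E <- nrow(mesh$elements)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2L * n)
  X <- matrix(0, n, m)
  Y <- matrix(0L, n, E)
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      set.seed(sub_seeds[2L * i - 1L])
      shape <- do.call(sample_inclusion, shape_args)
      y <- labels_from_shape(mesh, shape)
      sig <- conductivity_from_labels(y, conductivities[["background"]],
                                      conductivities[["inclusion"]])
      fr <- simulate_frame(mesh, sig, protocol)
      if (is.finite(snr_db)) fr <- add_noise(fr, snr_db, sub_seeds[2L * i])
      list(frame = fr, y = y, shape = shape)
    }, error = function(e) {
      stop(sprintf("dataset generation failed at sample %d: %s", i,
                   conditionMessage(e)), call. = FALSE)
    })
    X[i, ] <- res$frame$values
    Y[i, ] <- res$y
    shapes[[i]] <- res$shape
  }
  shape_tbl <- tibble::tibble(
    sample = seq_len(n),
    cx = vapply(shapes, function(s) s$center[1L], 1),
    cy = vapply(shapes, function(s) s$center[2L], 1),
    a = vapply(shapes, function(s) s$semi_axes[1L], 1),
    b = vapply(shapes, function(s) s$semi_axes[2L], 1),
    rotation = vapply(shapes, function(s) s$rotation, 1)
  )
  structure(list(
    X = X, Y = Y, shapes = shape_tbl,
    meta = list(n = n, m = m, n_elements = E,
                protocol_id = protocol_id(protocol),
                conductivities = conductivities,
                snr_db = snr_db, seed = seed,
                shape_args = shape_args[setdiff(names(shape_args), "outline")])
  ), class = "eit_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eit_dataset <- function(x, ...) {
  cat(sprintf("<eit_dataset> n = %d frames of m = %d voltages, %d elements, seed %s\n",
              x$meta$n, x$meta$m, x$meta$n_elements, format(x$meta$seed)))
  cat(sprintf("  positive label rate %.3f, noise %s\n",
              mean(x$Y), if (is.finite(x$meta$snr_db))
                paste0(x$meta$snr_db, " dB") else "none"))
  invisible(x)
}

#' Write / read a dataset as paired CSV files with a JSON sidecar
#'
#' `write_dataset()` stores `X.csv`, `Y.csv`, `shapes.csv` and `meta.json`
#' in `dir`; `read_dataset()` restores the `eit_dataset`.
#'
#' @param dataset An `eit_dataset`.
#' @param dir Directory (created if missing).
#' @return `write_dataset()` the directory path invisibly; `read_dataset()`
#'   the dataset.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eit_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xf <- file.path(dir, "X.csv")
  utils::write.table(format(dataset$X, digits = 17, scientific = TRUE, trim = TRUE),
                     xf, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(dataset$Y, file.path(dir, "Y.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(dataset$shapes, file.path(dir, "shapes.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  X <- as.matrix(utils::read.table(file.path(dir, "X.csv"), sep = ","))
  Y <- as.matrix(utils::read.table(file.path(dir, "Y.csv"), sep = ","))
  dimnames(X) <- dimnames(Y) <- NULL
  storage.mode(Y) <- "integer"
  shapes <- tibble::as_tibble(utils::read.csv(file.path(dir, "shapes.csv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(list(X = X, Y = Y, shapes = shapes, meta = meta),
            class = "eit_dataset")
}
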