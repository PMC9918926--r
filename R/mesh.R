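# Torso cross-section mesh construction.
#
# The meshing strategy is a deterministic ring (polar) triangulation of a
# star-shaped outline: boundary nodes are placed by arc length (with forced
# breakpoints at electrode ends and at polygon corners), interior rings are
# scaled copies of the outline with node counts proportional to radius, the
# annuli between rings are stitched by a circular staircase merge, and a few
# Laplacian smoothing sweeps even out the triangle shapes. The construction
# is fully reproducible: no randomness is involved.

#' Superellipse outline polygon
#'
#' Returns a closed counter-clockwise polygon approximating the superellipse
#' \eqn{|x/a|^p + |y/b|^p = 1}, a conventional stand-in for a torso
#' cross-section at bladder level. The default half-axes (0.15 m by 0.10 m)
#' are a plausible adult pelvis size; they are configuration, not anatomy.
#'
#' @param a,b Half-axes in meters.
#' @param exponent Superellipse exponent `p`; 2 gives an ellipse, larger
#'   values a flatter, more torso-like shape.
#' @param n Number of polygon vertices.
#' @return An `n` by 2 numeric matrix of vertices (the polygon is closed
#'   implicitly; the first vertex is not repeated).
#' @export
superellipse_outline <- function(a = 0.15, b = 0.10, exponent = 2.5, n = 720) {
  stopifnot(a > 0, b > 0, exponent > 0, n >= 16)
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * sign(cos(t)) * abs(cos(t))^(2 / exponent)
  y <- b * sign(sin(t)) * abs(sin(t))^(2 / exponent)
  cbind(x = x, y = y)
}

polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  i2 <- c(seq_len(nrow(p))[-1L], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

polygon_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  i2 <- c(seq_len(nrow(p))[-1L], 1L)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * a)
}

# Point-in-polygon by ray crossing; `pts` is k x 2, `poly` closed implicitly.
# Points exactly on the boundary are not guaranteed either way (callers that
# care use a margin).
point_in_polygon <- function(pts, poly) {
  px <- poly[, 1L]; py <- poly[, 2L]
  n <- length(px)
  jx <- px[c(n, seq_len(n - 1L))]; jy <- py[c(n, seq_len(n - 1L))]
  inside <- logical(nrow(pts))
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- jx[e]; y2 <- jy[e]
    crosses <- ((y1 > pts[, 2L]) != (y2 > pts[, 2L]))
    if (any(crosses)) {
      xint <- (x2 - x1) * (pts[crosses, 2L] - y1) / (y2 - y1) + x1
      flip <- pts[crosses, 1L] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  inside
}

# Arc-length machinery over a closed polygon ------------------------------

.outline_param <- function(poly) {
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1L], 1L)
  seg <- sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2))
  list(poly = poly, s = c(0, cumsum(seg)), total = sum(seg))
}

# Point(s) on the outline at arc length s (wrapped into [0, total)).
.arc_point <- function(par, s) {
  s <- s %% par$total
  idx <- findInterval(s, par$s, rightmost.closed = TRUE)
  idx[idx > nrow(par$poly)] <- nrow(par$poly)
  n <- nrow(par$poly)
  nxt <- ifelse(idx == n, 1L, idx + 1L)
  den <- par$s[idx + 1L] - par$s[idx]
  w <- ifelse(den > 0, (s - par$s[idx]) / den, 0)
  par$poly[idx, , drop = FALSE] * (1 - w) + par$poly[nxt, , drop = FALSE] * w
}

# Arc lengths of polygon vertices whose exterior turning angle exceeds
# `angle_deg` (used to keep genuine corners, e.g. of a square, in the mesh).
.corner_arclengths <- function(par, angle_deg = 20) {
  p <- par$poly
  n <- nrow(p)
  prv <- c(n, seq_len(n - 1L)); nxt <- c(seq_len(n)[-1L], 1L)
  v1 <- p - p[prv, , drop = FALSE]
  v2 <- p[nxt, , drop = FALSE] - p
  ang <- abs(atan2(v1[, 1L] * v2[, 2L] - v1[, 2L] * v2[, 1L],
                   rowSums(v1 * v2)))
  par$s[which(ang > angle_deg * pi / 180)]
}

# Mesh construction -------------------------------------------------------

#' Build a triangulated torso mesh with boundary electrodes
#'
#' Constructs a conforming triangulation of a star-shaped 2D outline and
#' places `electrode_count` line electrodes as contiguous, pairwise disjoint
#' runs of boundary edges on the front (lower) arc of the boundary, the
#' one-sided electrode placement used for wearable abdominal measurement
#' belts.
#'
#' @param outline Either a closed polygon (k by 2 matrix, counter-clockwise)
#'   or a list of superellipse parameters (`a`, `b`, `exponent`) passed to
#'   [superellipse_outline()]. Default: the standard torso outline.
#' @param electrode_count Number of electrodes (at least 2).
#' @param electrode_arc_fraction Fraction of the front-arc length covered by
#'   electrodes in total.
#' @param target_edge_length Requested edge length in meters.
#' @param min_angle Minimum acceptable triangle angle in degrees; meshing
#'   fails if the triangulation cannot reach it.
#' @param smooth_iter Laplacian smoothing sweeps applied to interior nodes.
#' @return A `torso_mesh` object: list with `nodes` (V x 2), `elements`
#'   (E x 3, counter-clockwise), `boundary_edges` (B x 2), `electrodes`
#'   (list of boundary-edge index vectors), `element_areas`,
#'   `element_centroids`, plus the outline and boundary arc-length bookkeeping
#'   used for uniform refinement.
#' @export
build_torso_mesh <- function(outline = list(a = 0.15, b = 0.10, exponent = 2.5),
                             electrode_count = 8L,
                             electrode_arc_fraction = 0.5,
                             target_edge_length = 0.012,
                             min_angle = 20,
                             smooth_iter = 3L) {
  if (is.list(outline) && !is.matrix(outline)) {
    outline <- do.call(superellipse_outline, outline)
  }
  stopifnot(is.matrix(outline), ncol(outline) == 2L, nrow(outline) >= 3L)
  if (polygon_area(outline) < 0) outline <- outline[rev(seq_len(nrow(outline))), ]
  if (!(electrode_count >= 2L)) stop("electrode_count must be >= 2", call. = FALSE)
  if (!(electrode_arc_fraction > 0 && electrode_arc_fraction < 1)) {
    stop("electrode_arc_fraction must lie in (0, 1)", call. = FALSE)
  }
  diam <- max(dist(outline[unique(round(seq(1L, nrow(outline),
                                            length.out = min(64L, nrow(outline))))), ]))
  if (!(target_edge_length > 0 && target_edge_length < diam)) {
    stop("target_edge_length must be positive and smaller than the outline diameter",
         call. = FALSE)
  }

  par <- .outline_param(outline)
  ctr <- polygon_centroid(outline)
  h <- target_edge_length

  # Front (lower) arc: the longest contiguous run of boundary edges whose
  # midpoints lie below the centroid.
  n <- nrow(outline)
  nxt <- c(seq_len(n)[-1L], 1L)
  midy <- (outline[, 2L] + outline[nxt, 2L]) / 2
  low <- midy < ctr[2L]
  if (!any(low)) stop("outline has no front (lower) arc", call. = FALSE)
  runs <- .circular_runs(low)
  run <- runs[[which.max(vapply(runs, length, 1L))]]
  sa <- par$s[run[1L]]
  sb <- par$s[run[length(run)] %% n + 1L]
  front_len <- (sb - sa) %% par$total
  if (front_len == 0) front_len <- par$total

  # Electrode layout along the front arc: equal gaps at the ends and between
  # electrodes.
  tot_el <- electrode_arc_fraction * front_len
  el_len <- tot_el / electrode_count
  gap <- (front_len - tot_el) / (electrode_count + 1L)
  if (gap <= 0 || el_len <= 0) {
    stop("electrodes overlap: electrode_arc_fraction too large for this outline",
         call. = FALSE)
  }

  # Boundary breakpoints (arc lengths, unwrapped starting at sa): alternating
  # gap / electrode segments on the front arc, then the back arc.
  brk <- sa
  seg_kind <- integer(0)            # 0 = inert, k>0 = electrode k
  pos <- sa
  for (k in seq_len(electrode_count)) {
    pos <- pos + gap; brk <- c(brk, pos); seg_kind <- c(seg_kind, 0L)
    pos <- pos + el_len; brk <- c(brk, pos); seg_kind <- c(seg_kind, k)
  }
  brk <- c(brk, sa + par$total)     # close with the back arc
  seg_kind <- c(seg_kind, 0L, 0L)   # final front gap + back arc
  pos <- pos + gap
  brk <- append(brk, pos, after = length(brk) - 1L)

  # Force polygon corners (sharp turning angles) into the subdivision so
  # coarse polygonal outlines (e.g. a square) keep their vertices.
  corners <- .corner_arclengths(par)
  if (length(corners)) {
    cu <- sort(((corners - sa) %% par$total)) + sa
    for (cs in cu) {
      j <- findInterval(cs, brk)
      if (j >= 1L && j < length(brk) &&
          cs - brk[j] > 1e-9 && brk[j + 1L] - cs > 1e-9) {
        brk <- append(brk, cs, after = j)
        seg_kind <- append(seg_kind, seg_kind[j], after = j)
      }
    }
  }

  # Subdivide each segment into edges of about the target length.
  bs <- numeric(0)                  # boundary node arc lengths (unwrapped)
  edge_kind <- integer(0)           # per boundary edge: electrode id or 0
  for (j in seq_len(length(brk) - 1L)) {
    len <- brk[j + 1L] - brk[j]
    if (len < 1e-12) next
    ne <- max(1L, round(len / h))
    ss <- brk[j] + len * (seq_len(ne) - 1L) / ne
    bs <- c(bs, ss)
    edge_kind <- c(edge_kind, rep.int(seg_kind[j], ne))
  }
  nB <- length(bs)
  bnodes <- .arc_point(par, bs)
  if (any(vapply(seq_len(electrode_count),
                 function(k) sum(edge_kind == k) == 0L, logical(1L)))) {
    stop("mesh resolution too coarse: an electrode received no boundary edge",
         call. = FALSE)
  }

  # Interior rings: scaled outline copies.
  rbar <- mean(sqrt(rowSums(sweep(bnodes, 2L, ctr)^2)))
  K <- max(1L, round(rbar / h))
  ring_nodes <- list(); ring_u <- list()
  if (K > 1L) {
    for (j in seq_len(K - 1L)) {
      mj <- max(6L, ceiling(nB * j / K))
      u <- par$total * (seq_len(mj) - 1L) / mj
      p <- .arc_point(par, u)
      t <- j / K
      ring_nodes[[j]] <- sweep(sweep(p, 2L, ctr) * t, 2L, ctr, `+`)
      ring_u[[j]] <- u / par$total
    }
  }

  nodes <- rbind(matrix(ctr, 1L, 2L), do.call(rbind, ring_nodes), bnodes)
  offs <- 1L + c(0L, cumsum(vapply(ring_nodes, nrow, 1L)))
  boundary_start <- offs[length(offs)] + 1L
  bidx <- boundary_start:(boundary_start + nB - 1L)

  tris <- list()
  ring_idx <- c(list(1L), lapply(seq_along(ring_nodes),
                                 function(j) (offs[j] + 1L):(offs[j + 1L])),
                list(bidx))
  ring_par <- c(list(0), ring_u, list((bs %% par$total) / par$total))
  # Fan from the center to the first ring.
  r1 <- ring_idx[[2L]]
  m1 <- length(r1)
  tris[[1L]] <- cbind(rep.int(1L, m1), r1, r1[c(seq_len(m1)[-1L], 1L)])
  # Staircase merge between successive rings.
  if (length(ring_idx) > 2L) {
    for (j in 2L:(length(ring_idx) - 1L)) {
      tris[[j]] <- .merge_rings(ring_idx[[j]], ring_par[[j]],
                                ring_idx[[j + 1L]], ring_par[[j + 1L]])
    }
  }
  elements <- do.call(rbind, tris)
  dimnames(elements) <- NULL
  storage.mode(elements) <- "integer"

  # Laplacian smoothing of interior nodes.
  if (smooth_iter > 0L && nrow(nodes) > nB + 1L) {
    interior <- setdiff(seq_len(nrow(nodes)), bidx)
    adj <- .node_adjacency(elements, nrow(nodes))
    deg <- Matrix::rowSums(adj)
    for (it in seq_len(smooth_iter)) {
      avg <- as.matrix(adj %*% nodes) / deg
      nodes[interior, ] <- avg[interior, ]
    }
  }

  boundary_edges <- cbind(bidx, bidx[c(seq_len(nB)[-1L], 1L)])
  dimnames(boundary_edges) <- NULL
  storage.mode(boundary_edges) <- "integer"
  electrodes <- lapply(seq_len(electrode_count), function(k) which(edge_kind == k))

  mesh <- new_torso_mesh(nodes, elements, boundary_edges, electrodes,
                         outline = outline,
                         boundary_s = bs %% par$total)
  q <- mesh_min_angle(mesh)
  if (q < min_angle) {
    stop(sprintf(
      "meshing failed: minimum triangle angle %.2f deg below the %.1f deg bound; adjust target_edge_length",
      q, min_angle), call. = FALSE)
  }
  mesh
}

# Contiguous circular runs of TRUE values.
.circular_runs <- function(x) {
  n <- length(x)
  if (all(x)) return(list(seq_len(n)))
  # rotate so the sequence starts on a FALSE
  st <- which(!x)[1L]
  ord <- c(st:n, seq_len(st - 1L))
  r <- rle(x[ord])
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i]) out[[length(out) + 1L]] <- ord[starts[i]:ends[i]]
  }
  out
}

# Triangulate the annulus between an inner ring (lo) and an outer ring (hi),
# both counter-clockwise with angular parameters in [0, 1).
.merge_rings <- function(idx_lo, u_lo, idx_hi, u_hi) {
  m_lo <- length(idx_lo); m_hi <- length(idx_hi)
  k <- which.min((u_hi - u_lo[1L]) %% 1)
  if (k > 1L) {
    idx_hi <- c(idx_hi[k:m_hi], idx_hi[seq_len(k - 1L)])
    u_hi <- c(u_hi[k:m_hi], u_hi[seq_len(k - 1L)])
  }
  dlo <- (u_lo - u_lo[1L]) %% 1
  dhi <- (u_hi - u_lo[1L]) %% 1
  dlo_ext <- c(dlo, 1); ilo_ext <- c(idx_lo, idx_lo[1L])
  dhi_ext <- c(dhi, dhi[1L] + 1); ihi_ext <- c(idx_hi, idx_hi[1L])
  tris <- matrix(0L, m_lo + m_hi, 3L)
  i <- 1L; j <- 1L; t <- 0L
  while (i <= m_lo || j <= m_hi) {
    adv_hi <- j <= m_hi && (i > m_lo || dhi_ext[j + 1L] <= dlo_ext[i + 1L])
    t <- t + 1L
    if (adv_hi) {
      tris[t, ] <- c(ihi_ext[j], ihi_ext[j + 1L], ilo_ext[i])
      j <- j + 1L
    } else {
      tris[t, ] <- c(ihi_ext[j], ilo_ext[i + 1L], ilo_ext[i])
      i <- i + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

.node_adjacency <- function(elements, nv) {
  e <- rbind(elements[, c(1L, 2L)], elements[, c(2L, 3L)], elements[, c(3L, 1L)])
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(nv, nv), use.last.ij = TRUE)
}

# torso_mesh class ---------------------------------------------------------

new_torso_mesh <- function(nodes, elements, boundary_edges, electrodes,
                           outline = NULL, boundary_s = NULL) {
  dimnames(nodes) <- NULL
  areas <- triangle_areas(nodes, elements)
  if (any(areas <= 0)) {
    flip <- which(areas <= 0)
    elements[flip, ] <- elements[flip, c(1L, 3L, 2L)]
    areas <- triangle_areas(nodes, elements)
  }
  if (any(areas <= 0)) stop("degenerate (zero-area) element in mesh", call. = FALSE)
  centroids <- (nodes[elements[, 1L], , drop = FALSE] +
                nodes[elements[, 2L], , drop = FALSE] +
                nodes[elements[, 3L], , drop = FALSE]) / 3
  structure(list(
    nodes = nodes,
    elements = elements,
    boundary_edges = boundary_edges,
    electrodes = electrodes,
    element_areas = areas,
    element_centroids = centroids,
    outline = outline,
    boundary_s = boundary_s
  ), class = "torso_mesh")
}

triangle_areas <- function(nodes, elements) {
  p1 <- nodes[elements[, 1L], , drop = FALSE]
  p2 <- nodes[elements[, 2L], , drop = FALSE]
  p3 <- nodes[elements[, 3L], , drop = FALSE]
  ((p2[, 1L] - p1[, 1L]) * (p3[, 2L] - p1[, 2L]) -
   (p3[, 1L] - p1[, 1L]) * (p2[, 2L] - p1[, 2L])) / 2
}

#' Minimum triangle angle of a mesh, in degrees
#' @param mesh A `torso_mesh`.
#' @return Smallest interior angle over all elements (degrees).
#' @export
mesh_min_angle <- function(mesh) {
  p1 <- mesh$nodes[mesh$elements[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[mesh$elements[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[mesh$elements[, 3L], , drop = FALSE]
  a2 <- rowSums((p2 - p3)^2); b2 <- rowSums((p1 - p3)^2); c2 <- rowSums((p1 - p2)^2)
  a <- sqrt(a2); b <- sqrt(b2); c <- sqrt(c2)
  angs <- cbind(acos(pmin(1, pmax(-1, (b2 + c2 - a2) / (2 * b * c)))),
                acos(pmin(1, pmax(-1, (a2 + c2 - b2) / (2 * a * c)))),
                acos(pmin(1, pmax(-1, (a2 + b2 - c2) / (2 * a * b)))))
  min(angs) * 180 / pi
}

#' Validate a torso mesh
#'
#' Checks the structural invariants: positive counter-clockwise element
#' areas, Euler consistency of the planar triangulation
#' (`V - edges + triangles = 1` for a simply connected open complex),
#' electrode edge sets pairwise disjoint and contained in the boundary, and
#' electrode contiguity along the boundary walk.
#'
#' @param mesh A `torso_mesh`.
#' @return The mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "torso_mesh"))
  if (max(mesh$elements) > nrow(mesh$nodes) || min(mesh$elements) < 1L) {
    stop("element references a missing node", call. = FALSE)
  }
  if (any(mesh$element_areas <= 0)) stop("non-positive element area", call. = FALSE)
  ed <- rbind(mesh$elements[, c(1L, 2L)], mesh$elements[, c(2L, 3L)],
              mesh$elements[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  n_edges <- length(unique(key))
  euler <- nrow(mesh$nodes) - n_edges + nrow(mesh$elements)
  if (euler != 1L) {
    stop(sprintf("Euler check failed: V - E + F = %d (expected 1)", euler),
         call. = FALSE)
  }
  be_key <- paste(pmin(mesh$boundary_edges[, 1L], mesh$boundary_edges[, 2L]),
                  pmax(mesh$boundary_edges[, 1L], mesh$boundary_edges[, 2L]))
  if (!all(be_key %in% key)) stop("boundary edge not part of any element", call. = FALSE)
  all_el <- unlist(mesh$electrodes)
  if (anyDuplicated(all_el)) stop("electrode edge sets overlap", call. = FALSE)
  if (length(all_el) && (max(all_el) > nrow(mesh$boundary_edges) || min(all_el) < 1L)) {
    stop("electrode references a non-boundary edge", call. = FALSE)
  }
  nb <- nrow(mesh$boundary_edges)
  for (el in mesh$electrodes) {
    if (length(el) > 1L) {
      d <- diff(sort(el))
      contiguous <- all(d == 1L) ||
        all(diff(sort((el - min(el)) %% nb)) == 1L)
      if (!contiguous) stop("electrode edges are not contiguous", call. = FALSE)
    }
  }
  invisible(mesh)
}

#' Uniformly refine a mesh
#'
#' Splits every triangle into four by edge midpoints. Midpoints of boundary
#' edges are projected back onto the outline curve (by arc length), so
#' successive refinements converge to the smooth domain; electrode membership
#' is inherited by the two child edges of an electrode edge.
#'
#' @param mesh A `torso_mesh` built by [build_torso_mesh()].
#' @return The refined `torso_mesh`.
#' @export
refine_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "torso_mesh"))
  nv <- nrow(mesh$nodes)
  el <- mesh$elements
  ed <- rbind(el[, c(1L, 2L)], el[, c(2L, 3L)], el[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  uk <- unique(key)
  mid_id <- match(key, uk) + nv
  first <- !duplicated(key)
  mids <- (mesh$nodes[ed[first, 1L], , drop = FALSE] +
           mesh$nodes[ed[first, 2L], , drop = FALSE]) / 2

  # Project boundary midpoints onto the outline.
  new_boundary_s <- rep(NA_real_, length(uk))
  if (!is.null(mesh$outline) && !is.null(mesh$boundary_s)) {
    par <- .outline_param(mesh$outline)
    bs_full <- rep(NA_real_, nv)
    bidx <- sort(unique(as.vector(mesh$boundary_edges)))
    bs_full[bidx] <- mesh$boundary_s
    be <- mesh$boundary_edges
    bkey <- paste(pmin(be[, 1L], be[, 2L]), pmax(be[, 1L], be[, 2L]))
    bmatch <- match(bkey, uk)
    s1 <- bs_full[be[, 1L]]; s2 <- bs_full[be[, 2L]]
    d <- (s2 - s1) %% par$total
    sm <- (s1 + d / 2) %% par$total
    mids[bmatch, ] <- .arc_point(par, sm)
    new_boundary_s[bmatch] <- sm
  }

  nodes <- rbind(mesh$nodes, mids)
  ne <- nrow(el)
  m12 <- mid_id[seq_len(ne)]
  m23 <- mid_id[ne + seq_len(ne)]
  m31 <- mid_id[2L * ne + seq_len(ne)]
  elements <- rbind(
    cbind(el[, 1L], m12, m31),
    cbind(el[, 2L], m23, m12),
    cbind(el[, 3L], m31, m23),
    cbind(m12, m23, m31)
  )
  storage.mode(elements) <- "integer"

  # Child boundary edges, in walk order, each inheriting its parent's slot.
  be <- mesh$boundary_edges
  bkey <- paste(pmin(be[, 1L], be[, 2L]), pmax(be[, 1L], be[, 2L]))
  bmid <- match(bkey, uk) + nv
  boundary_edges <- matrix(0L, 2L * nrow(be), 2L)
  boundary_edges[2L * seq_len(nrow(be)) - 1L, ] <- cbind(be[, 1L], bmid)
  boundary_edges[2L * seq_len(nrow(be)), ] <- cbind(bmid, be[, 2L])
  electrodes <- lapply(mesh$electrodes,
                       function(ix) sort(c(2L * ix - 1L, 2L * ix)))

  bs_full <- rep(NA_real_, nv)
  if (!is.null(mesh$boundary_s)) {
    bidx <- sort(unique(as.vector(mesh$boundary_edges)))
    bs_full[bidx] <- mesh$boundary_s
  }
  bs_all <- c(bs_full, new_boundary_s)
  bidx_new <- sort(unique(as.vector(boundary_edges)))
  new_torso_mesh(nodes, elements, boundary_edges, electrodes,
                 outline = mesh$outline,
                 boundary_s = bs_all[bidx_new])
}

#' @export
print.torso_mesh <- function(x, ...) {
  cat(sprintf(
    "<torso_mesh> %d nodes, %d triangles, %d boundary edges, %d electrodes\n",
    nrow(x$nodes), nrow(x$elements), nrow(x$boundary_edges), length(x$electrodes)))
  cat(sprintf("  area %.6g m^2, min angle %.1f deg\n",
              sum(x$element_areas), mesh_min_angle(x)))
  invisible(x)
}

#' @export
as_tibble.torso_mesh <- function(x, ...) {
  tibble::tibble(
    element = seq_len(nrow(x$elements)),
    n1 = x$elements[, 1L], n2 = x$elements[, 2L], n3 = x$elements[, 3L],
    area = x$element_areas,
    cx = x$element_centroids[, 1L],
    cy = x$element_centroids[, 2L]
  )
}
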