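# Mesh serialization: a native sectioned text format and the Triangle
# .node/.ele dialect (with a sidecar electrode file).
#
# The native format stores coordinates with full double precision ("%.17g"),
# so write-then-read round-trips bit-exactly.

#' Read or write a torso mesh
#'
#' Native dialect: one text file with `nodes`, `elements`, `boundary_edges`,
#' `electrodes` and optional `boundary_s` / `outline` sections. Triangle
#' dialect: the classic `.node`/`.ele` pair (1-based indices) plus a
#' `.electrodes` sidecar listing each electrode's boundary edges as node
#' pairs; `path` is the stem without extension.
#'
#' @param path File path (native) or path stem (triangle).
#' @param mode `"read"` or `"write"`.
#' @param mesh The mesh to write (ignored on read).
#' @param dialect `"native"` or `"triangle"`.
#' @return The mesh (read) or `path` invisibly (write).
#' @export
mesh_io <- function(path, mode = c("read", "write"), mesh = NULL,
                    dialect = c("native", "triangle")) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  if (mode == "write") {
    stopifnot(inherits(mesh, "torso_mesh"))
    if (dialect == "native") write_mesh_native(mesh, path) else
      write_mesh_triangle(mesh, path)
    invisible(path)
  } else {
    if (dialect == "native") read_mesh_native(path) else
      read_mesh_triangle(path)
  }
}

#' @rdname mesh_io
#' @export
write_mesh <- function(mesh, path, dialect = "native") {
  mesh_io(path, "write", mesh, dialect)
}

#' @rdname mesh_io
#' @export
read_mesh <- function(path, dialect = "native") {
  mesh_io(path, "read", dialect = dialect)
}

fmt_full <- function(x) sprintf("%.17g", x)

write_mesh_native <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# torso_mesh v1")
  wl(sprintf("nodes %d", nrow(mesh$nodes)))
  wl(paste(fmt_full(mesh$nodes[, 1L]), fmt_full(mesh$nodes[, 2L])))
  wl(sprintf("elements %d", nrow(mesh$elements)))
  wl(paste(mesh$elements[, 1L], mesh$elements[, 2L], mesh$elements[, 3L]))
  wl(sprintf("boundary_edges %d", nrow(mesh$boundary_edges)))
  wl(paste(mesh$boundary_edges[, 1L], mesh$boundary_edges[, 2L]))
  wl(sprintf("electrodes %d", length(mesh$electrodes)))
  for (k in seq_along(mesh$electrodes)) {
    wl(paste(c(k, mesh$electrodes[[k]]), collapse = " "))
  }
  if (!is.null(mesh$boundary_s)) {
    wl(sprintf("boundary_s %d", length(mesh$boundary_s)))
    wl(fmt_full(mesh$boundary_s))
  }
  if (!is.null(mesh$outline)) {
    wl(sprintf("outline %d", nrow(mesh$outline)))
    wl(paste(fmt_full(mesh$outline[, 1L]), fmt_full(mesh$outline[, 2L])))
  }
}

read_mesh_native <- function(path) {
  lines <- readLines(path)
  i <- 1L
  err <- function(msg) stop(sprintf("%s (line %d of %s)", msg, i, path),
                            call. = FALSE)
  skip_comments <- function() {
    while (i <= length(lines) && grepl("^\\s*(#|$)", lines[i])) i <<- i + 1L
  }
  read_section <- function(name) {
    skip_comments()
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(hdr) != 2L || hdr[1L] != name) err(paste("expected section", name))
    n <- as.integer(hdr[2L])
    if (is.na(n) || n < 0L) err("bad section count")
    i <<- i + 1L
    n
  }
  read_num_rows <- function(n, k) {
    out <- matrix(NA_real_, n, k)
    for (r in seq_len(n)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      if (length(v) != k || anyNA(v)) err("malformed numeric row")
      out[r, ] <- v
      i <<- i + 1L
    }
    out
  }
  nv <- read_section("nodes")
  nodes <- read_num_rows(nv, 2L)
  nel <- read_section("elements")
  elements <- read_num_rows(nel, 3L)
  storage.mode(elements) <- "integer"
  if (any(elements < 1L) || any(elements > nv)) {
    stop(sprintf("element references a missing node (file %s)", path),
         call. = FALSE)
  }
  nb <- read_section("boundary_edges")
  boundary_edges <- read_num_rows(nb, 2L)
  storage.mode(boundary_edges) <- "integer"
  nelec <- read_section("electrodes")
  electrodes <- vector("list", nelec)
  for (k in seq_len(nelec)) {
    skip_comments()
    v <- suppressWarnings(as.integer(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (anyNA(v) || length(v) < 2L) err("malformed electrode row")
    electrodes[[v[1L]]] <- v[-1L]
    i <- i + 1L
  }
  boundary_s <- NULL
  outline <- NULL
  skip_comments()
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (hdr[1L] == "boundary_s") {
      n <- as.integer(hdr[2L]); i <- i + 1L
      boundary_s <- as.numeric(read_num_rows(n, 1L))
    } else if (hdr[1L] == "outline") {
      n <- as.integer(hdr[2L]); i <- i + 1L
      outline <- read_num_rows(n, 2L)
    } else err("unknown section")
    skip_comments()
  }
  new_torso_mesh(nodes, elements, boundary_edges, electrodes,
                 outline = outline, boundary_s = boundary_s)
}

write_mesh_triangle <- function(mesh, stem) {
  nv <- nrow(mesh$nodes)
  node_lines <- c(sprintf("%d 2 0 0", nv),
                  sprintf("%d %s %s", seq_len(nv),
                          fmt_full(mesh$nodes[, 1L]), fmt_full(mesh$nodes[, 2L])))
  writeLines(node_lines, paste0(stem, ".node"))
  ne <- nrow(mesh$elements)
  ele_lines <- c(sprintf("%d 3 0", ne),
                 sprintf("%d %d %d %d", seq_len(ne), mesh$elements[, 1L],
                         mesh$elements[, 2L], mesh$elements[, 3L]))
  writeLines(ele_lines, paste0(stem, ".ele"))
  el_lines <- sprintf("%d", length(mesh$electrodes))
  for (k in seq_along(mesh$electrodes)) {
    ed <- mesh$boundary_edges[mesh$electrodes[[k]], , drop = FALSE]
    el_lines <- c(el_lines,
                  paste(c(k, t(ed)), collapse = " "))
  }
  writeLines(el_lines, paste0(stem, ".electrodes"))
  invisible(stem)
}

read_mesh_triangle <- function(stem) {
  nf <- paste0(stem, ".node")
  node_lines <- readLines(nf)
  hdr <- as.integer(strsplit(trimws(node_lines[1L]), "\\s+")[[1L]])
  nv <- hdr[1L]
  nodes <- matrix(NA_real_, nv, 2L)
  for (r in seq_len(nv)) {
    v <- as.numeric(strsplit(trimws(node_lines[r + 1L]), "\\s+")[[1L]])
    nodes[v[1L], ] <- v[2:3]
  }
  if (anyNA(nodes)) stop("malformed .node file: missing node rows", call. = FALSE)
  ele_lines <- readLines(paste0(stem, ".ele"))
  ne <- as.integer(strsplit(trimws(ele_lines[1L]), "\\s+")[[1L]])[1L]
  elements <- matrix(NA_integer_, ne, 3L)
  for (r in seq_len(ne)) {
    v <- as.integer(strsplit(trimws(ele_lines[r + 1L]), "\\s+")[[1L]])
    elements[v[1L], ] <- v[2:4]
  }
  if (any(is.na(elements)) || any(elements < 1L) || any(elements > nv)) {
    stop(sprintf("dangling node index in %s.ele", stem), call. = FALSE)
  }
  # boundary edges: edges appearing in exactly one triangle
  ed <- rbind(elements[, c(1L, 2L)], elements[, c(2L, 3L)], elements[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  once <- names(which(table(key) == 1L))
  boundary_edges <- ed[match(once, key), , drop = FALSE]
  electrodes <- list()
  ef <- paste0(stem, ".electrodes")
  if (file.exists(ef)) {
    el_lines <- readLines(ef)
    nelec <- as.integer(el_lines[1L])
    electrodes <- vector("list", nelec)
    bkey <- paste(pmin(boundary_edges[, 1L], boundary_edges[, 2L]),
                  pmax(boundary_edges[, 1L], boundary_edges[, 2L]))
    for (k in seq_len(nelec)) {
      v <- as.integer(strsplit(trimws(el_lines[k + 1L]), "\\s+")[[1L]])
      pairs <- matrix(v[-1L], ncol = 2L, byrow = TRUE)
      pk <- paste(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
      idx <- match(pk, bkey)
      if (anyNA(idx)) {
        stop(sprintf("electrode %d references a non-boundary edge in %s", v[1L], ef),
             call. = FALSE)
      }
      electrodes[[v[1L]]] <- idx
    }
  }
  new_torso_mesh(nodes, elements, boundary_edges, electrodes)
}
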