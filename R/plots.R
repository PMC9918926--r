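# ggplot2 visualization and broom-style summaries.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Long triangle table for ggplot: one row per element vertex.
mesh_triangles_df <- function(mesh, values = NULL) {
  E <- nrow(mesh$elements)
  ids <- rep(seq_len(E), each = 3L)
  verts <- as.vector(t(mesh$elements))
  tibble::tibble(
    element = ids,
    x = mesh$nodes[verts, 1L],
    y = mesh$nodes[verts, 2L],
    value = if (is.null(values)) NA_real_ else rep(values, each = 3L)
  )
}

#' @export
autoplot.torso_mesh <- function(object, ...) {
  df <- mesh_triangles_df(object)
  ed <- object$boundary_edges[unlist(object$electrodes), , drop = FALSE]
  el_id <- rep(seq_along(object$electrodes),
               vapply(object$electrodes, length, 1L))
  eldf <- tibble::tibble(
    electrode = factor(rep(el_id, each = 2L)),
    x = as.vector(t(cbind(object$nodes[ed[, 1L], 1L], object$nodes[ed[, 2L], 1L]))),
    y = as.vector(t(cbind(object$nodes[ed[, 1L], 2L], object$nodes[ed[, 2L], 2L]))),
    seg = rep(seq_len(nrow(ed)), each = 2L)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$element),
                          fill = "grey95", colour = "grey60", linewidth = 0.2) +
    ggplot2::geom_line(data = eldf,
                       ggplot2::aes(group = .data$seg, colour = .data$electrode),
                       linewidth = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [m]", y = "y [m]", colour = "electrode") +
    ggplot2::theme_minimal()
}

#' Plot per-element values on the mesh
#'
#' @param mesh A `torso_mesh`.
#' @param values Per-element values (probabilities, labels, ...).
#' @param limits Fill scale limits.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_element_map <- function(mesh, values, limits = c(0, 1), title = NULL) {
  df <- mesh_triangles_df(mesh, values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$element, fill = .data$value),
                          colour = NA) +
    ggplot2::scale_fill_viridis_c(limits = limits) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [m]", y = "y [m]", fill = "p", title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prob_map <- function(object, mesh, ...) {
  plot_element_map(mesh, object$p,
                   title = paste("inclusion probability,", object$method))
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.roc_curve <- function(x, ...) x$curve

#' @export
glance.roc_curve <- function(x, ...) tibble::tibble(auc = x$auc)

#' @export
tidy.method_comparison <- function(x, ...) x$table

#' @export
tidy.pipeline_result <- function(x, ...) x$reports

#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(method = x$config$method,
                                  n = x$config$n,
                                  n_test = length(x$split$test)),
                   x$pooled)
}

#' @export
tidy.element_bank <- function(x, ...) {
  tibble::tibble(
    element = seq_len(x$n_elements),
    model = vapply(x$models, function(m) class(m)[1L], character(1L)),
    constant = vapply(x$models, inherits, logical(1L), "constant_model")
  )
}

#' @export
glance.logistic_en <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda,
                 n_nonzero = sum(x$coefficients != 0),
                 cv_accuracy = x$cv$accuracy[x$cv$lambda == x$lambda][1L])
}

#' @export
glance.gaussian_da <- function(x, ...) {
  tibble::tibble(mode = x$mode, m = x$m,
                 prior_0 = x$priors[1L], prior_1 = x$priors[2L],
                 alpha = x$alpha %||% NA_real_, gamma = x$gamma %||% NA_real_)
}

#' @export
glance.cart_tree <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes),
                 n_leaves = sum(is.na(x$nodes$feature)),
                 depth = tree_depth(x))
}

tree_depth <- function(tree) {
  nd <- tree$nodes
  depth_of <- function(id) {
    if (is.na(nd$feature[id])) return(0L)
    1L + max(depth_of(nd$left[id]), depth_of(nd$right[id]))
  }
  depth_of(1L)
}

#' @importFrom rlang .data
NULL
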