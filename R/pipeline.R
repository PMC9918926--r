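# End-to-end pipeline: mesh -> simulate -> train -> reconstruct -> evaluate.
#
# A pipeline_config fully determines every artifact; each random stage
# derives its sub-seed deterministically from the master seed, so a re-run
# with the same config reproduces all artifacts bit-exactly. run_pipeline()
# writes a manifest with an md5 content hash per artifact.

#' Pipeline configuration
#'
#' @param mesh_args Arguments for [build_torso_mesh()].
#' @param electrode_count Electrodes for [default_protocol()].
#' @param n Number of simulated frames.
#' @param conductivities Named vector `c(background=, inclusion=)` (S/m).
#' @param snr_db Noise level (dB); `Inf` = noiseless.
#' @param shape_args Arguments for [sample_inclusion()].
#' @param method Classifier bank method tag (see [train_bank()]).
#' @param folds CV folds.
#' @param holdout Held-out fraction for evaluation (default 0.2).
#' @param threshold Decision threshold.
#' @param raster_n Raster size for image-quality metrics.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mesh_args = list(target_edge_length = 0.015),
                            electrode_count = 8L,
                            n = 1000L,
                            conductivities = c(background = 0.2, inclusion = 1.0),
                            snr_db = Inf,
                            shape_args = list(),
                            method = "qda-pca",
                            folds = 10L,
                            holdout = 0.2,
                            threshold = 0.5,
                            raster_n = 64L,
                            seed = 1L) {
  stopifnot(holdout > 0, holdout < 1, n >= 5L)
  structure(list(mesh_args = mesh_args, electrode_count = electrode_count,
                 n = n, conductivities = conductivities, snr_db = snr_db,
                 shape_args = shape_args, method = method, folds = folds,
                 holdout = holdout, threshold = threshold,
                 raster_n = raster_n, seed = seed),
            class = "pipeline_config")
}

# Stage sub-seeds derived deterministically from the master seed.
stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max, 3L)
  list(dataset = s[1L], split = s[2L], train = s[3L])
}

# Deterministic train/held-out split.
split_dataset <- function(n, holdout, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(n)
  n_test <- max(1L, round(holdout * n))
  list(train = sort(idx[seq_len(n - n_test)]),
       test = sort(idx[(n - n_test + 1L):n]))
}

subset_dataset <- function(dataset, rows) {
  out <- dataset
  out$X <- dataset$X[rows, , drop = FALSE]
  out$Y <- dataset$Y[rows, , drop = FALSE]
  out$shapes <- dataset$shapes[rows, ]
  out$meta$n <- length(rows)
  out
}

#' Run the full pipeline
#'
#' Executes mesh construction, dataset simulation, bank training, held-out
#' reconstruction and evaluation; optionally persists all artifacts plus a
#' manifest of md5 content hashes.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @param quiet Suppress progress messages.
#' @return A `pipeline_result`: the mesh, dataset, bank, split indices, the
#'   per-frame held-out fit reports (tibble), the pooled report, and mean
#'   image-quality metrics.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- stage_seeds(config$seed)

  say("stage mesh: building torso mesh")
  mesh <- do.call(build_torso_mesh, config$mesh_args)
  protocol <- default_protocol(config$electrode_count)

  say("stage simulate: n = %d frames (seed %d)", config$n, seeds$dataset)
  dataset <- generate_dataset(mesh, protocol, n = config$n,
                              conductivities = config$conductivities,
                              snr_db = config$snr_db, seed = seeds$dataset,
                              shape_args = config$shape_args)

  split <- split_dataset(config$n, config$holdout, seeds$split)
  say("stage train: method %s on %d frames (seed %d)",
      config$method, length(split$train), seeds$train)
  bank <- train_bank(subset_dataset(dataset, split$train), config$method,
                     folds = config$folds, seed = seeds$train)

  say("stage evaluate: %d held-out frames", length(split$test))
  P <- reconstruct_frames(bank, dataset$X[split$test, , drop = FALSE])
  Yte <- dataset$Y[split$test, , drop = FALSE]
  reports <- purrr::map_dfr(seq_along(split$test), function(i) {
    y <- Yte[i, ]
    if (sum(y) == 0L || sum(y) == length(y)) return(NULL)
    dplyr::bind_cols(tibble::tibble(frame = split$test[i]),
                     fit_report(P[i, ], y, config$threshold))
  })
  pooled <- fit_report(as.numeric(P), as.numeric(Yte), config$threshold)

  iq <- purrr::map_dfr(seq_along(split$test), function(i) {
    y <- Yte[i, ]
    if (sum(y) == 0L) return(NULL)
    truth_img <- rasterize(y, mesh, config$raster_n)
    pred_img <- rasterize(threshold_map(P[i, ], config$threshold), mesh,
                          config$raster_n)
    image_quality(truth_img, pred_img)
  })

  result <- structure(list(
    config = config, mesh = mesh, protocol = protocol, dataset = dataset,
    bank = bank, split = split, reports = reports, pooled = pooled,
    image_quality = iq
  ), class = "pipeline_result")

  if (!is.null(out_dir)) persist_pipeline(result, out_dir)
  result
}

persist_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(result$mesh, file.path(out_dir, "mesh.txt"))
  write_dataset(result$dataset, file.path(out_dir, "dataset"))
  write_bank(result$bank, file.path(out_dir, "bank.json"))
  utils::write.csv(result$reports, file.path(out_dir, "reports.csv"),
                   row.names = FALSE)
  utils::write.csv(result$pooled, file.path(out_dir, "pooled_report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$image_quality, file.path(out_dir, "image_quality.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(train = result$split$train, test = result$split$test),
    file.path(out_dir, "split.json"))
  cfg <- result$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(out_dir)
}

#' Verify a persisted pipeline directory against its manifest
#' @param out_dir Directory written by [run_pipeline()].
#' @return TRUE invisibly; errors on hash mismatch.
#' @export
verify_manifest <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  md5 <- unname(tools::md5sum(file.path(out_dir, manifest$file)))
  bad <- manifest$file[md5 != manifest$md5]
  if (length(bad)) {
    stop("manifest verification failed for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Compare several bank methods on the same data and split
#'
#' Trains one bank per method on a shared dataset/split and evaluates all of
#' them on the same held-out frames, yielding a measures-by-methods table in
#' the style of the study's comparison tables.
#'
#' @param config A `pipeline_config` (its `method` field is ignored).
#' @param methods Character vector of method tags.
#' @param quiet Suppress progress messages.
#' @return A `method_comparison`: `table` (tibble, one row per measure, one
#'   column per method; pooled over held-out frames) and `mean_table` (mean
#'   of per-frame measures).
#' @export
compare_methods <- function(config, methods = c("lda", "qda", "rda",
                                                "lda-pca", "qda-pca"),
                            quiet = FALSE) {
  stopifnot(length(methods) >= 1L)
  seeds <- stage_seeds(config$seed)
  mesh <- do.call(build_torso_mesh, config$mesh_args)
  protocol <- default_protocol(config$electrode_count)
  dataset <- generate_dataset(mesh, protocol, n = config$n,
                              conductivities = config$conductivities,
                              snr_db = config$snr_db, seed = seeds$dataset,
                              shape_args = config$shape_args)
  split <- split_dataset(config$n, config$holdout, seeds$split)
  train_ds <- subset_dataset(dataset, split$train)
  Yte <- dataset$Y[split$test, , drop = FALSE]

  pooled_rows <- list(); mean_rows <- list()
  for (j in seq_along(methods)) {
    meth <- methods[j]
    if (!quiet) message("training ", meth)
    bank <- train_bank(train_ds, meth, folds = config$folds,
                       seed = seeds$train)
    P <- reconstruct_frames(bank, dataset$X[split$test, , drop = FALSE])
    pooled_rows[[j]] <- fit_report(as.numeric(P), as.numeric(Yte),
                                   config$threshold)
    per_frame <- purrr::map_dfr(seq_len(nrow(Yte)), function(i) {
      y <- Yte[i, ]
      if (sum(y) == 0L || sum(y) == length(y)) return(NULL)
      fit_report(P[i, ], y, config$threshold)
    })
    mean_rows[[j]] <- dplyr::summarise(
      per_frame, dplyr::across(dplyr::where(is.numeric), mean))
  }
  keep <- c("accuracy", "sensitivity", "specificity",
            "pos_pred_value", "neg_pred_value", "precision", "f1",
            "prevalence", "detection_rate", "detection_prevalence",
            "balanced_accuracy", "auc", "kappa",
            "mcnemar_raw", "mcnemar_corrected")
  to_long <- function(rows) {
    cols <- lapply(rows, function(r) as.numeric(r[1L, keep]))
    out <- as.data.frame(cols, optional = TRUE)
    names(out) <- methods                   # duplicate tags stay duplicated
    tibble::as_tibble(cbind(data.frame(measure = keep), out),
                      .name_repair = "minimal")
  }
  structure(list(table = to_long(pooled_rows),
                 mean_table = to_long(mean_rows),
                 methods = methods),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> pooled held-out measures\n")
  tbl <- x$table
  tbl[-1L] <- lapply(tbl[-1L], round_half_up)
  print(as.data.frame(tbl), row.names = FALSE)
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> method %s, n = %d (%d held out)\n",
              x$config$method, x$config$n, length(x$split$test)))
  cat(sprintf("  pooled: AUC %.3f, kappa %.3f, accuracy %.3f\n",
              x$pooled$auc, x$pooled$kappa, x$pooled$accuracy))
  invisible(x)
}

# Bank serialization (versioned JSON schema) ------------------------------

serialize_model <- function(model) {
  if (inherits(model, "constant_model")) {
    list(type = "constant", rate = model$rate)
  } else if (inherits(model, "logistic_en")) {
    list(type = "logistic_en", coefficients = model$coefficients,
         intercept = model$intercept, alpha = model$alpha,
         lambda = model$lambda)
  } else if (inherits(model, "gaussian_da")) {
    list(type = "gaussian_da", mode = model$mode, priors = model$priors,
         means = model$means, covs = model$covs,
         alpha = model$alpha, gamma = model$gamma, m = model$m)
  } else if (inherits(model, "cart_tree")) {
    list(type = "cart_tree", nodes = as.list(model$nodes), m = model$m,
         hyper = model$hyper)
  } else stop("cannot serialize model", call. = FALSE)
}

deserialize_model <- function(s) {
  switch(s$type,
    constant = constant_model(s$rate),
    logistic_en = structure(list(coefficients = s$coefficients,
                                 intercept = s$intercept, alpha = s$alpha,
                                 lambda = s$lambda), class = "logistic_en"),
    gaussian_da = {
      covs <- if (is.array(s$covs) && length(dim(s$covs)) == 3L) {
        lapply(seq_len(dim(s$covs)[1L]),
               function(i) matrix(s$covs[i, , ], dim(s$covs)[2L]))
      } else {
        lapply(s$covs, as.matrix)
      }
      means <- if (is.matrix(s$means)) {
        lapply(seq_len(nrow(s$means)), function(i) as.numeric(s$means[i, ]))
      } else {
        lapply(s$means, as.numeric)
      }
      structure(list(mode = s$mode, priors = s$priors,
                     means = means,
                     covs = covs, chols = lapply(covs, chol),
                     alpha = s$alpha, gamma = s$gamma, m = s$m),
                class = "gaussian_da")
    },
    cart_tree = {
      nd <- s$nodes
      len <- length(nd$n)
      fix_col <- function(v) {
        if (is.null(v)) return(rep(NA, len))
        if (is.list(v)) v <- unlist(lapply(v, function(x) x %||% NA))
        rep_len(v, len)
      }
      nodes <- tibble::tibble(
        feature = as.integer(fix_col(nd$feature)),
        threshold = as.numeric(fix_col(nd$threshold)),
        left = as.integer(fix_col(nd$left)),
        right = as.integer(fix_col(nd$right)),
        n = as.integer(nd$n), n1 = as.integer(nd$n1),
        prob = as.numeric(nd$prob))
      structure(list(nodes = nodes, m = s$m, hyper = s$hyper),
                class = "cart_tree")
    },
    stop("unknown model type in bank file", call. = FALSE))
}

#' Write / read a classifier bank as JSON
#'
#' Versioned schema holding the method tag, hyperparameters, per-element
#' parameter blocks, the shared PCA transform and training metadata.
#' Numbers are stored at full precision.
#'
#' @param bank An `element_bank`.
#' @param path File path.
#' @return `write_bank()` the path invisibly; `read_bank()` the bank.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "element_bank"))
  payload <- list(
    schema = "eitclass-bank-v1",
    method = bank$method,
    n_elements = bank$n_elements,
    protocol_id = bank$protocol_id,
    meta = bank$meta,
    pca = if (is.null(bank$pca)) NULL else unclass(bank$pca),
    models = lapply(bank$models, serialize_model)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = TRUE)
  if (!identical(s$schema, "eitclass-bank-v1")) {
    stop("unrecognized bank schema in ", path, call. = FALSE)
  }
  pca <- s$pca
  if (!is.null(pca)) {
    pca$loadings <- as.matrix(pca$loadings)
    class(pca) <- "pca_transform"
  }
  structure(list(method = s$method,
                 models = lapply(s$models, deserialize_model),
                 pca = pca,
                 n_elements = s$n_elements,
                 protocol_id = s$protocol_id,
                 meta = s$meta),
            class = "element_bank")
}
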