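# End-to-end pipeline driver and run configuration, shared by the R API and
# the command-line front-end (inst/scripts/cellshaper).

#' Run configuration
#'
#' Collects the tunable parameters of an end-to-end run. Every stochastic
#' stage derives its stream from `seed`; outputs record the configuration
#' hash for provenance.
#'
#' @param n_shapes number of synthetic shapes to generate.
#' @param kind `"snl3d"`, `"blob3d"`, `"snl2d"` or `"pair2d"`.
#' @param max_order working SPHARM degree L for 3D shapes.
#' @param dims latent dimensions of the fitted shape space.
#' @param n_steps interpolation steps for the evolution stage.
#' @param seed master seed.
#' @param failure_threshold parameterization failure threshold in pixels.
#' @param out_dir output directory.
#' @param extra named list merged into the configuration.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_shapes = 10L, kind = "snl3d", max_order = 15L,
                       dims = 7L, n_steps = 10L, seed = 1L,
                       failure_threshold = 100, out_dir = "cellshaper_run",
                       extra = list()) {
  cfg <- list(n_shapes = as.integer(n_shapes), kind = kind,
              max_order = as.integer(max_order), dims = as.integer(dims),
              n_steps = as.integer(n_steps), seed = as.integer(seed),
              failure_threshold = failure_threshold, out_dir = out_dir)
  cfg[names(extra)] <- extra
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[sort(names(unclass(cfg)))], f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline from a configuration
#'
#' Simulates the requested synthetic dataset, runs parameterization /
#' outline extraction, fits the linear shape space, evaluates reconstruction
#' errors, and (for at least two shapes) computes one example evolution
#' path. Artifacts (error report, reconstructions, manifest with the
#' configuration hash) are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the fitted model, embeddings, the
#'   [error_report()], and per-shape diagnostics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("cellshaper run %s", hash),
                 sprintf("kind=%s n=%d seed=%d", config$kind,
                         config$n_shapes, config$seed))
  if (config$kind %in% c("snl3d", "blob3d")) {
    out <- run_pipeline_3d(config, hash)
  } else if (config$kind == "snl2d") {
    out <- run_pipeline_2d(config, hash)
  } else stop("unsupported kind: ", config$kind)
  manifest <- list(config = unclass(config), config_hash = hash,
                   mean_error = out$report$mean_error,
                   n_shapes = config$n_shapes,
                   failures = out$n_failures)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  writeLines(c(log_lines, sprintf("mean_error=%g", out$report$mean_error),
               sprintf("failures=%d", out$n_failures)),
             file.path(config$out_dir, "run.log"))
  invisible(out)
}

run_pipeline_3d <- function(config, hash) {
  n <- config$n_shapes
  descs <- vector("list", n)
  meshes <- vector("list", n)
  volumes <- vector("list", n)
  n_failures <- 0L
  diags <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- if (config$kind == "snl3d")
      generate_snl_3d(snl_params(n_neurites = c(0L, 2L), seed = config$seed),
                      index = i)
    else generate_blob_3d(seed = derive_seed(config$seed, i))
    res <- tryCatch(
      parameterize_robust(vol, list(max_order = config$max_order,
                                    failure_threshold = config$failure_threshold)),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failures <- n_failures + 1L
      diags[[i]] <- attr(res, "diagnostics")
      next
    }
    descs[[i]] <- foe_align(res$descriptor)
    meshes[[i]] <- res$mesh
    volumes[[i]] <- vol
    diags[[i]] <- res$diagnostics
  }
  ok <- which(!vapply(descs, is.null, logical(1)))
  if (length(ok) < 2) stop("fewer than 2 shapes parameterized successfully")
  descs <- descs[ok]; volumes <- volumes[ok]
  n_ok <- length(ok)
  if (config$dims > n_ok - 1)
    stop("dims = ", config$dims, " requires more than ", config$dims + 1,
         " successfully parameterized shapes")
  k <- config$dims
  model <- fit_descriptor_pca(descs, k)
  Z <- t(vapply(descs, function(d) embed(model, d), numeric(k)))
  errs <- numeric(n_ok)
  for (i in seq_len(n_ok)) {
    recon <- decode_shape(model, Z[i, ])
    errs[i] <- reconstruction_error_3d(volumes[[i]], recon)
    if (i <= 3) write_obj(recon, file.path(config$out_dir,
                                           sprintf("recon_%02d.obj", i)))
  }
  report <- error_report(errs, method = "spharm-rpdm-pca", latent_dims = k,
                         n_norm_params = 1L, dataset_id = config$kind)
  write_error_report(report, file.path(config$out_dir, "errors"))
  if (n >= 2) {
    ev <- evolution_energy(model, Z[1, ], Z[2, ], N = config$n_steps)
    jsonlite::write_json(list(normalized_energy = ev$normalized_energy,
                              energy = ev$energy, n_steps = ev$n_steps),
                         file.path(config$out_dir, "evolution.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(model = model, embeddings = Z, report = report,
       diagnostics = diags, n_failures = n_failures)
}

run_pipeline_2d <- function(config, hash) {
  n <- config$n_shapes
  params <- snl_params(seed = config$seed)
  outlines <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- generate_snl_2d(params, index = i)
    outlines[[i]] <- align_outline(extract_outline(mask, 2000L))
  }
  k <- min(config$dims, n - 1)
  if (config$dims > n - 1)
    stop("dims = ", config$dims, " requires more than ", n, " shapes")
  model <- fit_outline_pca(outlines, k)
  Z <- t(vapply(outlines, function(o) pca_encode(model, o), numeric(k)))
  errs <- vapply(seq_len(n), function(i)
    reconstruction_error_2d(outlines[[i]], pca_decode(model, Z[i, ])),
    numeric(1))
  report <- error_report(errs, method = "outline-pca", latent_dims = k,
                         n_norm_params = 1L, dataset_id = "snl2d")
  write_error_report(report, file.path(config$out_dir, "errors"))
  if (n >= 2) {
    ev <- evolution_energy(model, Z[1, ], Z[2, ], N = config$n_steps)
    jsonlite::write_json(list(normalized_energy = ev$normalized_energy,
                              energy = ev$energy, n_steps = ev$n_steps),
                         file.path(config$out_dir, "evolution.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(model = model, embeddings = Z, report = report,
       diagnostics = NULL, n_failures = 0L)
}
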