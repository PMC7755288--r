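#' Pipeline configuration
#'
#' Bundles the paths and parameters of a full analysis run: cells (positions
#' and polarity tensors or tripods), an optional segment network, the
#' reference mode (`"local"` for the punctured-Gaussian average of the
#' polarity tensors, `"network"` for the local network anisotropy), and the
#' model-fit switch. All lengths in micrometres. The configuration
#' round-trips through JSON and its hash is embedded in every output.
#'
#' @param cells Path to the cells CSV (see [read_cells()]).
#' @param segments Path to the segments CSV (required for
#'   `reference = "network"` and for the model fit).
#' @param reference `"local"` or `"network"`.
#' @param sigma Gaussian kernel standard deviation for the local reference
#'   (micrometres).
#' @param radius Region-of-interest radius for the network tensor
#'   (micrometres).
#' @param band_limit Spherical-harmonic band limit used where patterns are
#'   decomposed.
#' @param fit_model Run [fit_lambda()] against the measured COOP.
#' @param lambda_max,lambda_step Sweep grid for the model fit.
#' @param n_samples Model ensemble size per sweep point.
#' @param seed Seed for every stochastic stage.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cells, segments = NULL,
                       reference = c("network", "local"),
                       sigma = 20, radius = 20, band_limit = 16L,
                       fit_model = FALSE, lambda_max = 8, lambda_step = 0.25,
                       n_samples = 10000L, seed = 1L, out_dir = NULL) {
  reference <- match.arg(reference)
  stopifnot(sigma > 0, radius > 0, band_limit >= 0, lambda_max > 0,
            lambda_step > 0, n_samples >= 1)
  structure(list(cells = cells, segments = segments, reference = reference,
                 sigma = sigma, radius = radius,
                 band_limit = as.integer(band_limit),
                 fit_model = fit_model, lambda_max = lambda_max,
                 lambda_step = lambda_step, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Representative reference tensor of a network field
#'
#' Diagonal tensor built from the mean ordered eigenvalues of the non-empty
#' local tensors of a [network_field()] table; used as the fixed reference of
#' model sweeps matched to a measured tissue.
#'
#' @param field A [network_field()] tibble.
#' @return A `nematic_tensor` (frame: `v = e1` along x, `w = e2` along y,
#'   `u = e3` along z).
#' @export
field_reference_tensor <- function(field) {
  ok <- !field$empty
  eig <- t(vapply(which(ok), function(i) {
    m <- matrix(c(field$xx[i], field$xy[i], field$xz[i],
                  field$xy[i], field$yy[i], field$yz[i],
                  field$xz[i], field$yz[i], field$zz[i]), 3, 3)
    sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }, numeric(3)))
  mean_eig <- colMeans(eig)  # eps1 >= eps3 >= eps2
  mean_eig <- mean_eig - mean(mean_eig)
  as_nematic_tensor(diag(c(mean_eig[1], mean_eig[3], mean_eig[2])))
}

#' Run the full co-orientation analysis pipeline
#'
#' Orchestrates: read cells (and segments) -> derive polarity tripods from
#' tensors where needed -> build the reference field (punctured-Gaussian
#' local average or local network anisotropy) -> COOP -> optional
#' coupling-strength fit. When `out_dir` is set, every stage's outputs are
#' written (`coop.json`, `field.csv`, `sweep.csv`, `fit.json`) together with
#' a `log.json` recording the package version, seed and configuration hash;
#' identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return A list of class `run_bundle`: `cells`, `tripods`, `field` (or
#'   local reference tibble), `coop` (`coop_result`), `fit` (`lambda_fit` or
#'   `NULL`), `config`, `hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cells <- stage("read_cells", read_cells(config$cells))

  tensor_cols <- c("xx", "xy", "xz", "yy", "yz", "zz")
  tripod_cols <- c("nx", "ny", "nz", "mx", "my", "mz", "lx", "ly", "lz")
  tripods <- stage("polarity_axes", {
    if (all(tripod_cols %in% names(cells))) {
      validate_tripods(cells[tripod_cols])
    } else {
      # tripod roles from the polarity tensor: n = ring axis a2, m = a1
      mats <- tensor_list(cells[tensor_cols])
      axs <- lapply(mats, ordered_axes)
      tripod_ensemble(
        n = t(vapply(axs, `[[`, numeric(3), "a2")),
        m = t(vapply(axs, `[[`, numeric(3), "a1")),
        l = t(vapply(axs, `[[`, numeric(3), "a3")))
    }
  })

  field <- NULL
  if (config$reference == "network") {
    if (is.null(config$segments)) {
      stop("stage 'network_field' failed: reference = \"network\" needs a segments file",
           call. = FALSE)
    }
    segments <- stage("read_segments", read_segments(config$segments))
    field <- stage("network_field",
                   network_field(segments, cells, radius = config$radius))
    keep <- !field$empty & !field$degenerate
    coop_res <- stage("coop", {
      res <- coop_vs_tensors(tripods[keep, ], field[keep, tensor_cols],
                             seed = config$seed)
      res$dropped <- res$dropped + sum(!keep)
      res
    })
    ref_tensor <- stage("reference_tensor", field_reference_tensor(field))
  } else {
    if (!all(tensor_cols %in% names(cells))) {
      stop("stage 'local_reference' failed: local reference needs tensor columns",
           call. = FALSE)
    }
    field <- stage("local_reference",
                   local_reference_field(cells, sigma = config$sigma))
    keep <- !field$degenerate
    coop_res <- stage("coop", {
      res <- coop(tripods[keep, ], field[keep, 1:9], seed = config$seed)
      res$dropped <- sum(!keep)
      res
    })
    ref_tensor <- stage("reference_tensor",
                        field_reference_tensor(dplyr::mutate(field, empty = FALSE)))
  }

  fit <- NULL
  if (isTRUE(config$fit_model)) {
    fit <- stage("fit_lambda", fit_lambda(
      coop_res, reference = ref_tensor,
      lambdas = seq(0, config$lambda_max, by = config$lambda_step),
      config = model_config(n_samples = config$n_samples,
                            seed = config$seed)))
  }

  bundle <- structure(list(cells = cells, tripods = tripods, field = field,
                           coop = coop_res, fit = fit,
                           reference_tensor = ref_tensor,
                           config = config, hash = config_hash(config)),
                      class = "run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "nematiq",
               version = as.character(utils::packageVersion("nematiq")),
               seed = bundle$config$seed, config = unclass(bundle$config),
               config_hash = bundle$hash)
  jsonlite::write_json(meta, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  obj <- list(estimates = bundle$coop$estimates, n = bundle$coop$n,
              dropped = bundle$coop$dropped, config_hash = bundle$hash)
  jsonlite::write_json(obj, file.path(out_dir, "coop.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(bundle$field, file.path(out_dir, "field.csv"))
  if (!is.null(bundle$fit)) {
    readr::write_csv(bundle$fit$sweep, file.path(out_dir, "sweep.csv"))
    jsonlite::write_json(list(lambda_hat = bundle$fit$lambda_hat,
                              interval = bundle$fit$interval,
                              boundary = bundle$fit$boundary,
                              config_hash = bundle$hash),
                         file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle>", nrow(x$cells), "cells; reference =",
      x$config$reference, "\n")
  print(x$coop)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
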