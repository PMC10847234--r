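#' Write a parameter snapshot
#'
#' Serializes a [network_params()] as flat CSV matrices (one weights and
#' one delays file per non-input layer) plus a JSON sidecar manifest
#' recording the layer sizes, the neuron constants and a format-version
#' string.
#'
#' @param params A [network_params()].
#' @param dir Output directory (created if missing).
#' @param config The [neuron_config()] the parameters were trained under.
#' @return `dir`, invisibly.
#' @export
write_params <- function(params, dir, config = neuron_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = "delayprop-params-1",
    layer_sizes = params$layer_sizes,
    tau_m = config$tau_m, tau_s = config$tau_s,
    theta = config$theta, d_max = config$d_max
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (l in seq_along(params$weights)) {
    readr::write_csv(as.data.frame(params$weights[[l]]),
                     file.path(dir, sprintf("weights_l%d.csv", l + 1)),
                     col_names = FALSE, progress = FALSE)
    readr::write_csv(as.data.frame(params$delays[[l]]),
                     file.path(dir, sprintf("delays_l%d.csv", l + 1)),
                     col_names = FALSE, progress = FALSE)
  }
  invisible(dir)
}

#' Read a parameter snapshot
#'
#' @param dir Directory written by [write_params()].
#' @return A list with `params` (a [network_params()]) and `config` (the
#'   [neuron_config()] recorded in the manifest).
#' @export
read_params <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no parameter manifest at `%s`.", manifest_path))
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(m$format_version, "delayprop-params-1")) {
    abort(sprintf("unsupported parameter-archive version `%s`.",
                  m$format_version))
  }
  config <- neuron_config(m$tau_m, m$tau_s, m$theta, m$d_max)
  sizes <- as.integer(m$layer_sizes)
  read_mat <- function(path, nr, nc) {
    M <- as.matrix(readr::read_csv(path, col_names = FALSE,
                                   show_col_types = FALSE, progress = FALSE))
    dimnames(M) <- NULL
    if (!identical(dim(M), as.integer(c(nr, nc)))) {
      abort(sprintf("`%s` has shape %dx%d, expected %dx%d.",
                    path, nrow(M), ncol(M), nr, nc))
    }
    M
  }
  weights <- list()
  delays <- list()
  for (l in seq_len(length(sizes) - 1)) {
    weights[[l]] <- read_mat(file.path(dir, sprintf("weights_l%d.csv", l + 1)),
                             sizes[l], sizes[l + 1])
    delays[[l]] <- read_mat(file.path(dir, sprintf("delays_l%d.csv", l + 1)),
                            sizes[l], sizes[l + 1])
  }
  list(params = network_params(sizes, weights, delays, config),
       config = config)
}

#' Write a training-history log
#'
#' One line per epoch in delimited text (`epoch`, `mean_loss`,
#' `train_accuracy`, plus any extra columns present).
#'
#' @param history History tibble from an [srm_fit()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  readr::write_csv(history, path, progress = FALSE)
  invisible(path)
}
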