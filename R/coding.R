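#' Population-encoding configuration
#'
#' Parameters of the Gaussian receptive-field population code that turns a
#' real-valued feature into the spike times of `neurons_per_feature`
#' neurons.  Neuron `c` (`c = 1..M`) has center
#' `mu_c = i_min + (2c - 3)/2 * (i_max - i_min)/(M - 2)` and all neurons
#' share width `sigma = (i_max - i_min) / (gamma * (M - 2))` — the classic
#' layout with the two edge neurons centered just outside the feature
#' range.  A feature value elicits response `r_c = exp(-(v - mu_c)^2 /
#' (2 sigma^2))`; stronger response means earlier spike:
#' `t_c = (1 - r_c) * t_window`, snapped to the `dt` grid.  Responses below
#' `fire_cutoff` emit no spike at all (the weakly driven edge neurons stay
#' silent).
#'
#' @param neurons_per_feature Number of encoding neurons M per feature
#'   (>= 3 so the layout formulas are defined).
#' @param i_min,i_max Feature range bounds (`i_min < i_max`).
#' @param gamma Receptive-field width factor (> 0); larger = narrower
#'   fields.
#' @param t_window Encoding interval length in ms.
#' @param fire_cutoff Minimum Gaussian response to emit a spike, in (0, 1).
#' @param dt Grid step used to snap spike times (ms).
#' @return An object of class `population_encoding_config`.
#' @export
population_encoding_config <- function(neurons_per_feature = 6,
                                       i_min = 0, i_max = 1,
                                       gamma = 1.5, t_window = 10,
                                       fire_cutoff = 0.1, dt = 0.1) {
  stopifnot(neurons_per_feature >= 3, i_min < i_max, gamma > 0,
            t_window > 0, fire_cutoff > 0, fire_cutoff < 1, dt > 0)
  structure(
    list(neurons_per_feature = as.integer(neurons_per_feature),
         i_min = i_min, i_max = i_max, gamma = gamma,
         t_window = t_window, fire_cutoff = fire_cutoff, dt = dt),
    class = "population_encoding_config"
  )
}

# Receptive-field centers and shared width for a config.
population_fields <- function(cfg) {
  M <- cfg$neurons_per_feature
  span <- cfg$i_max - cfg$i_min
  centers <- cfg$i_min + (2 * seq_len(M) - 3) / 2 * span / (M - 2)
  sigma <- span / (cfg$gamma * (M - 2))
  list(centers = centers, sigma = sigma)
}

#' Population-encode one feature value
#'
#' @param value Scalar feature value.  Values outside `[i_min, i_max]` are
#'   clipped to the range with a warning, not rejected.
#' @param cfg A [population_encoding_config()].
#' @return Spike-time vector of length `neurons_per_feature` (ms; `NA` for
#'   neurons whose response falls below `fire_cutoff`).
#' @export
population_encode <- function(value, cfg = population_encoding_config()) {
  stopifnot(is.numeric(value), length(value) == 1)
  if (is.na(value)) abort("`value` must not be NA.")
  if (value < cfg$i_min || value > cfg$i_max) {
    warn(sprintf("feature value %g outside [%g, %g]; clipped.",
                 value, cfg$i_min, cfg$i_max))
    value <- min(max(value, cfg$i_min), cfg$i_max)
  }
  rf <- population_fields(cfg)
  r <- exp(-(value - rf$centers)^2 / (2 * rf$sigma^2))
  t_raw <- (1 - r) * cfg$t_window
  t_snap <- round(t_raw / cfg$dt) * cfg$dt
  ifelse(r < cfg$fire_cutoff, NA_real_, t_snap)
}

#' Latency-encode an intensity vector
#'
#' Maps each intensity linearly to a first-spike time: full intensity fires
#' at time 0, weaker intensities later, `t_i = (1 - p_i / p_max) *
#' t_window` snapped to the grid.  Zero-intensity entries are silent.
#'
#' @param pixels Non-negative intensity vector (e.g. image pixels).
#' @param t_window Encoding interval length in ms.
#' @param p_max Maximum representable intensity (> 0); defaults to 255.
#' @param dt Grid step used to snap spike times (ms).
#' @return Spike-time vector (ms; `NA` for zero intensities).
#' @export
latency_encode <- function(pixels, t_window = 10, p_max = 255, dt = 0.1) {
  stopifnot(is.numeric(pixels), p_max > 0, t_window > 0, dt > 0)
  if (any(pixels < 0, na.rm = TRUE)) {
    abort("negative intensities are not valid latency-encoding input.")
  }
  t_raw <- (1 - pmin(pixels, p_max) / p_max) * t_window
  t_snap <- round(t_raw / dt) * dt
  ifelse(pixels == 0, NA_real_, t_snap)
}

#' Desired output spike times for a class label
#'
#' Builds the target vector the temporal loss trains toward: the neuron of
#' the sample's class is asked to fire early (`t_early`), every other
#' output neuron late (`t_late`), which realizes "keep the non-target
#' neurons quiet" while still giving the loss a time for every output.
#'
#' In `"dynamic"` mode the target time adapts to the network's current
#' behavior: it is `max(t_early, earliest current output spike - margin)`,
#' pulling the target neuron just ahead of the pack instead of all the way
#' to `t_early` at once; with no output spikes to adapt to it falls back to
#' the static rule.  Static mode is the default for reproducibility.
#'
#' @param label Class index in `1..n_classes`.
#' @param n_classes Number of classes (= output neurons).
#' @param t_early Desired time for the target neuron (ms).
#' @param t_late Desired time for non-target neurons (ms, > `t_early`);
#'   placing it at the end of the simulation window trains non-targets
#'   toward silence, which is what the firing-count decision rule expects.
#' @param mode `"static"` or `"dynamic"`.
#' @param record Current `srm_record` (only used in dynamic mode).
#' @param margin Lead over the earliest current output spike in dynamic
#'   mode (ms).
#' @return Numeric vector of desired times, length `n_classes`, with
#'   `desired[label] < desired[k != label]`.
#' @export
desired_times <- function(label, n_classes, t_early = 14, t_late = 25,
                          mode = c("static", "dynamic"), record = NULL,
                          margin = 2) {
  mode <- match.arg(mode)
  stopifnot(label >= 1, label <= n_classes, t_early < t_late)
  out <- rep(t_late, n_classes)
  target <- t_early
  if (mode == "dynamic" && !is.null(record)) {
    t_o <- output_times(record)
    if (any(!is.na(t_o))) {
      target <- min(max(t_early, min(t_o, na.rm = TRUE) - margin),
                    t_late - 1e-9)
    }
  }
  out[label] <- target
  out
}

#' Classify a simulated record by its output layer
#'
#' The winner is the output neuron with the most spikes (under the
#' at-most-one-spike constraint: firing beats silence).  Among neurons with
#' equal spike counts the winner is the one with the largest membrane
#' potential over the window; exact ties go to the lowest index, so the
#' rule is total and deterministic.
#'
#' @param record An `srm_record` from [simulate_forward()].
#' @return Class index in `1..n_output`.
#' @export
classify_record <- function(record) {
  L <- length(record$times)
  t_o <- record$times[[L]]
  v_max <- record$v_max[[L]]
  counts <- as.integer(!is.na(t_o))
  cand <- which(counts == max(counts))
  cand[which.max(v_max[cand])]
}

#' Decoder for single-output-neuron tasks
#'
#' With one output neuron there is no per-class neuron to compare; the
#' class is instead the one whose desired output time is nearest to the
#' actual first-spike time.  A silent output decodes to the class with the
#' latest desired time (silence is "very late").
#'
#' @param class_times Numeric vector: desired output time of class `k` at
#'   position `k`.
#' @return A function `record -> class index` usable as a `decoder`.
#' @export
decoder_nearest_time <- function(class_times) {
  force(class_times)
  function(record) {
    t_o <- output_times(record)[1]
    if (is.na(t_o)) return(which.max(class_times))
    which.min(abs(class_times - t_o))
  }
}

#' Encode a feature table into spike-time samples
#'
#' Applies [population_encode()] to every feature of every row, optionally
#' appends a reference (bias) neuron firing at time 0, and attaches the
#' desired output times for each row's label.  Feature ranges default to
#' the per-feature min/max of the supplied data; pass `ranges` (a
#' two-row matrix, features in columns) to reuse the ranges of a training
#' set when encoding a test set.
#'
#' @param data Data frame with numeric feature columns and a label column.
#' @param label_col Name of the label column (integer classes `1..K`).
#' @param cfg A [population_encoding_config()]; its `i_min`/`i_max` are
#'   replaced per feature.
#' @param n_classes Number of classes; defaults to `max(label)`.
#' @param add_bias Append one always-on reference neuron spiking at t = 0.
#' @param t_early,t_late Desired output times passed to [desired_times()].
#' @param ranges Optional `2 x n_features` matrix of (min, max) per
#'   feature.
#' @return A tibble with list-columns `input_times`, `desired_times` and an
#'   integer `label` column; one row per sample.  The attribute `"ranges"`
#'   carries the feature ranges used.
#' @export
encode_features <- function(data, label_col = "label",
                            cfg = population_encoding_config(),
                            n_classes = NULL, add_bias = TRUE,
                            t_early = 14, t_late = 25, ranges = NULL) {
  stopifnot(label_col %in% names(data))
  labels <- as.integer(data[[label_col]])
  feats <- as.matrix(data[setdiff(names(data), c(label_col, "split"))])
  if (!is.numeric(feats)) abort("feature columns must be numeric.")
  if (is.null(n_classes)) n_classes <- max(labels)
  if (is.null(ranges)) {
    ranges <- rbind(apply(feats, 2, min), apply(feats, 2, max))
  }
  cfgs <- lapply(seq_len(ncol(feats)), function(f) {
    lo <- ranges[1, f]
    hi <- ranges[2, f]
    if (hi <= lo) hi <- lo + 1e-6  # constant feature: degenerate range
    modifyList(cfg, list(i_min = lo, i_max = hi))
  })
  input_times <- lapply(seq_len(nrow(feats)), function(r) {
    enc <- unlist(lapply(seq_len(ncol(feats)), function(f) {
      v <- min(max(feats[r, f], cfgs[[f]]$i_min), cfgs[[f]]$i_max)
      population_encode(v, cfgs[[f]])
    }))
    if (add_bias) enc <- c(enc, 0)
    unname(enc)
  })
  out <- tibble::tibble(
    input_times = input_times,
    desired_times = lapply(labels, desired_times, n_classes = n_classes,
                           t_early = t_early, t_late = t_late),
    label = labels
  )
  attr(out, "ranges") <- ranges
  out
}

#' Read a delimited feature table
#'
#' Thin wrapper over [readr::read_delim()] that returns a tibble with the
#' label column named `label`, ready for [encode_features()].
#'
#' @param path File path.
#' @param label_col Label column, by name or (integer) position.
#' @param delim Field delimiter (default comma).
#' @param col_names Whether the file has a header row.
#' @return A tibble with numeric feature columns and an integer `label`.
#' @export
read_feature_table <- function(path, label_col = "label", delim = ",",
                               col_names = TRUE) {
  df <- readr::read_delim(path, delim = delim, col_names = col_names,
                          show_col_types = FALSE, progress = FALSE)
  if (is.numeric(label_col)) label_col <- names(df)[label_col]
  if (!label_col %in% names(df)) {
    abort(sprintf("label column `%s` not found.", label_col))
  }
  names(df)[names(df) == label_col] <- "label"
  df$label <- as.integer(df$label)
  tibble::as_tibble(df)
}

#' Read an IDX raster file
#'
#' Reads the fixed-header big-endian IDX format used for raster image
#' archives (magic bytes 0, 0, type code, rank; then one 32-bit dimension
#' per axis; then the data).  Supports unsigned-byte (0x08), signed-byte
#' (0x09), 32-bit-integer (0x0C), float (0x0D) and double (0x0E) payloads.
#'
#' @param path File path.
#' @return For rank 1 a vector; otherwise an array with the file's
#'   dimensions (first axis = item index).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0) abort("not an IDX file (bad magic).")
  type <- magic[3]
  rank <- magic[4]
  dims <- readBin(con, "integer", n = rank, size = 4, endian = "big")
  n <- prod(dims)
  data <- switch(as.character(type),
    "8" = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    "9" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "12" = readBin(con, "integer", n = n, size = 4, endian = "big"),
    "13" = readBin(con, "numeric", n = n, size = 4, endian = "big"),
    "14" = readBin(con, "numeric", n = n, size = 8, endian = "big"),
    abort(sprintf("unsupported IDX type code 0x%02X.", type))
  )
  if (length(data) != n) abort("truncated IDX payload.")
  if (rank == 1) return(data)
  # IDX is row-major with the item index first; build the array so that
  # item i is x[i, , ...]
  aperm(array(data, dim = rev(dims)), rev(seq_len(rank)))
}
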