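#' Gaussian class-cluster dataset
#'
#' Draws `n_per_class` samples per class from isotropic Gaussians at
#' distinct centers, emulating the structure of small real-valued
#' classification benchmarks (three categories with four attributes, in the
#' Iris mold, under the defaults).  Class centers are placed along the
#' coordinate axes (cycling when there are more classes than features),
#' scaled so that the pairwise center distance is `class_separation` in
#' units of `noise_sd` (or in absolute feature units when `noise_sd = 0`).
#'
#' The stratified 50/50 train/test split uses its own RNG stream (seeded
#' from `seed + 1`) so that changing the noise draw never reshuffles split
#' membership.
#'
#' @param n_classes Number of classes.
#' @param n_features Number of feature dimensions.
#' @param n_per_class Samples per class (even, so the split is exact).
#' @param class_separation Pairwise center distance in noise-sd units.
#' @param noise_sd Isotropic within-class standard deviation.
#' @param seed Integer seed.
#' @return A tibble with numeric columns `f1..fK`, integer `label`
#'   (`1..n_classes`) and a `split` column (`"train"` / `"test"`,
#'   stratified 50/50).
#' @export
make_gaussian_classes <- function(n_classes = 3, n_features = 4,
                                  n_per_class = 50, class_separation = 4,
                                  noise_sd = 1, seed = 1L) {
  stopifnot(n_classes >= 1, n_features >= 1, n_per_class >= 1,
            noise_sd >= 0)
  sd_ref <- if (noise_sd > 0) noise_sd else 1
  # unit vectors along cycled axes have pairwise distance sqrt(2) (same
  # axis reuse aside), so scale accordingly
  scale <- class_separation * sd_ref / sqrt(2)
  centers <- t(vapply(seq_len(n_classes), function(c) {
    e <- numeric(n_features)
    axis <- (c - 1) %% n_features + 1
    e[axis] <- 1 + (c - 1) %/% n_features  # push repeats further out
    e * scale
  }, numeric(n_features)))

  set.seed(seed)
  feats <- do.call(rbind, lapply(seq_len(n_classes), function(c) {
    matrix(rnorm(n_per_class * n_features, sd = noise_sd),
           n_per_class, n_features) +
      matrix(centers[c, ], n_per_class, n_features, byrow = TRUE)
  }))
  labels <- rep(seq_len(n_classes), each = n_per_class)

  set.seed(seed + 1L)  # independent split stream
  split <- unlist(lapply(seq_len(n_classes), function(c) {
    n_train <- floor(n_per_class / 2)
    s <- rep("test", n_per_class)
    s[sample.int(n_per_class, n_train)] <- "train"
    s
  }))

  out <- tibble::as_tibble(as.data.frame(feats))
  names(out) <- paste0("f", seq_len(n_features))
  out$label <- labels
  out$split <- split
  out
}

#' Delay-coded two-class task
#'
#' A task whose discriminative information is purely temporal: both classes
#' emit exactly one spike on every channel (identical spike-count
#' histograms by construction), but class 2's spike times equal class 1's
#' base pattern shifted by a fixed per-channel offset pattern (`offset_ms`
#' on every other channel).  Gaussian jitter of `jitter_sd_ms` is added to
#' every spike.  Weight updates alone cannot exploit a pure timing shift as
#' directly as delay updates can, which is what this task is built to
#' probe.
#'
#' @param n_per_class Samples per class.
#' @param n_channels Number of input channels.
#' @param offset_ms Temporal offset distinguishing the classes (ms, >= 0).
#' @param jitter_sd_ms Spike-time jitter standard deviation (ms).
#' @param seed Integer seed.
#' @param t_window Encoding window; base times stay clear of its edges.
#' @param t_early,t_late Desired output times for target / non-target.
#' @param n_outputs Output-layer width (2: one neuron per class).
#' @return A tibble of encoded samples (`input_times`, `desired_times`,
#'   `label`) with a stratified 50/50 `split` column.
#' @export
make_delay_coded_task <- function(n_per_class = 20, n_channels = 6,
                                  offset_ms = 3, jitter_sd_ms = 0.5,
                                  seed = 1L, t_window = 10,
                                  t_early = 14, t_late = 25,
                                  n_outputs = 2) {
  stopifnot(offset_ms >= 0, jitter_sd_ms >= 0, n_channels >= 1)
  set.seed(seed)
  hi <- max(t_window - offset_ms - 1, 2)
  base <- runif(n_channels, 1, hi)
  pattern <- offset_ms * (seq_len(n_channels) %% 2)  # shift odd channels
  n <- 2 * n_per_class
  labels <- rep(1:2, each = n_per_class)
  input_times <- lapply(seq_len(n), function(r) {
    mu <- base + if (labels[r] == 2) pattern else 0
    t <- mu + rnorm(n_channels, sd = jitter_sd_ms)
    pmin(pmax(t, 0), t_window)
  })
  set.seed(seed + 1L)
  split <- unlist(lapply(1:2, function(c) {
    s <- rep("test", n_per_class)
    s[sample.int(n_per_class, floor(n_per_class / 2))] <- "train"
    s
  }))
  tibble::tibble(
    input_times = input_times,
    desired_times = lapply(labels, desired_times, n_classes = n_outputs,
                           t_early = t_early, t_late = t_late),
    label = labels,
    split = split
  )
}

#' Temporal XOR task
#'
#' The canonical four-pattern sanity task for spike-time learning: two
#' input neurons each spike early (0 ms) or late (`late_in` ms), plus a
#' reference neuron always spiking at 0 ms.  The single output neuron is
#' trained to fire at `t_true` when exactly one input is late (XOR true,
#' label 2) and at `t_false` otherwise (label 1).  Deterministic; `seed`
#' only fixes the row order.
#'
#' @param seed Integer seed (row shuffling only).
#' @param late_in Late input spike time (ms).
#' @param t_false,t_true Desired output times of the two classes (ms).
#' @return A tibble of 4 encoded samples (`input_times`, `desired_times`,
#'   `label`), with attribute `"class_times"` = `c(t_false, t_true)` for
#'   [decoder_nearest_time()].
#' @export
make_xor_temporal <- function(seed = 1L, late_in = 6,
                              t_false = 20, t_true = 14) {
  patterns <- list(c(0, 0), c(0, late_in), c(late_in, 0),
                   c(late_in, late_in))
  labels <- c(1L, 2L, 2L, 1L)  # XOR of (early = 0, late = 1)
  class_times <- c(t_false, t_true)
  set.seed(seed)
  ord <- sample.int(4)
  out <- tibble::tibble(
    input_times = lapply(patterns, function(p) c(p, 0))[ord],
    desired_times = lapply(labels[ord], function(lab) class_times[lab]),
    label = labels[ord]
  )
  attr(out, "class_times") <- class_times
  out
}

#' Write a feature table as delimited text
#'
#' Emits the same format [read_feature_table()] reads, so synthetic and
#' on-disk data share one path.
#'
#' @param data Data frame (e.g. from [make_gaussian_classes()]).
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}
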