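#' Scenario for synthetic multiview Gaussian clusters
#'
#' Describes a two-class multiview dataset with spherical Gaussian clusters:
#' in every informative view the two classes sit `separation` within-cluster
#' standard deviations apart (identity covariance); a non-informative view
#' draws both classes from the same standard normal, emulating a feature
#' representation that carries no class signal.
#'
#' @param n_per_class Samples per class, default 200.
#' @param n_views Number of views, default 2.
#' @param dims Integer vector of per-view dimensionalities (recycled),
#'   default 2 per view.
#' @param separation Distance between the class centers in units of the
#'   within-cluster standard deviation, default 6.
#' @param informative Logical per view (recycled); `FALSE` makes the view
#'   pure noise. Default all informative.
#' @param seed Integer seed, default 1.
#' @return A list of class `"mv_gaussian_scenario"`.
#' @export
mv_gaussian_scenario <- function(n_per_class = 200L, n_views = 2L,
                                 dims = 2L, separation = 6,
                                 informative = TRUE, seed = 1L) {
  n_views <- as.integer(n_views)
  dims <- rep_len(as.integer(dims), n_views)
  informative <- rep_len(as.logical(informative), n_views)
  if (separation < 0) stop("'separation' must be nonnegative", call. = FALSE)
  if (!any(informative) && separation > 0)
    warning("no informative view: classes are indistinguishable")
  structure(list(n_per_class = as.integer(n_per_class), n_views = n_views,
                 dims = dims, separation = separation,
                 informative = informative, seed = as.integer(seed)),
            class = "mv_gaussian_scenario")
}

#' Generate a synthetic multiview Gaussian dataset
#'
#' Class 0 is centred at the origin in every view; in informative views
#' class 1 is shifted by `separation` along the first coordinate, so the
#' center distance equals `separation` exactly. All clusters have identity
#' covariance. Fully deterministic per seed.
#'
#' @param scenario An [mv_gaussian_scenario()].
#' @return A list with `dataset` (a [multiview_dataset]), `labels`
#'   (0/1 per sample) and `params` (the generating centers per view).
#' @examples
#' sim <- gen_multiview_gaussian(mv_gaussian_scenario(n_per_class = 20))
#' sim$dataset
#' @export
gen_multiview_gaussian <- function(scenario = mv_gaussian_scenario()) {
  stopifnot(inherits(scenario, "mv_gaussian_scenario"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(scenario$seed)
  n <- scenario$n_per_class
  labels <- rep(c(0L, 1L), each = n)
  centers <- vector("list", scenario$n_views)
  views <- vector("list", scenario$n_views)
  for (i in seq_len(scenario$n_views)) {
    p <- scenario$dims[i]
    mu0 <- rep(0, p)
    mu1 <- if (scenario$informative[i])
      c(scenario$separation, rep(0, p - 1L)) else mu0
    X <- matrix(stats::rnorm(2L * n * p), 2L * n, p)
    X <- X + rbind(matrix(mu0, n, p, byrow = TRUE),
                   matrix(mu1, n, p, byrow = TRUE))
    views[[i]] <- X
    centers[[i]] <- rbind(mu0, mu1)
  }
  list(dataset = multiview_dataset(views,
                                   sample_ids = paste0("s", seq_len(2L * n))),
       labels = labels,
       params = list(centers = centers, separation = scenario$separation,
                     informative = scenario$informative))
}

#' Scenario for synthetic seizure-like EEG segments
#'
#' Background segments are per-channel noise (white or 1/f "pink") with unit
#' variance; seizure segments add a rhythmic sinusoidal discharge —
#' amplitude `seizure_amp_ratio` times the noise standard deviation at
#' `seizure_freq_hz` — with random per-channel phase on a random subset of
#' at least 8 of the 23 channels. The default 5 Hz tone mimics a
#' low-frequency rhythmic discharge while sitting inside the 4-30 Hz band
#' retained by the spectral view.
#'
#' @param n_segments Number of segments, default 40.
#' @param seizure_fraction Fraction of segments labelled seizure, in (0,1);
#'   default 0.5.
#' @param seizure_freq_hz Discharge frequency in Hz, default 5.
#' @param seizure_amp_ratio Discharge amplitude over noise SD, > 1,
#'   default 4.
#' @param noise_model `"white"` or `"pink"` (1/f) background, default white.
#' @param n_channels,n_time,sampling_rate Segment geometry; defaults
#'   23 x 256 at 256 Hz.
#' @param seed Integer seed, default 1.
#' @return A list of class `"eeg_scenario"`.
#' @export
eeg_scenario <- function(n_segments = 40L, seizure_fraction = 0.5,
                         seizure_freq_hz = 5, seizure_amp_ratio = 4,
                         noise_model = c("white", "pink"),
                         n_channels = 23L, n_time = 256L,
                         sampling_rate = 256, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (seizure_fraction <= 0 || seizure_fraction >= 1)
    stop("'seizure_fraction' must lie strictly between 0 and 1", call. = FALSE)
  if (seizure_amp_ratio <= 1)
    stop("'seizure_amp_ratio' must exceed 1 for the discharge to stand out",
         call. = FALSE)
  structure(list(n_segments = as.integer(n_segments),
                 seizure_fraction = seizure_fraction,
                 seizure_freq_hz = seizure_freq_hz,
                 seizure_amp_ratio = seizure_amp_ratio,
                 noise_model = noise_model,
                 n_channels = as.integer(n_channels),
                 n_time = as.integer(n_time),
                 sampling_rate = sampling_rate,
                 seed = as.integer(seed)),
            class = "eeg_scenario")
}

#' Generate synthetic EEG segments
#'
#' @param scenario An [eeg_scenario()].
#' @return A list of [eeg_segment()]s with labels attached (the first
#'   `round(seizure_fraction * n_segments)` are seizures).
#' @export
gen_synthetic_eeg <- function(scenario = eeg_scenario()) {
  stopifnot(inherits(scenario, "eeg_scenario"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(scenario$seed)
  n_sz <- round(scenario$seizure_fraction * scenario$n_segments)
  labels <- c(rep(1L, n_sz), rep(0L, scenario$n_segments - n_sz))
  tt <- (seq_len(scenario$n_time) - 1L) / scenario$sampling_rate
  lapply(seq_len(scenario$n_segments), function(k) {
    noise <- switch(scenario$noise_model,
                    white = matrix(stats::rnorm(scenario$n_channels *
                                                  scenario$n_time),
                                   scenario$n_channels),
                    pink = t(vapply(seq_len(scenario$n_channels),
                                    function(ch) pink_noise(scenario$n_time),
                                    numeric(scenario$n_time))))
    if (labels[k] == 1L) {
      n_active <- sample(8:scenario$n_channels, 1L)
      active <- sample.int(scenario$n_channels, n_active)
      for (ch in active) {
        phase <- stats::runif(1L, 0, 2 * pi)
        noise[ch, ] <- noise[ch, ] + scenario$seizure_amp_ratio *
          sin(2 * pi * scenario$seizure_freq_hz * tt + phase)
      }
    }
    eeg_segment(noise, sampling_rate = scenario$sampling_rate,
                segment_id = sprintf("seg%03d", k), label = labels[k])
  })
}

## Unit-variance 1/f noise via spectral shaping of white noise.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freqs <- c(1, seq_len(n - 1L))                 # keep DC unscaled
  shaped <- Re(stats::fft(f / sqrt(pmin(freqs, n - freqs + 1L)),
                          inverse = TRUE)) / n
  as.numeric(scale(shaped))
}

#' Fixed small multiview instance for oracle tests
#'
#' A deterministic 2-view, 6-sample, 2-cluster instance with hand-set
#' memberships, centers and weights, convenient for checking the update
#' rules and the objective against brute-force computation. Values are
#' literal constants and identical on every call.
#'
#' @return A list with `dataset`, `U` (2 x 6), `centers`, `weights`, and
#'   the instance dimensions.
#' @export
fixture_small_instance <- function() {
  v1 <- matrix(c(0.0, 0.2,
                 0.3, -0.1,
                 -0.2, 0.1,
                 5.8, 6.1,
                 6.2, 5.9,
                 6.0, 6.3), ncol = 2L, byrow = TRUE)
  v2 <- matrix(c(1.0, 0.9,
                 1.2, 1.1,
                 0.8, 1.0,
                 -2.1, -1.9,
                 -1.8, -2.2,
                 -2.0, -2.0), ncol = 2L, byrow = TRUE)
  U <- matrix(c(0.9, 0.8, 0.95, 0.1, 0.05, 0.2,
                0.1, 0.2, 0.05, 0.9, 0.95, 0.8),
              nrow = 2L, byrow = TRUE)
  centers <- list(matrix(c(0.0, 0.1, 6.0, 6.1), 2L, byrow = TRUE),
                  matrix(c(1.0, 1.0, -2.0, -2.0), 2L, byrow = TRUE))
  list(dataset = multiview_dataset(list(v1, v2)),
       U = U, centers = centers, weights = c(0.5, 0.5),
       K = 6L, N = 2L, C = 2L)
}
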