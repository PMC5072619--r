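#' Simulation configuration for a synthetic tracking experiment
#'
#' Bundles a [fractal_domain_model()] with the imaging parameters of a
#' synthetic single-nucleosome tracking run.  The simulator works entirely in
#' linearized mode space: each track is one nucleosome reconstructed from a
#' subdiffusive center-of-mass path plus `n_modes` stationary Gaussian normal
#' modes with Mittag-Leffler autocovariance, projected to the 2D imaging
#' plane, with i.i.d. Gaussian localization noise per axis.
#'
#' @param model a [fractal_domain_model()].
#' @param n_tracks number of tracks to generate.
#' @param frames_per_track frames per track (>= 2).
#' @param frame_interval seconds per frame (default 0.05).
#' @param localization_sigma per-axis Gaussian localization error, um
#'   (default 0.015; no measured value is available for the reference
#'   experiment, so this default is a nominal figure the user should own).
#' @param n_modes number of normal modes retained; default `min(N, 512)`,
#'   which keeps the neglected tail of the equilibrium mode variance around
#'   or below 1% for all valid fractal dimensions.  `0` keeps only the
#'   center-of-mass motion.
#' @param bead_sampling `"uniform"` to draw each track's bead index uniformly
#'   over `[0, N]`, or a single fixed index.
#' @param seed integer seed making the run reproducible; `NULL` leaves the
#'   RNG state alone.
#' @return object of class `"simulation_config"` (a validated list).
#' @export
simulation_config <- function(model, n_tracks, frames_per_track,
                              frame_interval = 0.05,
                              localization_sigma = 0.015,
                              n_modes = NULL, bead_sampling = "uniform",
                              seed = NULL) {
  model <- as_fdm(model)
  if (n_tracks < 1) stop("`n_tracks` must be >= 1", call. = FALSE)
  if (frames_per_track < 2) stop("`frames_per_track` must be >= 2",
                                 call. = FALSE)
  if (frame_interval <= 0) stop("`frame_interval` must be positive",
                                call. = FALSE)
  if (localization_sigma < 0) stop("`localization_sigma` must be >= 0",
                                   call. = FALSE)
  if (is.null(n_modes)) n_modes <- min(model$n_nucleosomes, 512L)
  if (n_modes < 0) stop("`n_modes` must be >= 0", call. = FALSE)
  if (!identical(bead_sampling, "uniform")) {
    if (!is.numeric(bead_sampling) || length(bead_sampling) != 1L ||
        bead_sampling < 0 || bead_sampling > model$n_nucleosomes) {
      stop("`bead_sampling` must be \"uniform\" or a bead index in [0, N]",
           call. = FALSE)
    }
  }
  structure(list(model = model, n_tracks = as.integer(n_tracks),
                 frames_per_track = as.integer(frames_per_track),
                 frame_interval = frame_interval,
                 localization_sigma = localization_sigma,
                 n_modes = as.integer(n_modes),
                 bead_sampling = bead_sampling,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

# Cholesky factor of a covariance matrix, adding jitter (<= 1e-10) only if
# plain factorization fails through roundoff.
chol_psd <- function(C) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  jit <- 1e-14
  while (is.null(R) && jit <= 1e-10) {
    R <- tryCatch(chol(C + diag(jit * mean(diag(C)), nrow(C))),
                  error = function(e) NULL)
    jit <- jit * 10
  }
  if (is.null(R)) {
    stop("covariance matrix is not positive semi-definite within jitter 1e-10",
         call. = FALSE)
  }
  R
}

# Cholesky factor for a stationary process given its autocovariance at lags
# 0..(n-1); exact dense-covariance factorization.
stationary_chol <- function(acov) {
  n <- length(acov)
  chol_psd(stats::toeplitz(acov))
}

#' Fractional Gaussian paths with an exact power-law MSD
#'
#' Generates zero-mean Gaussian paths with stationary increments whose
#' per-axis MSD is exactly `scale * t^alpha` (fractional Brownian motion
#' with Hurst index `alpha / 2`).  Increments are drawn with their exact
#' joint covariance (dense Cholesky factorization of the fractional
#' Gaussian noise covariance), not by Euler integration, so the MSD law
#' holds at every lag without discretization bias.
#'
#' @param alpha MSD exponent in (0, 1]; `alpha = 1` gives ordinary Brownian
#'   motion.
#' @param scale MSD prefactor per axis, um^2/s^alpha.
#' @param times equally spaced sample times (seconds); the path starts at 0
#'   at `times[1]`.
#' @param n_paths number of independent paths.
#' @param seed optional integer seed.
#' @return matrix `length(times) x n_paths` of positions (um).
#' @export
fractional_gaussian_path <- function(alpha, scale, times, n_paths = 1L,
                                     seed = NULL) {
  check_alpha(alpha)
  if (scale < 0) stop("`scale` must be >= 0", call. = FALSE)
  nt <- length(times)
  if (nt < 2L) stop("need at least 2 time points", call. = FALSE)
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]) || dt[1] <= 0) {
    stop("`times` must be strictly increasing and equally spaced",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (scale == 0) return(matrix(0, nt, n_paths))
  R <- stationary_chol(fgn_acov(alpha, scale, dt[1], nt - 1L))
  incr <- t(R) %*% matrix(stats::rnorm((nt - 1L) * n_paths), nt - 1L, n_paths)
  rbind(0, apply(incr, 2L, cumsum))
}

# autocovariance of fGn increments over step dt at lags 0..(n-1), for a
# process with per-axis MSD scale * t^alpha
fgn_acov <- function(alpha, scale, dt, n) {
  k <- 0:(n - 1L)
  scale * dt^alpha / 2 *
    ((k + 1)^alpha - 2 * k^alpha + abs(k - 1)^alpha)
}

#' Stationary sample path of one normal mode
#'
#' Draws the three Cartesian components of normal mode `p` as independent
#' stationary zero-mean Gaussian processes with per-axis variance
#' `mode_variance(model, p) / 3` and per-axis autocovariance
#' `mode_correlation(model, p, lag) / 3`, using the exact covariance of the
#' sampled time grid (the initial state is already at thermal equilibrium).
#'
#' @inheritParams simulation_config
#' @param p mode index >= 1.
#' @param times equally spaced sample times (seconds).
#' @param n_paths number of independent realizations.
#' @param kernel relaxation kernel passed to [mode_correlation()].
#' @param seed optional integer seed.
#' @return for `n_paths = 1` a `length(times) x 3` matrix (columns x, y, z);
#'   otherwise an array `[time, axis, path]`.
#' @export
stationary_mode_path <- function(model, p, times, n_paths = 1L,
                                 kernel = "exact", seed = NULL) {
  model <- as_fdm(model)
  nt <- length(times)
  lags <- times - times[1]
  acov <- mode_correlation(model, p, lags, kernel = kernel) / 3
  if (!is.null(seed)) set.seed(seed)
  R <- stationary_chol(acov)
  draw <- t(R) %*% matrix(stats::rnorm(nt * 3L * n_paths), nt)
  out <- array(draw, dim = c(nt, 3L, n_paths),
               dimnames = list(NULL, c("x", "y", "z"), NULL))
  if (n_paths == 1L) out[, , 1L] else out
}

#' Reconstruct a bead trajectory from mode coordinates
#'
#' Inverse normal-coordinate transform truncated at P modes:
#' \deqn{R(n, t) = X_0(t) + 2 \sum_{p=1}^{P} \cos(p\pi n/N)\, X_p(t).}
#'
#' @param com_path matrix of center-of-mass coordinates (rows = times).
#' @param mode_paths list of matrices conformable with `com_path`, element p
#'   holding mode p; an empty list returns the center-of-mass path.
#' @param bead_index bead position n in `[0, N]`.
#' @param n_nucleosomes chain length N.
#' @return matrix of bead coordinates, same shape as `com_path`.
#' @export
reconstruct_bead <- function(com_path, mode_paths, bead_index,
                             n_nucleosomes) {
  com_path <- as.matrix(com_path)
  out <- com_path
  for (p in seq_along(mode_paths)) {
    out <- out + 2 * cos(p * pi * bead_index / n_nucleosomes) *
      as.matrix(mode_paths[[p]])
  }
  out
}

#' Simulate a single-nucleosome tracking experiment
#'
#' Generates a [track_ensemble()] from the linearized mode-space model: for
#' each track a bead index is drawn, the center of mass and the retained
#' normal modes are sampled with their exact Gaussian covariance on the
#' frame grid (modes start in thermal equilibrium), the bead position is
#' reconstructed, the z axis is dropped to emulate 2D imaging, and Gaussian
#' localization noise is added per frame and axis.  Only the two imaged axes
#' are ever generated; by isotropy they carry the full statistics of the
#' model.
#'
#' @param config a [simulation_config()].
#' @return a [track_ensemble()] with attribute `"mode_tail_fraction"`, the
#'   fraction of equilibrium mode variance lost to truncation.
#' @examples
#' m <- fractal_domain_model(0.9, 2.09, 5000, 0.268)
#' cfg <- simulation_config(m, n_tracks = 20, frames_per_track = 11,
#'                          n_modes = 64, seed = 1)
#' trk <- simulate_tracking_experiment(cfg)
#' @export
simulate_tracking_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  model <- config$model
  if (!is.null(config$seed)) set.seed(config$seed)
  nt <- config$frames_per_track
  K <- config$n_tracks
  P <- config$n_modes
  times <- (seq_len(nt) - 1L) * config$frame_interval
  beads <- if (identical(config$bead_sampling, "uniform")) {
    stats::runif(K, 0, model$n_nucleosomes)
  } else {
    rep(config$bead_sampling, K)
  }
  # center of mass: per-axis fBM with one third of the 3D MSD coefficient
  tau <- relaxation_time(model)
  com_scale <- 2 * model$r_rms^2 /
    (scaling_constant_A(model$d_f) * gamma(1 + model$alpha)) / tau^model$alpha
  Rcom <- stationary_chol(fgn_acov(model$alpha, com_scale / 3,
                                   config$frame_interval, nt - 1L))
  draw_fbm <- function() {
    incr <- t(Rcom) %*% matrix(stats::rnorm((nt - 1L) * K), nt - 1L, K)
    rbind(0, apply(incr, 2L, cumsum))
  }
  pos_x <- draw_fbm()
  pos_y <- draw_fbm()
  # normal modes, exact Mittag-Leffler covariance per mode
  for (p in seq_len(P)) {
    acov <- mode_correlation(model, p, times, kernel = "exact") / 3
    Rp <- stationary_chol(acov)
    cf <- 2 * cos(p * pi * beads / model$n_nucleosomes)
    Xp <- t(Rp) %*% matrix(stats::rnorm(nt * K), nt, K)
    Yp <- t(Rp) %*% matrix(stats::rnorm(nt * K), nt, K)
    pos_x <- pos_x + Xp * rep(cf, each = nt)
    pos_y <- pos_y + Yp * rep(cf, each = nt)
  }
  if (config$localization_sigma > 0) {
    pos_x <- pos_x + matrix(stats::rnorm(nt * K, 0, config$localization_sigma),
                            nt, K)
    pos_y <- pos_y + matrix(stats::rnorm(nt * K, 0, config$localization_sigma),
                            nt, K)
  }
  tracks <- lapply(seq_len(K), function(j) cbind(x = pos_x[, j],
                                                 y = pos_y[, j]))
  out <- track_ensemble(tracks, frame_interval = config$frame_interval)
  attr(out, "mode_tail_fraction") <- mode_tail_fraction(model$d_f, P)
  out
}

# fraction of total equilibrium mode variance in modes p > P
mode_tail_fraction <- function(d_f, P) {
  s <- 1 + 2 / d_f
  head <- sum(seq_len(P)^(-s))
  tail <- P^(1 - s) / (s - 1)  # integral bound on the tail
  tail / (head + tail)
}

#' @describeIn simulate_tracking_experiment `simulate` method: draw `nsim`
#'   tracks directly from a model, forwarding the remaining
#'   [simulation_config()] fields.
#' @param object a [fractal_domain_model()].
#' @param nsim number of tracks.
#' @param seed integer seed.
#' @param ... further arguments for [simulation_config()].
#' @export
simulate.fractal_domain_model <- function(object, nsim = 1L, seed = NULL,
                                          ...) {
  cfg <- simulation_config(object, n_tracks = nsim, seed = seed, ...)
  simulate_tracking_experiment(cfg)
}

#' Read a simulation configuration from a key-value file
#'
#' Plain-text `key = value` lines (or `key: value`); `#` starts a comment.
#' Model keys: `alpha`, `d_f`, `n_nucleosomes`, `r_rms`, `d_egfp`.
#' Imaging keys: `n_tracks`, `frames_per_track`, `frame_interval`,
#' `localization_sigma`, `n_modes`, `bead_sampling`, `seed`.
#'
#' @param path file path.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$",
                                ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  need <- c("alpha", "d_f", "n_nucleosomes", "r_rms", "n_tracks",
            "frames_per_track")
  missing <- setdiff(need, names(kv))
  if (length(missing) > 0L) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("field `", key, "` is not numeric: ", kv[[key]],
                       call. = FALSE)
    v
  }
  model <- fractal_domain_model(num("alpha"), num("d_f"),
                                num("n_nucleosomes"), num("r_rms"),
                                d_egfp = num("d_egfp", 20.6))
  bead <- if (is.null(kv$bead_sampling) || kv$bead_sampling == "uniform") {
    "uniform"
  } else num("bead_sampling")
  simulation_config(model,
                    n_tracks = num("n_tracks"),
                    frames_per_track = num("frames_per_track"),
                    frame_interval = num("frame_interval", 0.05),
                    localization_sigma = num("localization_sigma", 0.015),
                    n_modes = num("n_modes"),
                    bead_sampling = bead,
                    seed = if (is.null(kv$seed)) NULL else num("seed"))
}
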