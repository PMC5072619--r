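#' Single-nucleosome track ensemble
#'
#' A set of 2D single-particle trajectories recorded at a fixed frame
#' interval.  Each track is a matrix with columns `x` and `y` (micrometres),
#' one row per consecutive frame.
#'
#' @param tracks list of numeric matrices (>= 2 rows, 2 columns x/y in um).
#' @param frame_interval time between frames in seconds (default 0.05,
#'   i.e. 50 ms per frame).
#' @param start_frames integer vector of the first frame index of each track
#'   (kept so that file round trips are lossless); recycled.
#' @param ids character vector of track identifiers; defaults to
#'   `"track_1"`, ...
#' @return object of class `"track_ensemble"`.
#' @export
track_ensemble <- function(tracks, frame_interval = 0.05, start_frames = 0L,
                           ids = NULL) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop("`tracks` must be a non-empty list of x/y matrices", call. = FALSE)
  }
  if (frame_interval <= 0) {
    stop("`frame_interval` must be positive", call. = FALSE)
  }
  tracks <- lapply(tracks, function(tr) {
    tr <- as.matrix(tr)
    if (ncol(tr) != 2L) stop("each track needs 2 columns (x, y)",
                             call. = FALSE)
    if (nrow(tr) < 2L) stop("each track needs at least 2 frames",
                            call. = FALSE)
    if (any(!is.finite(tr))) stop("track positions must be finite",
                                  call. = FALSE)
    colnames(tr) <- c("x", "y")
    tr
  })
  if (is.null(ids)) ids <- paste0("track_", seq_along(tracks))
  names(tracks) <- ids
  structure(list(tracks = tracks, frame_interval = frame_interval,
                 start_frames = rep_len(as.integer(start_frames),
                                        length(tracks))),
            class = "track_ensemble")
}

#' @export
print.track_ensemble <- function(x, ...) {
  len <- vapply(x$tracks, nrow, integer(1))
  cat(sprintf(paste0("Track ensemble: %d tracks, %d localizations, ",
                     "frame interval %g s\n"),
              length(x$tracks), sum(len), x$frame_interval))
  cat(sprintf("  track length: %d-%d frames (median %g)\n",
              min(len), max(len), stats::median(len)))
  invisible(x)
}

#' @export
length.track_ensemble <- function(x) length(x$tracks)

#' Read single-nucleosome tracks from delimited text
#'
#' Expects a header row and columns `track_id`, `frame`, `x_um`, `y_um`.
#' Frames within a track must be consecutive; a track containing frame gaps
#' is split into separate tracks at each gap (ids suffixed `.1`, `.2`, ...)
#' with a message, since displacement statistics must not bridge unobserved
#' frames.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) autodetects comma vs
#'   whitespace/tab from the header line.
#' @param frame_interval seconds per frame (default 0.05).
#' @return a [track_ensemble()].
#' @export
read_tracks <- function(path, sep = NULL, frame_interval = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    stop("empty track file: ", path, call. = FALSE)
  }
  if (is.null(sep)) sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    stop("track file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) == 0L) stop("empty track file: ", path, call. = FALSE)
  if (!is.numeric(d$frame) || !is.numeric(d$x_um) || !is.numeric(d$y_um) ||
      any(!is.finite(d$frame)) || any(!is.finite(d$x_um)) ||
      any(!is.finite(d$y_um))) {
    stop("malformed rows: frame, x_um, y_um must be finite numbers",
         call. = FALSE)
  }
  if (any(abs(d$x_um) > 1000 | abs(d$y_um) > 1000)) {
    warning("positions exceed 1000 um; are the coordinates really in um?")
  }
  tracks <- list()
  starts <- integer(0)
  ids <- character(0)
  n_split <- 0L
  for (id in unique(d$track_id)) {
    seg <- d[d$track_id == id, , drop = FALSE]
    seg <- seg[order(seg$frame), , drop = FALSE]
    if (any(duplicated(seg$frame))) {
      stop("duplicated frame index in track ", id, call. = FALSE)
    }
    gaps <- which(diff(seg$frame) != 1)
    pieces <- split(seq_len(nrow(seg)),
                    cumsum(seq_len(nrow(seg)) %in% (gaps + 1L)))
    if (length(pieces) > 1L) n_split <- n_split + 1L
    for (k in seq_along(pieces)) {
      idx <- pieces[[k]]
      if (length(idx) < 2L) next  # an isolated localization is not a track
      tracks[[length(tracks) + 1L]] <-
        cbind(x = seg$x_um[idx], y = seg$y_um[idx])
      starts <- c(starts, as.integer(seg$frame[idx[1]]))
      ids <- c(ids, if (length(pieces) > 1L) paste0(id, ".", k)
               else as.character(id))
    }
  }
  if (n_split > 0L) {
    message(n_split, " track(s) contained frame gaps and were split")
  }
  if (length(tracks) == 0L) {
    stop("no track with at least 2 consecutive frames in ", path,
         call. = FALSE)
  }
  track_ensemble(tracks, frame_interval = frame_interval,
                 start_frames = starts, ids = ids)
}

#' Write a track ensemble to delimited text
#'
#' @param ensemble a [track_ensemble()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ensemble, path, sep = "\t") {
  stopifnot(inherits(ensemble, "track_ensemble"))
  rows <- mapply(function(tr, id, s0) {
    data.frame(track_id = id, frame = s0 + seq_len(nrow(tr)) - 1L,
               x_um = tr[, "x"], y_um = tr[, "y"])
  }, ensemble$tracks, names(ensemble$tracks), ensemble$start_frames,
  SIMPLIFY = FALSE)
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' MSD curve container
#'
#' Ensemble MSD versus lag time with per-lag SEM and contributing-track
#' counts.  A plain data frame subclass with columns `lag_s`, `msd_um2`,
#' `sem_um2`, `m_i`.
#'
#' @param lag_s lag times in seconds.
#' @param msd_um2 MSD values in um^2 (3D-equivalent, see [ensemble_msd()]).
#' @param sem_um2 standard errors of the mean.
#' @param m_i number of tracks contributing at each lag.
#' @param frame_interval frame interval in seconds (stored as an attribute).
#' @return object of classes `"msd_curve"` and `"data.frame"`.
#' @export
msd_curve <- function(lag_s, msd_um2, sem_um2, m_i, frame_interval = NA_real_) {
  if (any(msd_um2 < 0, na.rm = TRUE)) stop("MSD must be >= 0", call. = FALSE)
  d <- data.frame(lag_s = lag_s, msd_um2 = msd_um2, sem_um2 = sem_um2,
                  m_i = as.integer(m_i))
  class(d) <- c("msd_curve", "data.frame")
  attr(d, "frame_interval") <- frame_interval
  d
}

#' Ensemble-averaged MSD of single-nucleosome tracks
#'
#' The origin-anchored estimator used for the single-nucleosome imaging
#' analysis: for lag \eqn{t_i = i \Delta t},
#' \deqn{\mathrm{MSD}(t_i) = \frac{3}{2}\,\frac{1}{M_i} \sum_{j=1}^{M_i}
#'   \big[(x_i^j - x_0^j)^2 + (y_i^j - y_0^j)^2\big],}
#' where the sum runs over the \eqn{M_i} tracks with at least `i + 1` frames
#' and displacements are taken from each track's first frame (not
#' time-averaged).  The factor 3/2 converts the 2D imaging-plane value to a
#' 3D-equivalent MSD assuming isotropy.  The SEM at each lag is the sample
#' standard deviation of the per-track 3/2-scaled squared displacements
#' divided by \eqn{\sqrt{M_i}}.
#'
#' @param ensemble a [track_ensemble()].
#' @param max_lag_frames largest lag in frames; defaults to the longest
#'   track's length minus one.  Lags with no contributing track are omitted.
#' @return an [msd_curve()].
#' @export
ensemble_msd <- function(ensemble, max_lag_frames = NULL) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  len <- vapply(ensemble$tracks, nrow, integer(1))
  if (is.null(max_lag_frames)) max_lag_frames <- max(len) - 1L
  if (max_lag_frames < 1) stop("`max_lag_frames` must be >= 1", call. = FALSE)
  lags <- seq_len(min(max_lag_frames, max(len) - 1L))
  rows <- lapply(lags, function(i) {
    use <- which(len >= i + 1L)
    if (length(use) == 0L) return(NULL)
    sq <- vapply(ensemble$tracks[use], function(tr) {
      1.5 * ((tr[i + 1L, "x"] - tr[1L, "x"])^2 +
               (tr[i + 1L, "y"] - tr[1L, "y"])^2)
    }, numeric(1))
    m <- length(sq)
    data.frame(lag_s = i * ensemble$frame_interval, msd_um2 = mean(sq),
               sem_um2 = if (m > 1L) stats::sd(sq) / sqrt(m) else NA_real_,
               m_i = m)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  d <- do.call(rbind, rows)
  msd_curve(d$lag_s, d$msd_um2, d$sem_um2, d$m_i,
            frame_interval = ensemble$frame_interval)
}

#' Time-averaged MSD (sliding-window alternative)
#'
#' Standard single-particle-tracking alternative to [ensemble_msd()],
#' provided for comparison only: per track, squared displacements at lag i
#' are averaged over all start frames (sliding window), then averaged across
#' tracks; the same 3/2 isotropy factor is applied.  The origin-anchored
#' estimator is the package default because it is the printed definition the
#' experimental analysis uses; for a stationary-increment process both agree
#' in expectation.
#'
#' @inheritParams ensemble_msd
#' @return an [msd_curve()]; here the SEM is the between-track standard
#'   deviation of the per-track time-averaged values divided by
#'   \eqn{\sqrt{M_i}}.
#' @export
time_averaged_msd <- function(ensemble, max_lag_frames = NULL) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  len <- vapply(ensemble$tracks, nrow, integer(1))
  if (is.null(max_lag_frames)) max_lag_frames <- max(len) - 1L
  if (max_lag_frames < 1) stop("`max_lag_frames` must be >= 1", call. = FALSE)
  lags <- seq_len(min(max_lag_frames, max(len) - 1L))
  rows <- lapply(lags, function(i) {
    use <- which(len >= i + 1L)
    if (length(use) == 0L) return(NULL)
    per_track <- vapply(ensemble$tracks[use], function(tr) {
      n <- nrow(tr)
      j <- seq_len(n - i)
      mean(1.5 * ((tr[j + i, "x"] - tr[j, "x"])^2 +
                    (tr[j + i, "y"] - tr[j, "y"])^2))
    }, numeric(1))
    m <- length(per_track)
    data.frame(lag_s = i * ensemble$frame_interval,
               msd_um2 = mean(per_track),
               sem_um2 = if (m > 1L) stats::sd(per_track) / sqrt(m)
                         else NA_real_,
               m_i = m)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  d <- do.call(rbind, rows)
  msd_curve(d$lag_s, d$msd_um2, d$sem_um2, d$m_i,
            frame_interval = ensemble$frame_interval)
}

#' Write / read an MSD curve as delimited text
#'
#' Columns `lag_s`, `msd_um2`, `sem_um2`, `m_i`, tab-separated with header.
#'
#' @param msd an [msd_curve()].
#' @param path file path.
#' @return `path` (write) or an [msd_curve()] (read).
#' @export
write_msd <- function(msd, path) {
  stopifnot(inherits(msd, "msd_curve") || is.data.frame(msd))
  utils::write.table(as.data.frame(msd), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_msd
#' @export
read_msd <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("lag_s", "msd_um2")
  if (!all(need %in% names(d))) {
    stop("MSD file must have columns lag_s and msd_um2", call. = FALSE)
  }
  if (is.null(d$sem_um2)) d$sem_um2 <- NA_real_
  if (is.null(d$m_i)) d$m_i <- NA_integer_
  msd_curve(d$lag_s, d$msd_um2, d$sem_um2, d$m_i)
}
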