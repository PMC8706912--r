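#' Construct a uniaxial sensor signal
#'
#' A uniaxial signal is the time series recorded by one axis `m` of one
#' sensor `g` (e.g. the x-axis of the wrist accelerometer), sampled at a
#' fixed rate.
#'
#' @param samples Numeric vector of at least two finite samples.
#' @param sensor Positive integer sensor index `g`.
#' @param axis Positive integer axis index `m` within the sensor.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `uniaxial_signal`.
#' @export
uniaxial_signal <- function(samples, sensor = 1L, axis = 1L, sample_rate = 100) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a uniaxial signal needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("uniaxial signal samples must all be finite", call. = FALSE)
  }
  if (sensor < 1L || axis < 1L) stop("sensor and axis indices are 1-based", call. = FALSE)
  structure(
    list(samples = samples, sensor = as.integer(sensor),
         axis = as.integer(axis), sample_rate = sample_rate),
    class = "uniaxial_signal"
  )
}

#' @export
print.uniaxial_signal <- function(x, ...) {
  cat(sprintf("<uniaxial_signal> sensor %d axis %d: %d samples @ %g Hz\n",
              x$sensor, x$axis, length(x$samples), x$sample_rate))
  invisible(x)
}

#' Construct a movement recording
#'
#' One movement instance: the bundle of all `M_G = sum(m_g)` uniaxial
#' signals recorded by `G` multi-axial sensors during a single segmented
#' movement, optionally carrying its class label.
#'
#' @param signals List of [uniaxial_signal()] objects; every (sensor, axis)
#'   pair must appear exactly once and axes within each sensor must be
#'   numbered 1..m_g.
#' @param label Optional integer class index in 1..H (H is only known to the
#'   ensemble, so only positivity is checked here).
#' @param metadata Optional named list of free-form provenance values.
#' @return An object of class `movement_recording` with attributes `G`,
#'   `m_g` (axes per sensor) and `M_G`.
#' @export
movement_recording <- function(signals, label = NULL, metadata = list()) {
  if (!length(signals)) stop("a recording needs at least one signal", call. = FALSE)
  ok <- vapply(signals, inherits, logical(1), "uniaxial_signal")
  if (!all(ok)) stop("all elements of `signals` must be uniaxial_signal objects", call. = FALSE)
  sensors <- vapply(signals, `[[`, integer(1), "sensor")
  axes <- vapply(signals, `[[`, integer(1), "axis")
  G <- max(sensors)
  if (!setequal(unique(sensors), seq_len(G))) {
    stop("sensors must be numbered contiguously 1..G", call. = FALSE)
  }
  m_g <- integer(G)
  for (g in seq_len(G)) {
    ax <- sort(axes[sensors == g])
    if (anyDuplicated(ax) || !identical(ax, seq_along(ax))) {
      stop(sprintf("sensor %d axes must appear exactly once, numbered 1..m_g", g),
           call. = FALSE)
    }
    m_g[g] <- length(ax)
  }
  if (!is.null(label)) {
    label <- as.integer(label)
    if (length(label) != 1L || is.na(label) || label < 1L) {
      stop("label must be a single positive class index", call. = FALSE)
    }
  }
  ord <- order(sensors, axes) # sensor-major, then axis
  structure(
    list(signals = signals[ord], label = label, metadata = metadata),
    class = "movement_recording",
    G = G, m_g = m_g, M_G = sum(m_g)
  )
}

#' @export
print.movement_recording <- function(x, ...) {
  cat(sprintf("<movement_recording> G=%d sensors, M_G=%d channels%s\n",
              attr(x, "G"), attr(x, "M_G"),
              if (is.null(x$label)) "" else sprintf(", class %d", x$label)))
  invisible(x)
}

#' Number of sensors / axes of a recording
#' @param rec A [movement_recording()].
#' @return `rec_G`: integer G; `rec_mg`: integer vector of axes per sensor;
#'   `rec_MG`: total channel count.
#' @export
rec_G <- function(rec) attr(rec, "G")

#' @rdname rec_G
#' @export
rec_mg <- function(rec) attr(rec, "m_g")

#' @rdname rec_G
#' @export
rec_MG <- function(rec) attr(rec, "M_G")

#' Extract one channel of a recording
#' @param rec A [movement_recording()].
#' @param sensor,axis Channel address.
#' @return The matching [uniaxial_signal()].
#' @export
rec_channel <- function(rec, sensor, axis) {
  for (s in rec$signals) {
    if (s$sensor == sensor && s$axis == axis) return(s)
  }
  stop(sprintf("no channel (sensor %d, axis %d) in recording", sensor, axis),
       call. = FALSE)
}

#' Restrict a recording to a single channel
#'
#' Used by the uniaxial baselines: the selected channel becomes sensor 1,
#' axis 1 of a one-channel recording, label and metadata preserved.
#' @inheritParams rec_channel
#' @return A one-channel [movement_recording()].
#' @export
subset_channel <- function(rec, sensor, axis) {
  s <- rec_channel(rec, sensor, axis)
  s$sensor <- 1L
  s$axis <- 1L
  movement_recording(list(s), label = rec$label, metadata = rec$metadata)
}

#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.movement_recording <- function(x, ...) {
  purrr::map_dfr(x$signals, function(s) {
    tibble::tibble(
      sensor = s$sensor, axis = s$axis,
      t = seq_along(s$samples) / s$sample_rate,
      value = s$samples
    )
  })
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Duration-normalize a signal to a common length
#'
#' Linear expansion or compression: the signal is re-parameterized on
#' `target_len` uniformly spaced positions over its original index range
#' and evaluated by piecewise-linear interpolation, so the first and last
#' samples are preserved exactly.
#'
#' @param signal A [uniaxial_signal()] or bare numeric vector.
#' @param target_len Target number of samples (>= 2).
#' @return Same type as `signal`, with exactly `target_len` samples.
#' @export
duration_normalize <- function(signal, target_len) {
  target_len <- as.integer(target_len)
  if (is.na(target_len) || target_len < 2L) {
    stop("target_len must be an integer >= 2", call. = FALSE)
  }
  x <- if (inherits(signal, "uniaxial_signal")) signal$samples else as.numeric(signal)
  if (!all(is.finite(x))) stop("cannot duration-normalize non-finite samples", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("signal must have at least 2 samples", call. = FALSE)
  out <- if (n == target_len) x else {
    stats::approx(x = seq_len(n), y = x,
                  xout = seq(1, n, length.out = target_len))$y
  }
  if (inherits(signal, "uniaxial_signal")) {
    signal$samples <- out
    signal
  } else {
    out
  }
}

#' Learn duration targets and amplitude extrema from a training set
#'
#' Computes the common lengths used to make channel durations compatible
#' with an input model: one global target (rounded mean duration over every
#' channel of every training recording) for the inter-sensor matrix and
#' cuboid models, one per-sensor target for the per-sensor matrix model,
#' and per-channel mean lengths (used when averaging per-axis templates and
#' when sizing per-axis network inputs). Optionally also fits per-axis
#' min-max amplitude statistics pooled over the whole training set.
#'
#' @param train Non-empty list of [movement_recording()]s with identical
#'   sensor/axis layout.
#' @param model_tag One of `"VI"`, `"LMI"`, `"GMI"`, `"GCI"`.
#' @param amplitude_mode `"none"` (default) or `"minmax_per_axis"`.
#' @return An object of class `normalization_spec` with fields `model_tag`,
#'   `global_len`, `sensor_len`, `channel_len`, `amplitude_mode`, `minmax`.
#' @export
fit_normalization <- function(train, model_tag = c("VI", "LMI", "GMI", "GCI"),
                              amplitude_mode = c("none", "minmax_per_axis")) {
  model_tag <- match.arg(model_tag)
  amplitude_mode <- match.arg(amplitude_mode)
  if (!length(train)) stop("training set is empty", call. = FALSE)
  G <- rec_G(train[[1]])
  m_g <- rec_mg(train[[1]])
  lens <- purrr::map_dfr(train, function(rec) {
    purrr::map_dfr(rec$signals, function(s) {
      tibble::tibble(sensor = s$sensor, axis = s$axis, len = length(s$samples))
    })
  })
  global_len <- as.integer(round_half_away(mean(lens$len)))
  sensor_len <- lens |>
    dplyr::group_by(.data$sensor) |>
    dplyr::summarise(len = as.integer(round_half_away(mean(.data$len))),
                     .groups = "drop")
  channel_len <- lens |>
    dplyr::group_by(.data$sensor, .data$axis) |>
    dplyr::summarise(len = as.integer(round_half_away(mean(.data$len))),
                     .groups = "drop")
  minmax <- if (amplitude_mode == "minmax_per_axis") minmax_fit(train) else NULL
  structure(
    list(model_tag = model_tag, G = G, m_g = m_g,
         global_len = max(global_len, 2L),
         sensor_len = sensor_len, channel_len = channel_len,
         amplitude_mode = amplitude_mode, minmax = minmax),
    class = "normalization_spec"
  )
}

#' Duration targets of a fitted normalization spec
#'
#' @param spec A `normalization_spec` from [fit_normalization()].
#' @return For `"GMI"`/`"GCI"` a single global length; for `"LMI"` the
#'   per-sensor lengths (named by sensor); for `"VI"` `NULL` (channel
#'   durations stay free).
#' @export
compute_target_lengths <- function(spec) {
  switch(spec$model_tag,
    GMI = ,
    GCI = spec$global_len,
    LMI = stats::setNames(spec$sensor_len$len, spec$sensor_len$sensor),
    VI = NULL
  )
}

#' Pooled per-axis min-max amplitude statistics
#'
#' The extrema are pooled over every recording of the training set per
#' (sensor, axis) pair, so the same affine map applies at train and test
#' time; test values outside the training range are not clipped.
#'
#' @param train Non-empty list of [movement_recording()]s.
#' @return A tibble with columns `sensor`, `axis`, `min`, `max`.
#' @export
minmax_fit <- function(train) {
  if (!length(train)) stop("training set is empty", call. = FALSE)
  purrr::map_dfr(train, function(rec) {
    purrr::map_dfr(rec$signals, function(s) {
      tibble::tibble(sensor = s$sensor, axis = s$axis,
                     min = min(s$samples), max = max(s$samples))
    })
  }) |>
    dplyr::group_by(.data$sensor, .data$axis) |>
    dplyr::summarise(min = min(.data$min), max = max(.data$max),
                     .groups = "drop") |>
    (\(d) {
      bad <- d$min >= d$max
      if (any(bad)) {
        stop(sprintf(
          "degenerate (constant) axis: %s",
          paste(sprintf("sensor %d axis %d", d$sensor[bad], d$axis[bad]),
                collapse = ", ")), call. = FALSE)
      }
      d
    })()
}

#' Apply fitted min-max normalization to one signal
#'
#' @param signal A [uniaxial_signal()].
#' @param stats Tibble from [minmax_fit()] (or the `minmax` field of a
#'   fitted `normalization_spec`).
#' @return The signal mapped through `(x - min) / (max - min)` for its axis.
#' @export
minmax_apply <- function(signal, stats) {
  row <- stats[stats$sensor == signal$sensor & stats$axis == signal$axis, ]
  if (nrow(row) != 1L) {
    stop(sprintf("min-max spec does not cover sensor %d axis %d",
                 signal$sensor, signal$axis), call. = FALSE)
  }
  signal$samples <- (signal$samples - row$min) / (row$max - row$min)
  signal
}

amp_normalize <- function(signal, spec) {
  if (!is.null(spec) && spec$amplitude_mode == "minmax_per_axis") {
    minmax_apply(signal, spec$minmax)
  } else {
    signal
  }
}

#' Build a classifier input from a recording
#'
#' Packages one recording into one of the four classifier input models:
#' \describe{
#'   \item{VI}{a list of the `M_G` raw channel vectors (durations untouched);}
#'   \item{LMI}{`G` per-sensor matrices `m_g x n_g`, each channel
#'     duration-normalized to its sensor's common length;}
#'   \item{GMI}{one global `M_G x N` matrix, rows ordered sensor-major then
#'     axis, all channels normalized to the global common length;}
#'   \item{GCI}{one `M x N x G` cuboid whose depth-frame `g` is the sensor-g
#'     matrix (requires all sensors to have the same number of axes).}
#' }
#' Amplitude normalization follows the spec's `amplitude_mode`.
#'
#' @param rec A [movement_recording()].
#' @param model_tag One of `"VI"`, `"LMI"`, `"GMI"`, `"GCI"`; defaults to the
#'   tag the spec was fitted for.
#' @param spec A `normalization_spec` from [fit_normalization()].
#' @return An object of class `fused_input`: list with `model_tag` and
#'   `payload`.
#' @export
build_input <- function(rec, model_tag = spec$model_tag, spec) {
  model_tag <- match.arg(model_tag, c("VI", "LMI", "GMI", "GCI"))
  G <- rec_G(rec)
  m_g <- rec_mg(rec)
  if (model_tag == "GCI" && length(unique(m_g)) != 1L) {
    stop("model not applicable: the cuboid input requires all sensors to have ",
         "an equal number of axes", call. = FALSE)
  }
  sig <- lapply(rec$signals, amp_normalize, spec = spec)
  payload <- switch(model_tag,
    VI = {
      out <- lapply(sig, `[[`, "samples")
      names(out) <- vapply(sig, function(s) sprintf("s%d.%d", s$sensor, s$axis), "")
      out
    },
    LMI = {
      targets <- stats::setNames(spec$sensor_len$len, spec$sensor_len$sensor)
      lapply(seq_len(G), function(g) {
        rows <- Filter(function(s) s$sensor == g, sig)
        rows <- rows[order(vapply(rows, `[[`, integer(1), "axis"))]
        do.call(rbind, lapply(rows, function(s) {
          duration_normalize(s$samples, targets[[as.character(g)]])
        }))
      })
    },
    GMI = {
      N <- spec$global_len
      do.call(rbind, lapply(sig, function(s) duration_normalize(s$samples, N)))
    },
    GCI = {
      N <- spec$global_len
      M <- m_g[1]
      cub <- array(0, dim = c(M, N, G))
      for (g in seq_len(G)) {
        rows <- Filter(function(s) s$sensor == g, sig)
        rows <- rows[order(vapply(rows, `[[`, integer(1), "axis"))]
        cub[, , g] <- do.call(rbind, lapply(rows, function(s) {
          duration_normalize(s$samples, N)
        }))
      }
      cub
    }
  )
  structure(list(model_tag = model_tag, payload = payload), class = "fused_input")
}

#' Energy-based movement segmentation
#'
#' Locates candidate movement segments in a continuous multi-channel stream
#' by thresholding short-time energy: energies (squared samples summed over
#' all channels) are accumulated in a sliding rectangular window, and
#' maximal runs where the windowed energy reaches `threshold_frac` of its
#' global peak become segments; runs separated by fewer than `min_gap`
#' samples are merged. A simplified stand-in for the dedicated onset/offset
#' detectors used with commercial IMUs; the classifiers consume its output,
#' they do not depend on its exact boundaries.
#'
#' @param stream A [movement_recording()] (or list of equal-length
#'   [uniaxial_signal()]s) holding the raw continuous stream.
#' @param window Sliding-window length in samples (>= 1).
#' @param threshold_frac Fraction of the peak windowed energy, in (0, 1).
#' @param min_gap Runs closer than this many samples are merged.
#' @return A tibble with columns `start`, `end`: half-open `[start, end)`
#'   1-based sample intervals in ascending order; zero rows for an all-zero
#'   stream.
#' @export
segment_energy <- function(stream, window = 10L, threshold_frac = 0.1,
                           min_gap = 10L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("threshold_frac must lie strictly between 0 and 1", call. = FALSE)
  }
  signals <- if (inherits(stream, "movement_recording")) stream$signals else stream
  lens <- vapply(signals, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels of the stream must have equal length", call. = FALSE)
  }
  n <- lens[1]
  energy <- rowSums(vapply(signals, function(s) s$samples^2, numeric(n)))
  win <- as.numeric(stats::filter(energy, rep(1, window), sides = 2))
  win[is.na(win)] <- 0
  peak <- max(win)
  if (peak <= 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  active <- win >= threshold_frac * peak
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(start = starts[r$values], end = ends[r$values] + 1L)
  if (!nrow(runs)) return(tibble::tibble(start = integer(), end = integer()))
  merged <- list(c(runs$start[1], runs$end[1]))
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs$start[k] - last[2] < min_gap) {
        merged[[length(merged)]][2] <- runs$end[k]
      } else {
        merged[[length(merged) + 1L]] <- c(runs$start[k], runs$end[k])
      }
    }
  }
  tibble::tibble(
    start = vapply(merged, `[`, numeric(1), 1) |> as.integer(),
    end = vapply(merged, `[`, numeric(1), 2) |> as.integer()
  )
}
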