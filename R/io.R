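# On-disk layout: one CSV per recording (columns sensor,axis,t,value) with a
# JSON sidecar manifest (label, sample rate, metadata); an ensemble is a
# directory of such pairs. A single-file JSON container holds many
# recordings for speed.

#' Write / read a movement ensemble as CSV + manifest files
#'
#' Each recording becomes `rec_<k>.csv` (long format: `sensor,axis,t,value`)
#' plus `rec_<k>.json` holding label, sample rate and metadata.
#'
#' @param recs List of [movement_recording()]s.
#' @param dir Directory (created if missing).
#' @return `write_recordings` returns the directory invisibly;
#'   `read_recordings` returns the list of recordings.
#' @export
write_recordings <- function(recs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    utils::write.csv(as_tibble(rec), file.path(dir, sprintf("rec_%04d.csv", k)),
                     row.names = FALSE)
    manifest <- list(
      label = rec$label, sample_rate = rec$signals[[1]]$sample_rate,
      metadata = rec$metadata
    )
    jsonlite::write_json(manifest, file.path(dir, sprintf("rec_%04d.json", k)),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(dir)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "^rec_\\d+\\.csv$", full.names = TRUE))
  if (!length(csvs)) stop("no recordings found in ", dir, call. = FALSE)
  lapply(csvs, function(f) {
    d <- utils::read.csv(f)
    need <- c("sensor", "axis", "t", "value")
    if (!all(need %in% names(d))) {
      stop(sprintf("malformed recording CSV %s: expected columns %s",
                   basename(f), paste(need, collapse = ",")), call. = FALSE)
    }
    mf <- jsonlite::read_json(sub("\\.csv$", ".json", f), simplifyVector = TRUE)
    signals <- d |>
      dplyr::group_by(.data$sensor, .data$axis) |>
      dplyr::group_map(function(g, key) {
        uniaxial_signal(g$value[order(g$t)], key$sensor, key$axis,
                        sample_rate = mf$sample_rate %||% 100)
      })
    movement_recording(signals,
                       label = if (is.null(mf$label)) NULL else as.integer(mf$label),
                       metadata = as.list(mf$metadata))
  })
}

#' Write / read a movement ensemble as a single JSON container
#'
#' One self-contained file holding every recording (samples, layout, label,
#' metadata) plus the generating config when present — convenient for
#' moving whole synthetic ensembles around.
#'
#' @param recs List of [movement_recording()]s.
#' @param path File path.
#' @return `write_container` returns `path` invisibly; `read_container`
#'   the list of recordings (config reattached when stored).
#' @export
write_container <- function(recs, path) {
  payload <- list(
    format = "movefuse-ensemble-v1",
    config = if (!is.null(attr(recs, "config"))) unclass(attr(recs, "config")),
    recordings = lapply(recs, function(rec) {
      list(label = rec$label, metadata = rec$metadata,
           signals = lapply(rec$signals, function(s) {
             list(sensor = s$sensor, axis = s$axis,
                  sample_rate = s$sample_rate, samples = s$samples)
           }))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "movefuse-ensemble-v1")) {
    stop("not a movefuse ensemble container: ", path, call. = FALSE)
  }
  recs <- lapply(payload$recordings, function(r) {
    signals <- lapply(r$signals, function(s) {
      uniaxial_signal(unlist(s$samples), s$sensor, s$axis, s$sample_rate)
    })
    movement_recording(signals,
                       label = if (is.null(r$label)) NULL else as.integer(r$label),
                       metadata = as.list(r$metadata))
  })
  if (!is.null(payload$config)) {
    cfg <- payload$config
    attr(recs, "config") <- do.call(synthetic_config, cfg[setdiff(
      names(cfg), c("m_g"))] |> (\(x) { x$axes_per_sensor <- unlist(cfg$m_g); x })())
  }
  recs
}

#' Serialize DTW templates to a JSON file
#'
#' Stores the per-class template payloads together with the estimator tag
#' and the fitted normalization spec, and restores them.
#'
#' @param templates A `movement_templates` object.
#' @param path File path.
#' @return `write_templates` returns `path` invisibly; `read_templates` the
#'   restored `movement_templates`.
#' @export
write_templates <- function(templates, path) {
  spec <- templates$spec
  payload <- list(
    format = "movefuse-templates-v1",
    model_tag = templates$model_tag, estimator = templates$estimator,
    alpha = templates$alpha, H = templates$H,
    spec = list(model_tag = spec$model_tag, G = spec$G, m_g = spec$m_g,
                global_len = spec$global_len,
                sensor_len = as.list(spec$sensor_len),
                channel_len = as.list(spec$channel_len),
                amplitude_mode = spec$amplitude_mode,
                minmax = if (!is.null(spec$minmax)) as.list(spec$minmax)),
    templates = lapply(templates$templates, function(tpl) {
      if (is.matrix(tpl)) {
        list(kind = "matrix", nrow = nrow(tpl), data = as.numeric(tpl))
      } else if (is.list(tpl) && is.matrix(tpl[[1]])) {
        list(kind = "matrices",
             items = lapply(tpl, function(m) list(nrow = nrow(m),
                                                  data = as.numeric(m))))
      } else {
        list(kind = "vectors", items = tpl)
      }
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(list(
    model_tag = p$spec$model_tag, G = p$spec$G, m_g = p$spec$m_g,
    global_len = p$spec$global_len,
    sensor_len = tibble::as_tibble(p$spec$sensor_len),
    channel_len = tibble::as_tibble(p$spec$channel_len),
    amplitude_mode = p$spec$amplitude_mode,
    minmax = if (!is.null(p$spec$minmax)) tibble::as_tibble(p$spec$minmax)
  ), class = "normalization_spec")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)$templates
  templates <- lapply(raw, function(tpl) {
    kind <- tpl$kind
    if (kind == "matrix") {
      matrix(unlist(tpl$data), nrow = tpl$nrow)
    } else if (kind == "matrices") {
      lapply(tpl$items, function(m) matrix(unlist(m$data), nrow = m$nrow))
    } else {
      lapply(tpl$items, unlist)
    }
  })
  structure(
    list(model_tag = p$model_tag, estimator = p$estimator, alpha = p$alpha,
         spec = spec, H = p$H, templates = templates),
    class = "movement_templates"
  )
}
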