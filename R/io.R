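# Portable containers: a recording is stored as a delimited-text matrix
# (`<path>.tsv`, channels in rows, first column the channel name) plus a
# JSON sidecar (`<path>.json`) holding the sampling rate, 3-D sensor
# positions, and — for simulations — run-length-encoded truth labels.

#' Write a recording to the text + JSON container
#'
#' @param rec a `recording`.
#' @param path file path prefix (no extension); `<path>.tsv` and
#'   `<path>.json` are produced.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  # %.17g guarantees a bit-exact float64 round trip (fwrite's default 15
  # significant digits would not)
  lines <- vapply(seq_len(nrow(rec$data)), function(ch)
    paste(c(rec$layout$names[ch], sprintf("%.17g", rec$data[ch, ])),
          collapse = "\t"),
    character(1))
  writeLines(lines, paste0(path, ".tsv"))
  side <- list(fs = rec$fs,
               n_sensors = rec$layout$n_sensors,
               channel_names = rec$layout$names,
               positions = rec$layout$positions)
  if (!is.null(rec$truth_labels)) {
    r <- rle(ifelse(is.na(rec$truth_labels$labels), 0L,
                    rec$truth_labels$labels))
    side$truth <- list(K = rec$truth_labels$K,
                       run_values = r$values, run_lengths = r$lengths)
  }
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording from the text + JSON container
#'
#' @param path file path prefix used with [write_recording()].
#' @return a `recording`.
#' @export
read_recording <- function(path) {
  jpath <- paste0(path, ".json")
  tpath <- paste0(path, ".tsv")
  for (f in c(jpath, tpath)) {
    if (!file.exists(f)) stop_invalid("schema error: missing file '%s'", f)
  }
  side <- tryCatch(jsonlite::read_json(jpath, simplifyVector = TRUE),
                   error = function(e)
                     stop_invalid("schema error: unreadable sidecar '%s' (%s)",
                                  jpath, conditionMessage(e)))
  for (f in c("fs", "positions", "channel_names")) {
    if (is.null(side[[f]])) {
      stop_invalid("schema error: sidecar field '%s' missing in %s", f, jpath)
    }
  }
  dt <- tryCatch(data.table::fread(tpath, sep = "\t", header = FALSE),
                 error = function(e)
                   stop_invalid("schema error: unreadable data matrix '%s' (%s)",
                                tpath, conditionMessage(e)))
  mat <- as.matrix(dt[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  pos <- matrix(as.numeric(side$positions), ncol = 3)
  if (nrow(pos) != nrow(mat)) {
    stop_invalid("schema error: %d positions for %d channels",
                 nrow(pos), nrow(mat))
  }
  layout <- structure(list(n_sensors = nrow(mat), positions = pos,
                           names = as.character(side$channel_names)),
                      class = "sensor_layout")
  side$fs <- as.numeric(side$fs)
  truth <- NULL
  if (!is.null(side$truth)) {
    lab <- inverse.rle(list(lengths = as.integer(side$truth$run_lengths),
                            values = as.integer(side$truth$run_values)))
    lab[lab == 0L] <- NA_integer_
    if (length(lab) != ncol(mat)) {
      stop_invalid("schema error: truth labels length != n_samples")
    }
    truth <- label_sequence(lab, as.integer(side$truth$K), side$fs)
  }
  recording(mat, side$fs, layout, truth_labels = truth)
}

#' Write / read a pipeline or cohort configuration
#'
#' JSON (default) or YAML, chosen by file extension (`.yaml`/`.yml`
#' requires the `yaml` package).
#'
#' @param config a configuration list.
#' @param path file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("the 'yaml' package is required for YAML configs")
    }
    yaml::write_yaml(unclass_deep(config), path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Serialized-config hash
#'
#' Deterministic 8-hex-digit FNV-1a hash of the JSON serialization of a
#' configuration, stamped into pipeline reports for provenance.
#'
#' @param config configuration list.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  fnv1a_hash(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)))
}
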