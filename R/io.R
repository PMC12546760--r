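# Plain-text readers/writers with strict schema validation. Traces travel as
# two-column CSV with '#key=value' metadata headers; feature tables as CSV
# with the 23 canonical columns plus a cell identifier and a JSON sidecar
# recording the transform state.

#' Write / read a voltage trace as CSV
#'
#' Columns `time_ms`, `vm_mV`; protocol metadata (`dt`, `t_on`, `t_off`,
#' `i_inj_pA` and the generating parameters when present) travel in `#key=value`
#' comment lines.
#'
#' @param trace a [VoltageTrace-class].
#' @param path file path.
#' @return `writeTraceCSV` returns `path` invisibly; `readTraceCSV` the
#'   reconstructed [VoltageTrace-class].
#' @export
writeTraceCSV <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(dt = trace@dt, t_on = trace@tOn, t_off = trace@tOff,
            i_inj_pA = trace@iInj, diverged = as.numeric(trace@diverged))
  if (length(trace@params)) {
    meta <- c(meta, stats::setNames(trace@params,
                                    paste0("param_", names(trace@params))))
  }
  writeLines(sprintf("#%s=%.17g", names(meta), meta), con)
  utils::write.csv(data.frame(time_ms = traceTime(trace), vm_mV = trace@vm),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path) {
  lines <- readLines(path)
  isMeta <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[isMeta]) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- utils::read.csv(text = lines[!isMeta])
  need <- c("time_ms", "vm_mV")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace file ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  for (k in c("dt", "t_on", "t_off", "i_inj_pA")) {
    if (is.null(meta[[k]])) stop("trace file ", path,
                                 " is missing metadata line #", k, "=...")
  }
  isPar <- startsWith(names(meta), "param_")
  params <- if (any(isPar)) {
    stats::setNames(unlist(meta[isPar]),
                    sub("^param_", "", names(meta)[isPar]))
  } else numeric(0)
  new("VoltageTrace", vm = df$vm_mV, dt = meta$dt, tOn = meta$t_on,
      tOff = meta$t_off, iInj = meta$i_inj_pA, params = params,
      diverged = isTRUE(meta$diverged == 1))
}

#' Write / read feature tables as CSV
#'
#' One row per trace with a `cell_id` column and the 23 canonical feature
#' columns; undefined features are empty cells. A JSON sidecar
#' (`<path>.json`) records whether the features are raw or transformed.
#'
#' @param x feature matrix with canonical column names.
#' @param path file path.
#' @param transformed logical flag recorded in the sidecar.
#' @param ids optional cell identifiers.
#' @return `writeFeatureCSV` returns `path` invisibly; `readFeatureCSV` a
#'   list with `features` (matrix), `ids`, `transformed`.
#' @export
writeFeatureCSV <- function(x, path, transformed = TRUE, ids = NULL) {
  x <- rbind(x)
  stopifnot(identical(colnames(x), ephysFeatureNames()))
  df <- data.frame(cell_id = ids %||% sprintf("cell_%04d", seq_len(nrow(x))),
                   x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(list(transformed = transformed,
                            features = ephysFeatureNames()),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(c("cell_id", ephysFeatureNames()), names(df))
  if (length(miss)) stop("feature file ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  sidecar <- paste0(path, ".json")
  transformed <- if (file.exists(sidecar)) {
    isTRUE(jsonlite::read_json(sidecar)$transformed)
  } else NA
  m <- as.matrix(df[, ephysFeatureNames(), drop = FALSE])
  list(features = m, ids = df$cell_id, transformed = transformed)
}

#' Read parameter sets from CSV
#'
#' @param path CSV with the 13 canonical parameter columns (extra columns,
#'   e.g. `cell_id`, are preserved as rownames when present).
#' @return n x 13 matrix.
#' @export
readParamsCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(hhParameterNames(), names(df))
  if (length(miss)) stop("parameter file ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(df[, hhParameterNames(), drop = FALSE])
  if ("cell_id" %in% names(df)) rownames(m) <- df$cell_id
  m
}

#' @rdname readParamsCSV
#' @param x parameter matrix.
#' @param ids optional cell identifiers.
#' @export
writeParamsCSV <- function(x, path, ids = NULL) {
  x <- rbind(x)
  colnames(x) <- colnames(x) %||% hhParameterNames()
  df <- data.frame(cell_id = ids %||% sprintf("cell_%04d", seq_len(nrow(x))),
                   x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
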