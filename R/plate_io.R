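#' @keywords internal
.normalize_well <- function(well) {
  w <- toupper(trimws(well))
  sub("^([A-H])([1-9])$", "\\10\\2", w)
}

.is_well_label <- function(well) {
  grepl("^[A-H](0[1-9]|1[0-2])$", .normalize_well(well))
}

.time_factor <- function(time_unit) {
  switch(time_unit,
         hours = 1, minutes = 1 / 60, seconds = 1 / 3600,
         stop("time_unit must be hours, minutes or seconds", call. = FALSE))
}

.plate_dataset <- function(curves, conditions = NULL, metadata = list()) {
  grids <- lapply(curves, `[[`, "time")
  ragged <- length(unique(vapply(grids, function(g)
    paste(g, collapse = ","), character(1)))) > 1L
  structure(list(curves = curves, conditions = conditions,
                 metadata = c(metadata, list(ragged = ragged))),
            class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf("Plate dataset: %d curves%s%s\n", length(x$curves),
              if (isTRUE(x$metadata$ragged)) " (ragged grids)" else "",
              if (!is.null(x$conditions))
                sprintf(", %d mapped conditions", length(x$conditions)) else ""))
  invisible(x)
}

#' Read a long-format plate-reader table
#'
#' Tab-delimited text with header columns `sample`, `well`, `time`, `od`
#' (extra columns are preserved in the dataset metadata). Rows are grouped
#' into one growth curve per (sample, well), sorted by time. Time is in
#' hours unless `time_unit` says otherwise. Well labels are normalised to
#' the zero-padded form (`"A1"` -> `"A01"`) so joins against condition
#' maps are stable.
#'
#' @param path Path to the file.
#' @param time_unit One of `"hours"`, `"minutes"`, `"seconds"`; readings
#'   are converted to hours on read.
#' @return A `plate_dataset` whose `curves` element is a named list of
#'   [growth_curve()] keyed `"sample/well"`.
#' @export
read_long_table <- function(path, time_unit = "hours") {
  fac <- .time_factor(time_unit)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("sample", "well", "time", "od"))
    if (!col %in% names(df))
      stop("missing required column: ", col, call. = FALSE)
  time <- suppressWarnings(as.numeric(df$time))
  od <- suppressWarnings(as.numeric(df$od))
  bad <- which(!is.finite(time) | !is.finite(od))
  if (length(bad))
    stop("non-numeric time/od on line ", bad[1] + 1L,  # +1 for header
         call. = FALSE)
  df$time <- time * fac
  df$od <- od
  df$well <- .normalize_well(df$well)
  key <- paste(df$sample, df$well, sep = "/")
  dup <- duplicated(data.frame(key, df$time))
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate reading for sample %s, well %s, time %g",
                 df$sample[i], df$well[i], df$time[i]), call. = FALSE)
  }
  curves <- lapply(split(df, key), function(g) {
    if (is.unsorted(g$time)) {
      message("unsorted times for ", g$sample[1], "/", g$well[1],
              "; sorting")
      g <- g[order(g$time), ]
    }
    growth_curve(g$time, g$od, well_id = g$well[1], sample = g$sample[1])
  })
  extra_names <- setdiff(names(df), c("sample", "well", "time", "od"))
  extra <- if (length(extra_names))
    utils::type.convert(df[c("sample", "well", "time", extra_names)],
                        as.is = TRUE)
  .plate_dataset(curves,
                 metadata = list(source = path, format = "long",
                                 extra_columns = extra))
}

#' Read a wide-format plate CSV
#'
#' Comma-separated with a first column named `time` (hours) and one column
#' per well, headed by its 96-well label. All wells share the time grid.
#' Columns that contain no readings are skipped with a warning.
#'
#' @inheritParams read_long_table
#' @return A `plate_dataset`.
#' @export
read_wide_csv <- function(path, time_unit = "hours") {
  fac <- .time_factor(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (length(df) == 0L || tolower(names(df)[1]) != "time")
    stop("first column must be 'time'", call. = FALSE)
  time <- suppressWarnings(as.numeric(df[[1]]))
  if (any(!is.finite(time)))
    stop("non-numeric time on line ",
         which(!is.finite(time))[1] + 1L, call. = FALSE)
  time <- time * fac
  wells <- names(df)[-1]
  ok <- .is_well_label(wells)
  if (any(!ok))
    stop("'", wells[!ok][1], "' is not a 96-well label", call. = FALSE)
  curves <- list()
  for (j in seq_along(wells)) {
    od <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (all(is.na(od))) {
      warning("well column ", wells[j], " is empty; skipped", call. = FALSE)
      next
    }
    if (any(!is.finite(od)))
      stop("non-numeric od for well ", wells[j], " on line ",
           which(!is.finite(od))[1] + 1L, call. = FALSE)
    w <- .normalize_well(wells[j])
    curves[[w]] <- growth_curve(time, od, well_id = w)
  }
  .plate_dataset(curves, metadata = list(source = path, format = "wide"))
}

#' Read a well-to-condition map
#'
#' Tab-delimited with at least columns `well` and `condition` (e.g. the 96
#' minimal-media conditions of a phenotype microarray plate); additional
#' columns are preserved as attributes. Wells absent from the map resolve
#' to `"unknown"` via [condition_of()].
#'
#' @param path Path to the file.
#' @return A named character vector, well label -> condition, with
#'   attribute `extra` holding any additional columns.
#' @export
read_condition_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("well", "condition"))
    if (!col %in% names(df))
      stop("missing required column: ", col, call. = FALSE)
  bad <- which(is.na(df$well) | !nzchar(df$well) |
                 is.na(df$condition) | !nzchar(df$condition))
  if (length(bad))
    stop("malformed row on line ", bad[1] + 1L, call. = FALSE)
  df$well <- .normalize_well(df$well)
  if (anyDuplicated(df$well))
    stop("duplicate well in condition map: ",
         df$well[duplicated(df$well)][1], call. = FALSE)
  map <- stats::setNames(df$condition, df$well)
  extra <- df[setdiff(names(df), c("well", "condition"))]
  attr(map, "extra") <- if (length(extra)) extra else NULL
  map
}

#' @rdname read_condition_map
#' @param map A condition map from [read_condition_map()] (or `NULL`).
#' @param well Well label(s) to look up.
#' @export
condition_of <- function(map, well) {
  if (is.null(map)) return(rep("unknown", length(well)))
  out <- unname(map[.normalize_well(well)])
  out[is.na(out)] <- "unknown"
  out
}

#' Fit and score every curve of a plate dataset
#'
#' Runs [fit_logistic()] and [score_curve()] on each curve and assembles
#' one row per well.
#'
#' @param dataset A `plate_dataset`.
#' @param conditions Optional condition map ([read_condition_map()]).
#' @param gl_thresholds,gs_thresholds Class thresholds (defaults shipped
#'   with the package).
#' @param opts [fit_options()] passed to the fitter.
#' @return A data.frame with columns sample, well, condition, y0, lag, mu,
#'   A, rss, converged, gl, gs, gl_class, gs_class, ordered by sample then
#'   well.
#' @export
score_plate <- function(dataset, conditions = NULL,
                        gl_thresholds = default_thresholds()$gl,
                        gs_thresholds = default_thresholds()$gs,
                        opts = fit_options()) {
  stopifnot(inherits(dataset, "plate_dataset"))
  rows <- lapply(dataset$curves, function(cv) {
    fit <- fit_logistic(cv, opts)
    sc <- score_curve(fit, gl_thresholds, gs_thresholds,
                      allow_unconverged = TRUE)
    data.frame(sample = cv$sample %||% "", well = cv$well_id %||% "",
               condition = condition_of(conditions, cv$well_id %||% ""),
               y0 = fit$params$y0, lag = fit$params$lag,
               mu = fit$params$mu, A = fit$params$A,
               rss = fit$rss, converged = fit$converged,
               gl = sc$gl, gs = sc$gs,
               gl_class = sc$gl_class, gs_class = sc$gs_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$sample, out$well), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results table
#'
#' One record per curve, with floats at 6 significant digits and a
#' deterministic row order (sample, then well), as tab-delimited text or a
#' JSON array of objects with the same field names.
#'
#' @param results A data.frame as produced by [score_plate()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  out <- results[order(results$sample, results$well), , drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "converged"
  out[num] <- lapply(out[num], signif, digits = 6)
  if (format == "tsv") {
    con <- file(path, open = "wb")  # binary: LF endings on every platform
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
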