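#' Write / read a breath tracing as delimited text
#'
#' The tracing file is comma-separated with header
#' `time_s,paw_cmh2o,flow_lps,volume_l`, one row per sample, values printed
#' with 9 significant digits (which round-trips bit-exactly on the text
#' representation). A JSON sidecar (`<path>.json`) carries the sampling
#' metadata: sample rate, inspiratory window, hold window, and — when the
#' breath was simulated — the ventilator settings, ground-truth mechanics
#' and seed.
#'
#' @param breath A `breath_tracing`.
#' @param path Tracing file path; the sidecar is written next to it.
#' @return `write_tracing` returns `path` invisibly; `read_tracing` returns
#'   the restored `breath_tracing`.
#' @export
write_tracing <- function(breath, path) {
  stopifnot(inherits(breath, "breath_tracing"))
  fmt <- function(x) sprintf("%.9g", x)
  lines <- c("time_s,paw_cmh2o,flow_lps,volume_l",
             paste(fmt(breath$time), fmt(breath$paw), fmt(breath$flow),
                   fmt(breath$volume), sep = ","))
  writeLines(lines, path)
  meta <- list(sample_rate = breath$sample_rate,
               insp_start = breath$insp_start, insp_end = breath$insp_end,
               has_hold = breath$has_hold,
               hold_start = breath$hold_start, hold_end = breath$hold_end)
  if (!is.null(breath$meta$settings))
    meta$settings <- unclass(breath$meta$settings)
  if (!is.null(breath$meta$truth))
    meta$truth <- unclass(breath$meta$truth)
  if (!is.null(breath$meta$seed)) meta$seed <- breath$meta$seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_tracing
#' @export
read_tracing <- function(path) {
  vr_check(file.exists(path), paste("no such tracing file:", path),
           "format_error")
  lines <- readLines(path)
  vr_check(length(lines) >= 2, "tracing file is empty", "format_error")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  expected <- c("time_s", "paw_cmh2o", "flow_lps", "volume_l")
  vr_check(identical(header, expected),
           paste("missing or misordered columns; expected header:",
                 paste(expected, collapse = ",")),
           "format_error")
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  bad_len <- which(lengths(body) != 4)
  vr_check(length(bad_len) == 0,
           paste("malformed rows (wrong field count) at lines:",
                 paste(utils::head(bad_len + 1, 5), collapse = ", ")),
           "format_error")
  m <- matrix(suppressWarnings(as.numeric(unlist(body))), ncol = 4, byrow = TRUE)
  bad_num <- which(apply(!is.finite(m), 1, any))
  vr_check(length(bad_num) == 0,
           paste("non-numeric values at lines:",
                 paste(utils::head(bad_num + 1, 5), collapse = ", ")),
           "format_error")
  time <- m[, 1]
  vr_check(all(diff(time) > 0), "time column is not strictly increasing",
           "format_error")

  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    sample_rate <- meta$sample_rate
    insp_start <- meta$insp_start; insp_end <- meta$insp_end
    has_hold <- isTRUE(meta$has_hold)
    hold_start <- if (is.null(meta$hold_start)) NA_integer_ else meta$hold_start
    hold_end <- if (is.null(meta$hold_end)) NA_integer_ else meta$hold_end
    extra <- list()
    if (!is.null(meta$settings))
      extra$settings <- do.call(ventilator_settings, meta$settings)
    if (!is.null(meta$truth))
      extra$truth <- do.call(mechanics_params, meta$truth)
    if (!is.null(meta$seed)) extra$seed <- meta$seed
  } else {
    # no sidecar: infer the sampling rate from the time axis and the
    # inspiratory window as the initial run of positive flow
    sample_rate <- 1 / stats::median(diff(time))
    pos <- m[, 3] > 0
    insp_start <- 1L
    insp_end <- if (any(!pos)) which(!pos)[1] else nrow(m) + 1L
    has_hold <- FALSE; hold_start <- hold_end <- NA_integer_
    extra <- list()
  }
  new_breath_tracing(time = time, paw = m[, 2], flow = m[, 3], volume = m[, 4],
                     insp_start = insp_start, insp_end = insp_end,
                     sample_rate = sample_rate, has_hold = has_hold,
                     hold_start = hold_start, hold_end = hold_end,
                     meta = extra)
}

#' Write / read a breath pool as a directory of tracing files
#'
#' Each record becomes `rec_NNN_regular.csv` and `rec_NNN_hold.csv` (with
#' their JSON sidecars); `pool.json` records the seed and record count.
#'
#' @param pool A `breath_pool`.
#' @param dir Directory (created if needed).
#' @return `write_pool` returns `dir` invisibly; `read_pool` the restored
#'   `breath_pool`.
#' @export
write_pool <- function(pool, dir) {
  stopifnot(inherits(pool, "breath_pool"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pool)) {
    write_tracing(pool[[i]]$regular,
                  file.path(dir, sprintf("rec_%03d_regular.csv", i)))
    write_tracing(pool[[i]]$hold,
                  file.path(dir, sprintf("rec_%03d_hold.csv", i)))
  }
  jsonlite::write_json(list(n_recordings = length(pool),
                            seed = attr(pool, "seed")),
                       file.path(dir, "pool.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_pool
#' @export
read_pool <- function(dir) {
  manifest <- file.path(dir, "pool.json")
  vr_check(file.exists(manifest), paste("no pool manifest in", dir),
           "format_error")
  info <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  n <- info$n_recordings
  pool <- vector("list", n)
  for (i in seq_len(n)) {
    reg <- read_tracing(file.path(dir, sprintf("rec_%03d_regular.csv", i)))
    hold <- read_tracing(file.path(dir, sprintf("rec_%03d_hold.csv", i)))
    pool[[i]] <- list(regular = reg, hold = hold, truth = reg$meta$truth)
  }
  structure(pool, class = "breath_pool", seed = info$seed)
}

#' Read a run configuration from YAML or JSON
#'
#' A run configuration fully determines a pipeline run: pool size and
#' sampler ranges, ventilator settings, training plan, sweep grid and the
#' master seed. Fields absent from the file take the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list with components `n_recordings`, `seed`, `sampler`
#'   ([pool_sampler_config()]), `settings` ([ventilator_settings()]),
#'   `plan` ([training_plan()]), `kinds` and `levels`.
#' @export
read_run_config <- function(path) {
  vr_check(file.exists(path), paste("no such config file:", path),
           "format_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  take <- function(x, defaults) {
    if (is.null(x)) return(defaults)
    bad <- setdiff(names(x), names(defaults))
    vr_check(length(bad) == 0,
             paste("unknown config fields:", paste(bad, collapse = ", ")),
             "format_error")
    utils::modifyList(defaults, x)
  }
  sampler_args <- take(raw$sampler, formals_defaults(pool_sampler_config))
  settings_args <- take(raw$settings, formals_defaults(ventilator_settings))
  plan_args <- take(raw$plan, formals_defaults(training_plan))
  list(n_recordings = raw$n_recordings %||% 378,
       seed = raw$seed %||% 1,
       hold_duration = raw$hold_duration %||% 2,
       sampler = do.call(pool_sampler_config, sampler_args),
       settings = do.call(ventilator_settings, settings_args),
       plan = do.call(training_plan, plan_args),
       kinds = raw$kinds %||% c("RN", "TD"),
       levels = raw$levels %||% seq(0, 50, by = 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

formals_defaults <- function(f) {
  d <- formals(f)
  lapply(d, eval, envir = environment(f))
}
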