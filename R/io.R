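#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) key-value file describing one simulation run and
#' fills defaults. Recognized keys: `model`, `experiment` (`phase`, `ild`,
#' `am`, or `isi`), `fm` (Hz), `ipsi_level` (dB), `level` (dB, ISI runs),
#' `dt` (ms, default 0.002, maximum 0.01), `duration` (ms, default 40000),
#' `seed` (default 0). Unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A validated list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping: ", path)
  defaults <- list(model = NULL, experiment = NULL, fm = 300,
                   ipsi_level = 35, level = 35, dt = 0.002,
                   duration = 40000, seed = 0L)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, cfg)
  problems <- character(0)
  if (is.null(cfg$model) || !cfg$model %in% model_variants())
    problems <- c(problems, paste0(
      "model must be one of: ", paste(model_variants(), collapse = ", ")))
  if (is.null(cfg$experiment) ||
      !cfg$experiment %in% c("phase", "ild", "am", "isi"))
    problems <- c(problems, "experiment must be one of: phase, ild, am, isi")
  if (!is.numeric(cfg$dt) || cfg$dt <= 0 || cfg$dt > 0.01)
    problems <- c(problems, "dt must lie in (0, 0.01] ms")
  if (!is.numeric(cfg$duration) || cfg$duration <= 0)
    problems <- c(problems, "duration must be positive")
  if (length(problems))
    stop("invalid config (", path, "): ", paste(problems, collapse = "; "))
  structure(cfg, class = "run_config")
}

#' Write / read a tuning curve as CSV
#'
#' @param curve A `tuning_curve`.
#' @param path Output path.
#' @return `read_tuning_curve` returns the curve; writers return the path
#'   invisibly.
#' @export
write_tuning_curve <- function(curve, path) {
  df <- data.frame(abscissa = curve$abscissa, rate_spk_per_s = curve$rate)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tuning_curve
#' @export
read_tuning_curve <- function(path) {
  df <- read.csv(path)
  new_tuning_curve(df$abscissa, df$rate_spk_per_s, kind = "from file",
                   unit = "")
}

#' Write / read a spike train as CSV
#'
#' One spike time (ms) per line, full double precision; the duration is
#' stored alongside so that the round trip reproduces the object.
#'
#' @param train A [spike_train()].
#' @param path Output path.
#' @export
write_spike_train <- function(train, path) {
  df <- data.frame(time_ms = train$times,
                   duration_ms = rep(train$duration, length(train$times)))
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  df <- read.csv(path)
  dur <- if (nrow(df)) df$duration_ms[1] else NA_real_
  spike_train(df$time_ms, dur)
}

#' Write / read a full afferent input set as CSV
#'
#' One row per input spike with columns `fiber_id` (`exc_01` ... `exc_20`,
#' `inh_01` ... `inh_08`), `time_ms`, and `duration_ms`, so that the exact
#' same input realization can be re-read and delivered to every model
#' variant.
#'
#' @param inputs A list with `exc` and `inh` lists of [spike_train()]s, as
#'   returned by [generate_input_trains()].
#' @param path Output path.
#' @export
write_input_trains <- function(inputs, path) {
  row_block <- function(trains, prefix) {
    do.call(rbind, lapply(seq_along(trains), function(i) {
      tr <- trains[[i]]
      if (!length(tr$times)) return(NULL)
      data.frame(fiber_id = sprintf("%s_%02d", prefix, i),
                 time_ms = tr$times, duration_ms = tr$duration)
    }))
  }
  df <- rbind(row_block(inputs$exc, "exc"), row_block(inputs$inh, "inh"))
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_input_trains
#' @export
read_input_trains <- function(path) {
  df <- read.csv(path)
  dur <- df$duration_ms[1]
  get_group <- function(prefix, n) {
    lapply(seq_len(n), function(i) {
      id <- sprintf("%s_%02d", prefix, i)
      spike_train(df$time_ms[df$fiber_id == id], dur)
    })
  }
  # infer fiber counts from the largest index present (silent fibers at the
  # end of the bank cannot be recovered from the file)
  idx_of <- function(prefix) {
    ids <- grep(paste0("^", prefix), df$fiber_id, value = TRUE)
    if (!length(ids)) return(0L)
    max(as.integer(sub(".*_", "", ids)))
  }
  n_exc <- idx_of("exc")
  n_inh <- idx_of("inh")
  list(exc = get_group("exc", n_exc), inh = get_group("inh", n_inh))
}

#' Write a voltage trace as CSV
#'
#' Columns `time_ms` and `V_mV`.
#'
#' @param trace A [voltage_trace()].
#' @param path Output path.
#' @export
write_voltage_trace <- function(trace, path) {
  write.csv(data.frame(time_ms = trace_times(trace), V_mV = trace$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Write / read a criteria report as JSON
#'
#' The JSON object carries the per-criterion table, the targeted `score`
#' ("k/9"), and the accepted-pass count.
#'
#' @param report A [score_criteria()] report.
#' @param path Output path.
#' @export
write_criteria_report <- function(report, path) {
  obj <- list(score = attr(report, "score"),
              n_accepted = attr(report, "n_accepted"),
              criteria = as.data.frame(report))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_criteria_report
#' @export
read_criteria_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj$criteria, score = obj$score, n_accepted = obj$n_accepted,
            class = c("criteria_report", "data.frame"))
}
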