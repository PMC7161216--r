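#' Read detections from CSV
#'
#' Expects a header `frame,x,y`; frames are integers, coordinates numeric.
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data frame with columns `frame`, `x`, `y`, sorted by frame.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("frame", "x", "y")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_detections: %s must have columns frame,x,y (found: %s)",
                 path, paste(names(df), collapse = ",")), call. = FALSE)
  }
  if (!nrow(df)) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0)))
  }
  frame <- suppressWarnings(as.integer(df$frame))
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(frame) | !is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop(sprintf("read_detections: non-numeric values at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path), call. = FALSE)
  }
  out <- data.frame(frame = frame, x = x, y = y)
  out[order(out$frame), , drop = FALSE]
}

#' Write tracks to CSV
#'
#' Columns `track_id,frame,x,y,status`.
#'
#' @param tracks result of [track_sequence()] or a data frame from
#'   [tracks_to_df()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- if (is.data.frame(tracks)) tracks else tracks_to_df(tracks)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a policy checkpoint
#'
#' Checkpoints are a single JSON document holding the architecture, the
#' normalization scheme, batch-normalization running statistics, training
#' metadata and all parameters (text, so checkpoints survive any
#' source-only transport).
#'
#' @param model a [policy_model()].
#' @param path file path (conventionally `.json`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored [policy_model()].
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "policy_model"))
  payload <- list(
    format = "lapnet-policy-1",
    n_blocks = model$n_blocks, n_channels = model$n_channels,
    kernel_size = model$kernel_size,
    bn_eps = model$bn_eps, bn_momentum = model$bn_momentum,
    normalization = model$normalization,
    training_steps = model$training_steps, seed = model$seed,
    bn_mean = model$bn_mean, bn_var = model$bn_var,
    params = list(
      W1 = as.vector(model$params$W1), b1 = model$params$b1,
      Wmid = lapply(model$params$Wmid, as.vector),
      Wlast = as.vector(model$params$Wlast), blast = model$params$blast))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "lapnet-policy-1")) {
    stop("load_checkpoint: unrecognized checkpoint format", call. = FALSE)
  }
  model <- policy_model(n_blocks = p$n_blocks, n_channels = p$n_channels,
                        kernel_size = p$kernel_size, seed = p$seed)
  k2 <- p$kernel_size^2
  f <- p$n_channels
  model$params$W1 <- base::matrix(p$params$W1, k2, f)
  model$params$b1 <- as.numeric(p$params$b1)
  # jsonlite simplifies a list of equal-length vectors to a row-major matrix
  split_rows <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else x
  }
  wm <- split_rows(p$params$Wmid)
  model$params$Wmid <- lapply(wm, function(w) base::matrix(w, k2 * f, f))
  model$params$Wlast <- base::matrix(p$params$Wlast, k2 * f, 1L)
  model$params$blast <- as.numeric(p$params$blast)
  bm <- split_rows(p$bn_mean)
  bv <- split_rows(p$bn_var)
  model$bn_mean <- lapply(bm, as.numeric)
  model$bn_var <- lapply(bv, as.numeric)
  model$bn_eps <- p$bn_eps
  model$bn_momentum <- p$bn_momentum
  model$training_steps <- as.integer(p$training_steps)
  model
}

#' Write / read a flat run configuration file
#'
#' One `key: value` pair per line; values are scalars.  Used so every
#' experiment directory carries its resolved configuration.
#'
#' @param config named list of scalar values.
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a named list (numbers parsed where possible).
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s: %s", k, format(config[[k]], scientific = FALSE, trim = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    sep <- regexpr(":", ln, fixed = TRUE)
    if (sep < 0) stop(sprintf("read_run_config: malformed line %s", ln),
                      call. = FALSE)
    key <- trimws(substr(ln, 1L, sep - 1L))
    val <- trimws(substr(ln, sep + 1L, nchar(ln)))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a tracking scenario to CSV files
#'
#' @param scenario a [generate_crossing_scenario()] result.
#' @param truth_path,measurements_path output CSV paths (`target_id,frame,x,y`
#'   and `frame,x,y`).
#' @return invisibly, the two paths.
#' @export
write_scenario <- function(scenario, truth_path, measurements_path) {
  utils::write.csv(scenario$truth, truth_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(scenario$measurements, measurements_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(truth_path, measurements_path))
}
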