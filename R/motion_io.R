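#' Construct a motion trial
#'
#' A motion trial holds time-sampled generalized-coordinate values: a strictly
#' increasing time vector (seconds) and a frames-by-columns value matrix in
#' internal units (radians for rotations, meters for translations).
#'
#' @param name trial name.
#' @param times numeric vector of frame times (s), strictly increasing.
#' @param values numeric matrix, one row per frame, one column per coordinate.
#' @param column_names coordinate column names (defaults to `colnames(values)`).
#' @param source `"real"` (measured motion) or `"random"`.
#' @return an object of class `motion_trial`.
#' @export
motion_trial <- function(name, times, values, column_names = colnames(values),
                         source = c("real", "random")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop("length(times) must equal nrow(values)")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (is.null(column_names) || length(column_names) != ncol(values))
    stop("column_names must name every value column")
  colnames(values) <- column_names
  structure(list(name = name, column_names = column_names,
                 times = as.numeric(times), values = values, source = source),
            class = "motion_trial")
}

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("<motion_trial> %s: %d frames x %d columns [%s]\n",
              x$name, nrow(x$values), ncol(x$values), x$source))
  invisible(x)
}

n_frames <- function(trial) nrow(trial$values)

mot_format_error <- function(path, line, msg) {
  stop(structure(class = c("skelsynth_format_error", "error", "condition"),
                 list(message = sprintf("%s:%d: %s", path, line, msg), call = NULL)))
}

# Decide which .mot columns hold rotational quantities (for degree conversion).
# With a bound model, a column is rotational iff the matching coordinate drives
# a rotation DOF; otherwise a documented heuristic is used: every non-time
# column is rotational unless its name carries a translation marker
# (_tx/_ty/_tz suffix).
rotational_columns <- function(cols, model = NULL) {
  if (!is.null(model)) {
    kind <- character(0)
    for (j in model$joints) for (d in j$dofs) kind[d$coordinate] <- d$kind
    out <- vapply(cols, function(cn) {
      if (cn %in% names(kind)) kind[[cn]] == "rotation" else !grepl("_t[xyz]$", cn)
    }, NA)
  } else {
    out <- !grepl("_t[xyz]$", cols)
  }
  stats::setNames(out, cols)
}

#' Read an OpenSim .mot motion file
#'
#' Parses the text header (key=value lines terminated by `endheader`,
#' case-insensitive keys), then the column-name row (which must contain
#' `time`) and whitespace- or tab-delimited data rows. If the header declares
#' `inDegrees=yes` (the OpenSim default when the key is absent), rotational
#' columns are converted to radians; which columns are rotational is decided by
#' the bound `model` when given, else by name heuristic (see Details).
#'
#' @details Without a model, every non-time column is treated as rotational
#'   unless its name ends in `_tx`, `_ty` or `_tz`; pass `rotational` to
#'   override column classification explicitly.
#'
#' @param path .mot file path.
#' @param model optional `skeletal_model` used to classify columns.
#' @param rotational optional named logical vector overriding the
#'   rotational-column classification.
#' @param source source tag stored on the trial (`"real"` or `"random"`).
#' @return a `motion_trial` with values in radians/meters.
#' @export
read_mot <- function(path, model = NULL, rotational = NULL,
                     source = c("real", "random")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop(sprintf(".mot file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  end_idx <- which(tolower(trimws(lines)) == "endheader")
  if (length(end_idx) == 0)
    mot_format_error(path, length(lines), "no 'endheader' line found")
  end_idx <- end_idx[1]
  header <- list()
  for (i in seq_len(end_idx - 1)) {
    ln <- trimws(lines[i])
    if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      header[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  in_degrees <- tolower(header[["indegrees"]] %||% "yes") %in% c("yes", "true", "1")
  body <- lines[(end_idx + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1) mot_format_error(path, end_idx + 1, "missing column header row")
  split_row <- function(ln) strsplit(trimws(ln), "[ \t]+")[[1]]
  cols <- split_row(body[1])
  time_col <- which(tolower(cols) == "time")
  if (length(time_col) != 1)
    mot_format_error(path, end_idx + 1, "column header must contain exactly one 'time' column")
  data_lines <- body[-1]
  vals <- matrix(NA_real_, nrow = length(data_lines), ncol = length(cols))
  for (i in seq_along(data_lines)) {
    fields <- split_row(data_lines[i])
    if (length(fields) != length(cols))
      mot_format_error(path, end_idx + 1 + i,
                       sprintf("row has %d fields, expected %d", length(fields), length(cols)))
    v <- suppressWarnings(as.numeric(fields))
    if (any(is.na(v)))
      mot_format_error(path, end_idx + 1 + i, "non-numeric field in data row")
    vals[i, ] <- v
  }
  times <- vals[, time_col]
  values <- vals[, -time_col, drop = FALSE]
  value_cols <- cols[-time_col]
  colnames(values) <- value_cols
  if (in_degrees) {
    rot <- if (!is.null(rotational)) {
      vapply(value_cols, function(cn) isTRUE(rotational[[cn]]), NA)
    } else {
      rotational_columns(value_cols, model)
    }
    values[, rot] <- values[, rot, drop = FALSE] * pi / 180
  }
  name <- header[["name"]] %||% tools::file_path_sans_ext(basename(path))
  motion_trial(name = name, times = times, values = values,
               column_names = value_cols, source = source)
}

#' Write a motion trial as an OpenSim .mot file
#'
#' Emits a header (`nRows`, `nColumns`, `inDegrees=no`, `endheader`) followed
#' by tab-delimited data; values are written in internal units (radians /
#' meters) at full precision, so `read_mot(write_mot(x))` round-trips within
#' 1e-10.
#'
#' @param trial a `motion_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(trial, path) {
  stopifnot(inherits(trial, "motion_trial"))
  if (n_frames(trial) == 0) stop("refusing to write an empty trial")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(trial$name,
               "version=1",
               sprintf("nRows=%d", n_frames(trial)),
               sprintf("nColumns=%d", ncol(trial$values) + 1L),
               "inDegrees=no",
               "endheader",
               paste(c("time", trial$column_names), collapse = "\t")), con)
  rows <- cbind(trial$times, trial$values)
  writeLines(apply(rows, 1, function(r) paste(sprintf("%.12g", r), collapse = "\t")), con)
  invisible(path)
}

#' Select an equal number of frames from each motion trial
#'
#' Emulates drawing a fixed total frame budget evenly across motion trials so
#' every motion type is represented: each trial receives
#' `floor(total / n_trials)` frames, with the remainder going to the first
#' `total %% n_trials` trials in input order. Within a trial the selected frame
#' indices are evenly strided from the first to the last frame
#' (`round(k * (F - 1) / (q - 1))` for `k = 0..q-1`, first frame only when
#' `q = 1`).
#'
#' @param trials list of `motion_trial` objects.
#' @param total total number of frames to select (>= number of trials).
#' @return data.frame with columns `trial` (name) and `frame` (1-based index),
#'   in trial order.
#' @export
extract_equal_frames <- function(trials, total) {
  n <- length(trials)
  if (n == 0) stop("no trials given")
  if (total < n) stop("total must be at least the number of trials")
  quotas <- rep(total %/% n, n) + c(rep(1L, total %% n), rep(0L, n - total %% n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    trial <- trials[[i]]
    f <- n_frames(trial)
    q <- quotas[i]
    if (f == 0) stop(sprintf("trial '%s' has no frames", trial$name))
    if (q > f) stop(sprintf("quota %d exceeds frame count %d of trial '%s'",
                            q, f, trial$name))
    idx <- if (q == 1) 0L else round((0:(q - 1)) * (f - 1) / (q - 1))
    out[[i]] <- data.frame(trial = trial$name, frame = as.integer(idx) + 1L,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build a pose from one frame of a motion trial
#'
#' Columns are matched to model coordinates by exact name; coordinates absent
#' from the trial take their model default; trial columns that match no
#' coordinate are ignored with a warning.
#'
#' @param model a `skeletal_model`.
#' @param trial a `motion_trial`.
#' @param index 1-based frame index.
#' @return a named numeric pose vector.
#' @export
pose_from_frame <- function(model, trial, index) {
  if (index < 1 || index > n_frames(trial))
    stop(sprintf("frame index %d out of range [1, %d]", index, n_frames(trial)))
  pose <- default_pose(model)
  shared <- intersect(trial$column_names, names(pose))
  extra <- setdiff(trial$column_names, names(pose))
  if (length(extra) > 0)
    warning(sprintf("ignoring trial columns with no matching coordinate: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  pose[shared] <- trial$values[index, shared]
  pose
}
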