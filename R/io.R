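# Plain-text serialization: trajectories as CSV, models as key-value text.

#' Write and read stage trajectories as CSV
#'
#' The on-disk format is a plain CSV with header
#' `time_days,H,I,P,M`.
#'
#' @param trajectory A `stage_trajectory` tibble.
#' @param path Output file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a `stage_trajectory` tibble.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(trajectory[, c("time_days", "H", "I", "P", "M")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  stopifnot(all(c("time_days", "H", "I", "P", "M") %in% names(df)))
  class(df) <- c("stage_trajectory", class(df))
  df
}

#' Serialize a stage model as key-value text
#'
#' Rates, time steps, cost diagonals, threshold and (if solved) the gain
#' rows are written one `key = value` pair per line.
#'
#' @param model A [stage_model()].
#' @param path Output file path.
#' @return `write_stage_model()` returns `path` invisibly;
#'   `read_stage_model()` returns a `stage_model` (gain re-attached if
#'   present).
#' @export
write_stage_model <- function(model, path) {
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  lines <- c(
    paste("natural =", num(as.numeric(model$natural))),
    paste("actuated =", num(as.numeric(model$actuated))),
    paste("dt =", num(model$dt)),
    paste("lqr_dt =", num(model$lqr_dt)),
    paste("Q_diag =", num(diag(model$Q))),
    paste("R_diag =", num(diag(model$R))),
    paste("heal_threshold =", num(model$heal_threshold))
  )
  if (!is.null(model$K)) {
    lines <- c(lines, vapply(1:4, function(r) {
      paste0("K_row", r, " = ", num(model$K[r, ]))
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stage_model
#' @export
read_stage_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(
    lapply(kv, function(x) as.numeric(strsplit(trimws(x[2]), "\\s+")[[1]])),
    vapply(kv, `[`, character(1), 1)
  )
  model <- stage_model(
    natural = do.call(rate_constants, as.list(vals$natural)),
    actuated = do.call(rate_constants, as.list(vals$actuated)),
    dt = vals$dt, lqr_dt = vals$lqr_dt,
    Q = diag(vals$Q_diag), R = diag(vals$R_diag),
    heal_threshold = vals$heal_threshold
  )
  if (!is.null(vals$K_row1)) {
    model$K <- rbind(vals$K_row1, vals$K_row2, vals$K_row3, vals$K_row4)
    dimnames(model$K) <- NULL
  }
  model
}
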