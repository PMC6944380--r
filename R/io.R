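#' Write / read a trial log as CSV
#'
#' Columns: `n`, `block`, `target_id`, `u_x`, `u_y`, `q1..qS`, `p_x`, `p_y`,
#' `e_norm`, `pe` (plus `phase` for two-phase sessions). Noise draws
#' (`xi*`) are internal state and are not serialized.
#'
#' @param x A `bomi_session`, `bomi_subject`, or trial-log tibble.
#' @param path CSV path.
#' @return `write_trial_log_csv()` returns `path` invisibly;
#'   `read_trial_log_csv()` returns a tibble.
#' @export
write_trial_log_csv <- function(x, path) {
  log <- if (inherits(x, "bomi_subject")) x$log
         else if (inherits(x, "bomi_session")) x$log
         else x
  keep <- !grepl("^xi[0-9]+$", names(log))
  utils::write.csv(as.data.frame(log[, keep]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log_csv
#' @export
read_trial_log_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write / read learner-state snapshots as long-format CSV
#'
#' One row per (trial, matrix, row, col) entry, so the full trajectory of
#' H_hat and G round-trips through a plain text file.
#'
#' @param states The `states` element of a `bomi_session`.
#' @param path CSV path.
#' @return `write_states_csv()` returns `path` invisibly;
#'   `read_states_csv()` returns a `states`-shaped list.
#' @export
write_states_csv <- function(states, path) {
  stopifnot(is.list(states), !is.null(states$H_hat), !is.null(states$G))
  long <- function(arr, name) {
    d <- dim(arr)
    data.frame(n = rep(seq_len(d[3]), each = d[1] * d[2]),
               matrix = name,
               row = rep(seq_len(d[1]), times = d[2] * d[3]),
               col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               value = as.numeric(arr))
  }
  utils::write.csv(rbind(long(states$H_hat, "H_hat"), long(states$G, "G")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states_csv
#' @export
read_states_csv <- function(path) {
  df <- utils::read.csv(path)
  rebuild <- function(name) {
    d <- df[df$matrix == name, ]
    arr <- array(NA_real_, c(max(d$row), max(d$col), max(d$n)))
    arr[cbind(d$row, d$col, d$n)] <- d$value
    arr
  }
  list(H_hat = rebuild("H_hat"), G = rebuild("G"))
}

#' Write an analysis-results summary as JSON
#'
#' @param results A named list (e.g. per-subject parameter and fit values).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
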