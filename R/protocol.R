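#' Center-out protocol configuration
#'
#' Describes the training session: `n_targets` targets equally spaced on a
#' circle of radius `radius`, presented in randomized blocks (within each
#' cycle of `n_targets` trials every target appears exactly once), for
#' `n_blocks` blocks of `reps_per_block` cycles. The default reproduces the
#' study session: 6 targets at 5 cm, 6 blocks x 9 repetitions = 324
#' center-out movements. `blind_duration` (the initial feedback-free phase of
#' each reach, seconds) is carried as metadata; the model is endpoint-level.
#'
#' @param n_targets Number of peripheral targets.
#' @param radius Target distance from the workspace center (cm).
#' @param target_radius Target disc radius (cm); also the success criterion
#'   for the windowed reaching error.
#' @param n_blocks,reps_per_block Session structure.
#' @param blind_duration Feedback-free phase duration (s), metadata only.
#' @param seed RNG seed for the target order.
#' @return A `bomi_protocol` list.
#' @export
protocol_config <- function(n_targets = 6, radius = 5, target_radius = 1,
                            n_blocks = 6, reps_per_block = 9,
                            blind_duration = 0.4, seed = 1) {
  stopifnot(n_targets >= 1, n_blocks >= 1, reps_per_block >= 1,
            radius > target_radius, target_radius > 0)
  structure(list(n_targets = as.integer(n_targets), radius = radius,
                 target_radius = target_radius, n_blocks = as.integer(n_blocks),
                 reps_per_block = as.integer(reps_per_block),
                 blind_duration = blind_duration, seed = as.integer(seed)),
            class = "bomi_protocol")
}

#' Generate the center-out target sequence
#'
#' Target k (k = 0, ..., n_targets - 1) sits at angle k * 360/n_targets
#' degrees, counterclockwise from +x, at distance `radius` from the origin
#' (the workspace center). Presentation order is randomized per cycle under
#' the constraint that no target repeats before all others have been
#' presented (randomized blocks). Return-to-center movements are not
#' enumerated as learning trials: at the center target u = 0 the
#' inverse-model update vanishes identically.
#'
#' @param cfg A [protocol_config()].
#' @return A tibble with one row per center-out trial: `n` (trial index),
#'   `block`, `cycle`, `target_id` (1-based), `u_x`, `u_y` (cm). The
#'   configuration is attached as attribute `"protocol"`.
#' @export
generate_targets <- function(cfg = protocol_config()) {
  stopifnot(inherits(cfg, "bomi_protocol"))
  k <- seq_len(cfg$n_targets) - 1
  ang <- 2 * pi * k / cfg$n_targets
  ux <- cfg$radius * cos(ang)
  uy <- cfg$radius * sin(ang)
  n_cycles <- cfg$n_blocks * cfg$reps_per_block
  order_ids <- withr_seed(cfg$seed, {
    unlist(lapply(seq_len(n_cycles), function(i) sample.int(cfg$n_targets)))
  })
  n_total <- n_cycles * cfg$n_targets
  out <- tibble::tibble(
    n = seq_len(n_total),
    block = rep(seq_len(cfg$n_blocks), each = cfg$reps_per_block * cfg$n_targets),
    cycle = rep(seq_len(n_cycles), each = cfg$n_targets),
    target_id = order_ids,
    u_x = ux[order_ids],
    u_y = uy[order_ids]
  )
  attr(out, "protocol") <- cfg
  out
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Trailing windows over a series ("movement sets")
#'
#' The analysis operates on movement sets: the window ending at trial n
#' contains trials n - r + 1, ..., n, and windows shift by one trial. With
#' the default r = 12 and six targets, each window contains on average two
#' trials per target.
#'
#' @param x A vector, or a list/data frame whose elements/rows are trials.
#' @param r Window length (>= 1).
#' @return A list of windows; element i is the window ending at trial
#'   r + i - 1. Names give the ending trial index.
#' @export
windowed <- function(x, r = 12) {
  stopifnot(r >= 1)
  len <- if (is.data.frame(x)) nrow(x) else length(x)
  if (len < r) stop("series shorter than the window length r", call. = FALSE)
  ends <- r:len
  win <- lapply(ends, function(e) {
    idx <- (e - r + 1):e
    if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
  })
  names(win) <- ends
  win
}
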