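#' Build an interleaved multi-echo schedule
#'
#' Constructs the echo-time schedule of a multi-echo gradient-echo
#' acquisition in which `n_trains` interleaved echo trains together sample a
#' uniform effective echo spacing. Echo `k` has
#' `TE_k = first_te + (k - 1) * effective_spacing`, and train `j` owns echoes
#' `j, j + n_trains, ...`. The default protocol acquires 18 echoes as three
#' interleaved six-echo trains with a 1.395 ms first echo and 0.737 ms
#' effective spacing, so the last echo falls at 13.92 ms.
#'
#' @param n_echoes total number of echoes.
#' @param first_te first echo time (ms).
#' @param effective_spacing uniform effective echo spacing (ms).
#' @param n_trains number of interleaved trains; must divide `n_echoes`.
#' @return An object of class `echo_schedule`: list with `te_ms`, `train`
#'   (train index per echo) and `n_trains`.
#' @examples
#' sched <- build_echo_schedule(18, 1.395, 0.737, 3)
#' round(sched$te_ms[4], 2)   # 3.61
#' @export
build_echo_schedule <- function(n_echoes = 18L, first_te = 1.395,
                                effective_spacing = 0.737, n_trains = 3L) {
  n_echoes <- as.integer(check_scalar(n_echoes, "n_echoes", 1))
  n_trains <- as.integer(check_scalar(n_trains, "n_trains", 1))
  check_scalar(first_te, "first_te", 0)
  check_scalar(effective_spacing, "effective_spacing", 1e-9)
  if (n_echoes %% n_trains != 0L)
    stop_cfg("n_echoes (%d) must be divisible by n_trains (%d)", n_echoes, n_trains)
  te <- first_te + (seq_len(n_echoes) - 1) * effective_spacing
  train <- ((seq_len(n_echoes) - 1L) %% n_trains) + 1L
  structure(list(te_ms = te, train = train, n_trains = n_trains),
            class = "echo_schedule")
}

#' @export
print.echo_schedule <- function(x, ...) {
  cat(sprintf("Echo schedule: %d echoes in %d interleaved train(s)\n",
              length(x$te_ms), x$n_trains))
  cat(sprintf("  TE %.3f .. %.3f ms (effective spacing %.3f ms)\n",
              x$te_ms[1], x$te_ms[length(x$te_ms)],
              if (length(x$te_ms) > 1) diff(x$te_ms)[1] else NA_real_))
  invisible(x)
}

# Subset a schedule to a set of retained echo indices.
subset_schedule <- function(schedule, keep) {
  structure(list(te_ms = schedule$te_ms[keep], train = schedule$train[keep],
                 n_trains = schedule$n_trains),
            class = "echo_schedule")
}

#' Drop the first echo of every echo train
#'
#' Removes the leading echo of each interleaved train from a multi-echo
#' series (or bare schedule) to suppress eddy-current phase contamination of
#' the first readout in each train. Under the default 18-echo, 3-train
#' schedule this retains 15 echoes, the earliest at 3.61 ms. The operation is
#' deliberately not idempotent: applying it again removes the next leading
#' echo of each train.
#'
#' @param x an `echo_series` or `echo_schedule`.
#' @return object of the same class with the leading train echoes removed.
#' @export
drop_leading_train_echoes <- function(x) {
  schedule <- if (inherits(x, "echo_series")) x$schedule else x
  if (!inherits(schedule, "echo_schedule")) stop_cfg("need an echo_schedule or echo_series")
  per_train <- table(schedule$train)
  if (any(per_train <= 1L))
    stop_cfg("cannot drop the leading echo of a length-1 train")
  first_of_train <- !duplicated(schedule$train)
  keep <- which(!first_of_train)
  new_sched <- subset_schedule(schedule, keep)
  if (inherits(x, "echo_schedule")) return(new_sched)
  x$data <- x$data[, , , keep, drop = FALSE]
  x$schedule <- new_sched
  x
}
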