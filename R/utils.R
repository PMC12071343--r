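# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort warn inform
NULL

stop_fc <- function(msg, class = "fibercouple_error") {
  rlang::abort(msg, class = class)
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_fc(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_fc(sprintf("`%s` must be > 0 (got %g)", name, x))
  invisible(x)
}

# index of the sample nearest to time `t` on a uniform grid starting at time[1]
nearest_index <- function(time, t) {
  i <- round((t - time[1]) / (time[2] - time[1])) + 1L
  pmin(pmax(as.integer(i), 1L), length(time))
}
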