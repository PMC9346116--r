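# Internal validation helpers. All user-facing errors go through
# rlang::abort with a class so tests can assert on them.

stop_config <- function(msg) rlang::abort(msg, class = "cupcompass_config_error")
stop_format <- function(msg) rlang::abort(msg, class = "cupcompass_format_error")
stop_input  <- function(msg) rlang::abort(msg, class = "cupcompass_input_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config(sprintf("`%s` must be a single non-missing number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  if (!lo_ok || x > upper) {
    stop_config(sprintf("`%s` = %s is outside [%s, %s]", name, x, lower, upper))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, lower = min)
  if (x != as.integer(x)) {
    stop_config(sprintf("`%s` must be an integer", name))
  }
  invisible(as.integer(x))
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_input(sprintf("`%s` must be a numeric matrix", name))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_input(sprintf("`%s` must have row and column names", name))
  }
  invisible(x)
}

# lognormal draws with a given arithmetic mean and coefficient of variation;
# cv = 0 degenerates to the mean exactly
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
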