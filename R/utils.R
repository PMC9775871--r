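# shared validation helpers; errors are classed so the CLI can map them to
# exit codes and tests can assert on the class rather than the message

stop_bilexnet <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("bilexnet_", class), "bilexnet_error"), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_na = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || (!allow_na && is.na(x))) {
    stop_bilexnet(sprintf("`%s` must be a single number.", name), "validation")
  }
  if (!is.na(x) && (x < min || x > max)) {
    stop_bilexnet(
      sprintf("`%s` must be in [%s, %s], got %s.", name, format(min), format(max), format(x)),
      "validation"
    )
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x)) {
    stop_bilexnet(sprintf("`%s` must be a single integer.", name), "validation")
  }
  if (x < min) {
    stop_bilexnet(sprintf("`%s` must be >= %d, got %d.", name, min, as.integer(x)), "validation")
  }
  as.integer(x)
}

check_prob <- function(x, name) check_number(x, name, min = 0, max = 1)

check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_bilexnet(
      sprintf("%s is missing required column(s): %s.", what, paste(missing, collapse = ", ")),
      "schema"
    )
  }
  invisible(data)
}

# run `code` under `seed` without disturbing the caller's RNG state;
# seed = NULL means "use the current stream"
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
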