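abort_afms <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "afms_error", "error", "condition")))
}

abort_validation <- function(msg) abort_afms(msg, "afms_validation_error")
abort_config <- function(msg) abort_afms(msg, "afms_config_error")
abort_io <- function(msg) abort_afms(msg, "afms_io_error")

# A feature map is a finite 5-axis array (batch, H, W, D, channel).
check_feature_map <- function(x, what = "x") {
  if (!is.array(x) || length(dim(x)) != 5L)
    abort_validation(sprintf("%s must be a 5-axis array (batch, H, W, D, channel)", what))
  if (!all(is.finite(x)))
    abort_validation(sprintf("%s contains non-finite values", what))
  invisible(x)
}

# Parameter getter over a nested list, addressed "conv.W", "it1.c1.gamma", ...
nested_getter <- function(params) {
  function(name) {
    v <- params
    for (p in strsplit(name, ".", fixed = TRUE)[[1]]) {
      v <- v[[p]]
      if (is.null(v)) abort_config(sprintf("missing parameter '%s'", name))
    }
    v
  }
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

conv_init <- function(k, cin, cout) {
  list(W = he_uniform(c(k, k, k, cin, cout), k^3 * cin), b = numeric(cout))
}

bn_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
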