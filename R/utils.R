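# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a per-stage seed from a global one; kept well below .Machine$integer.max.
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2100000000L
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("wtte_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("wtte_data_error", "error")))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("wtte_domain_error", "error")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_config("'", name, "' must be a single finite positive number")
  }
  invisible(x)
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config("'", name, "' must be a probability in [0, 1]")
  }
  invisible(x)
}
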