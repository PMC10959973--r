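# internal helpers

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
  w <- a - 2 * pi * round(a / (2 * pi))
  w[w <= -pi] <- pi
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# structured one-line log; suppress with options(shoaldyn.quiet = TRUE)
shoal_log <- function(stage, ...) {
  if (isTRUE(getOption("shoaldyn.quiet", TRUE))) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), unname(lapply(kv, format)),
                      sep = "=", collapse = " "))
  message(msg)
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# bin index for left-closed bins [lo, lo+w), values equal to the upper
# edge fall in the last bin
bin_index <- function(x, lo, w, nbin) {
  i <- floor((x - lo) / w) + 1L
  i[x == lo + w * nbin] <- nbin
  i[i < 1L | i > nbin] <- NA_integer_
  as.integer(i)
}
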