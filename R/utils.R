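# internal argument checking helpers

stop_invalid <- function(...) {
  stop(structure(
    class = c("lsci_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_invalid(name, " must be a single non-missing number")
  if (finite && !is.finite(x))
    stop_invalid(name, " must be finite")
  if (positive && x <= 0)
    stop_invalid(name, " must be > 0")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_num(x, name)
  if (x != round(x) || x < min)
    stop_invalid(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

# population standard deviation (divides by n, not n-1)
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
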