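# Internal helpers shared across modules.

.msg <- function(...) message("[madcpop] ", sprintf(...))

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) .stopf("'%s' must be a number in %s%g, %g%s (got %s)",
                  name, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]", format(x)[1])
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
  if (!ok) .stopf("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

# Largest-remainder apportionment of n items over weights w (sums to n).
.apportion <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

.DNA <- c("A", "C", "G", "T")

# Random DNA string(s) of length len using the current RNG stream.
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(.DNA, len, replace = TRUE), collapse = ""), character(1))
}
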