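#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate arrange group_by summarise ungroup pull
#'   bind_rows distinct across left_join n
NULL

# centred moving average; edge samples keep shorter symmetric windows so the
# smoothed series has the same length and no NA padding
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  half <- k %/% 2L
  out <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  for (i in seq_len(min(half, n))) {
    w <- i - 1L
    out[i] <- mean(x[max(1L, i - w):min(n, i + w)])
    j <- n - i + 1L
    out[j] <- mean(x[max(1L, j - w):min(n, j + w)])
  }
  out
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
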