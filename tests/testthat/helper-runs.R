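# Build a binary string with n1 ones, n0 zeros and exactly R runs (used to
# exercise every (n0, n1, R) combination of the runs-test comparison).
make_runs_string <- function(n1, n0, R) {
  build <- function(first_n, second_n, R) {
    k1 <- ceiling(R / 2)  # blocks of the starting symbol
    k2 <- floor(R / 2)
    if (k1 > first_n || k2 > second_n) return(NULL)
    b1 <- c(rep(1, k1 - 1), first_n - (k1 - 1))
    b2 <- if (k2 > 0) c(rep(1, k2 - 1), second_n - (k2 - 1)) else integer(0)
    out <- integer(0)
    for (i in seq_len(max(k1, k2))) {
      if (i <= k1) out <- c(out, rep(0L, b1[i]))
      if (i <= k2) out <- c(out, rep(1L, b2[i]))
    }
    out
  }
  v <- build(n0, n1, R)           # starts with 0
  if (is.null(v)) {
    v <- 1L - build(n1, n0, R)    # starts with 1
  }
  stopifnot(!is.null(v), sum(v) == n1, length(v) == n0 + n1,
            1 + sum(diff(v) != 0) == R)
  v
}
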