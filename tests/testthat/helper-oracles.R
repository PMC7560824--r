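# independent brute-force oracle for the one-tailed rank-sum p value:
# enumerate every group-A assignment of the combined sample by bitmask
brute_mw <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  count <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(2^(0:(n - 1)), mask) > 0)
    if (length(sel) != na) next
    total <- total + 1L
    U <- sum(r[sel]) - na * (na + 1) / 2
    if (U >= U_obs - 1e-9) count <- count + 1L
  }
  count / total
}
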