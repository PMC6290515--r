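# Independent local-alignment oracle: exhaustive affine-gap dynamic
# programming written in plain R, used to cross-check the package's
# alignment engine on small instances. Deliberately shares no code with
# the implementation path.

oracle_local_score <- function(a, b, open = 11, ext = 1,
                               mat = flexscan::substitution_matrix()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av)
  n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
      FF[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, FF[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + mat[av[i], bv[j]],
                             E[i + 1, j + 1],
                             FF[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}
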