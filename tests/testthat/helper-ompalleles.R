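# Shared fixtures: built in code, once per test run.
SCHEME <- load_scheme()
REF <- SCHEME$reference$mature

# Mutate single positions of a sequence.
mutate_at <- function(seq, pos, res) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- res[i]
  seq
}

# Independent affine-gap Needleman-Wunsch oracle (match +1, mismatch -1,
# gap cost 5 for the first gapped residue, +1 per further residue) with
# traceback to a reference->query position map.  Deliberately plain loops:
# independent of the alignment library the package uses.
nw_map_oracle <- function(query, ref) {
  q <- strsplit(query, "")[[1]]; r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -5 - (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- -5 - (j - 2)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (q[i - 1] == r[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - 5, X[i - 1, j] - 1)
      Y[i, j] <- max(M[i, j - 1] - 5, Y[i, j - 1] - 1)
    }
  }
  # traceback
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  map_ref <- integer(m); map_ref[] <- NA_integer_
  while (i > 1 || j > 1) {
    if (state == 1) {
      map_ref[j - 1] <- i - 1
      s <- if (q[i - 1] == r[j - 1]) 1 else -1
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {      # gap in reference (query residue unaligned)
      state <- if (abs(X[i, j] - (M[i - 1, j] - 5)) < 1e-9) 1 else 2
      i <- i - 1
    } else {                      # gap in query (reference position deleted)
      state <- if (abs(Y[i, j] - (M[i, j - 1] - 5)) < 1e-9) 1 else 3
      j <- j - 1
    }
  }
  tibble::tibble(ref_pos = seq_len(m), query_pos = map_ref)
}

expect_one_row <- function(x) expect_identical(nrow(x), 1L)
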