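# Independent Levenshtein oracle: classic dynamic program written against
# the recursive definition (min over insert / delete / substitute), kept
# separate from the package's implementation path.

lev_oracle <- function(a, b) {
  A <- utf8ToInt(a)
  B <- utf8ToInt(b)
  la <- length(A)
  lb <- length(B)
  if (la == 0L) return(lb)
  if (lb == 0L) return(la)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    cur[1] <- i
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,       # delete from a
                         cur[j] + 1L,             # insert into a
                         prev[j] + (A[i] != B[j]))  # substitute/match
    }
    prev <- cur
  }
  prev[lb + 1L]
}

# All strings of length 0..max_len over the given alphabet.
all_strings <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (n in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}
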