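# Independent oracle implementations used by the suite.

# MSD by the literal double loop over the defining sum.
msd_brute_force <- function(x) {
  N <- length(x)
  sapply(seq_len(N - 1), function(n) {
    s <- 0
    for (i in seq_len(N - n)) s <- s + (x[i + n] - x[i])^2
    s / (N - n)
  })
}

# Junction microhomology by exhaustive prefix comparison on character vectors.
mh_brute_force <- function(ref_chars, start, len) {
  n <- length(ref_chars)
  best <- 0L
  for (m in seq_len(len)) {
    idx_del <- start:(start + m - 1L)
    idx_after <- (start + len):(start + len + m - 1L)
    if (max(idx_after) > n) break
    if (all(ref_chars[idx_del] == ref_chars[idx_after])) best <- m else break
  }
  best
}

# TRUE when a deletion placement is already canonical (cannot shift left)
left_alignment_stable <- function(ref, start, len) {
  s <- start
  while (s > 1 && substring(ref, s - 1, s - 1) ==
         substring(ref, s + len - 1, s + len - 1)) s <- s - 1
  s == start
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
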