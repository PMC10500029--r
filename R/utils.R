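# Internal helpers shared across modules.

# Derive a child seed from a user seed and a stream label, staying well below
# .Machine$integer.max so derived seeds remain valid R integers.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(stream)) * 131L
  as.integer((as.integer(seed) + offs) %% 2147483546L) + 1L
}


relu <- function(x) {
  x[x < 0] <- 0
  x
}

# min-max rescale to [0, 1]; constant vectors map to 0
normalize01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}
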