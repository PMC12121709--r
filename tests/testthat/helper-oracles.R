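# exhaustive enumeration oracles for the rank tests, written independently of
# the package implementations (expand.grid / combn over all assignments)

oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(ws <= W + 1e-9), mean(ws >= W - 1e-9)))
}

oracle_rank_sum <- function(a, b) {
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  U <- u_of(a, b)
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
}
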