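deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

tand <- function(x) tan(deg2rad(x))

atand <- function(x) rad2deg(atan(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing so that independent stages of a simulation can
#' be seeded from one master seed without sharing RNG streams. Values stay
#' below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param k stream index (any non-negative integer)
#' @return an integer seed
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807 + 11) %% 2147483647)
}

# FNV-1a style rolling hash over a serialized object; provenance tag only
object_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (as.double(h) * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}
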