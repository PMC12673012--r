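# Fast vectorized sine and cosine integrals Si(x), Ci(x) for x > 0.
# Small arguments: power series.  Large arguments: E1(ix) by a modified
# Lentz continued fraction, using Ci(x) = -Re E1(ix), Si(x) = pi/2 + Im
# E1(ix).  Needed in bulk (~1e6 lattice points) by the filtered-coupling
# Green tensor, where library scalar implementations are too slow.

sici <- function(x) {
  stopifnot(all(x > 0))
  si <- ci <- numeric(length(x))
  small <- x < 4
  if (any(small)) {
    xs <- x[small]
    x2 <- xs * xs
    s <- xs; term <- xs
    for (n in 1:30) {
      term <- -term * x2 / ((2 * n) * (2 * n + 1))
      s <- s + term / (2 * n + 1)
    }
    cs <- rep(0, length(xs)); term <- rep(1, length(xs))
    for (n in 1:30) {
      term <- -term * x2 / ((2 * n - 1) * (2 * n))
      cs <- cs + term / (2 * n)
    }
    si[small] <- s
    ci[small] <- 0.5772156649015328606 + log(xs) + cs
  }
  if (any(!small)) {
    z <- 1i * x[!small]
    # modified Lentz for E1(z) = exp(-z)/(z + 1/(1 + 1/(z + 2/(1 + ...))))
    tiny <- 1e-30
    f <- z
    C <- f; D <- rep(0i, length(z))
    for (i in 1:60) {
      an <- ceiling(i / 2)
      bn <- if (i %% 2 == 1) 1 else z
      D <- bn + an * D
      D[D == 0] <- tiny
      C <- bn + an / C
      C[C == 0] <- tiny
      D <- 1 / D
      f <- f * (C * D)
    }
    E1 <- exp(-z) / f
    ci[!small] <- -Re(E1)
    si[!small] <- pi / 2 + Im(E1)
  }
  list(si = si, ci = ci)
}
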