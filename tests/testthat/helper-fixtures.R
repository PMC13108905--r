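# small configurations used across test files; kept tiny so the default
# suite stays fast

toyConfig <- function(...) {
  # 3 genes (negative / wild-type / control), 2 guides, coverage 100
  simConfig(n = 3, nGuides = 2, coverage = 100,
            pctNeg = 1 / 3, pctPos = 0, pctCtrl = 1 / 3, pctWT = NA,
            pctGI = 1, ...)
}

smallConfig <- function(...) {
  simConfig(n = 12, nGuides = 2, coverage = 30, ...)
}

# brute-force oracle for the dual-knockout division distribution:
# enumerate the 3x3 joint outcomes of the two independent single-knockout
# division variables and push through y = 1(x1*x2 != 0) * (x1 + x2 - 1)
bruteForceDKO <- function(p1, p2) {
  px1 <- c(max(-p1, 0), 1 - abs(p1), max(p1, 0))
  px2 <- c(max(-p2, 0), 1 - abs(p2), max(p2, 0))
  out <- numeric(4)
  for (x1 in 0:2) {
    for (x2 in 0:2) {
      y <- if (x1 * x2 == 0) 0 else x1 + x2 - 1
      out[y + 1] <- out[y + 1] + px1[x1 + 1] * px2[x2 + 1]
    }
  }
  out
}
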