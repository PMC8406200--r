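# shared fixture builders; everything is generated in code at test time

# write a minimal hand-constructed PDB file and return its path
writeMiniPdb <- function(lines = NULL) {
  if (is.null(lines))
    lines <- c(
      paste0("ATOM      1  N   ALA A   1       0.000   1.000   2.000",
             "  1.00  0.00           N"),
      paste0("ATOM      2  CA  ALA A   1       1.500   1.000   2.000",
             "  1.00  0.00           C"),
      paste0("ATOM      3  C   ALA A   1       2.000   2.400   2.000",
             "  1.00  0.00           C"),
      "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# a straight C-alpha chain along x
straightChain <- function(n, spacing = 3.8, chain = "A") {
  structureFromAtoms(data.frame(chain = chain, resno = seq_len(n),
                                x = (seq_len(n) - 1) * spacing,
                                y = 0, z = 0))
}

# coordinates of a small rigid test cloud (fixed, not random)
testCloud <- function(n = 10) {
  k <- seq_len(n)
  cbind(sin(k) * 5 + k * 0.7, cos(k) * 4, (k %% 3) * 2.5)
}

randomRotation <- function() {
  axis <- rnorm(3)
  rotationMatrix(axis / sqrt(sum(axis^2)), runif(1, 1, 179))
}
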