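# build a small synthetic CA-only PDB (ideal-helix trace) covering the
# given residue range; plain text, generated at test time
write_toy_pdb <- function(path, residues = 1:60, chain = "A") {
  lines <- character(0)
  for (i in seq_along(residues)) {
    t <- i * 100 * pi / 180
    xyz <- c(2.3 * cos(t), 2.3 * sin(t), 1.5 * i)
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, chain, residues[i], xyz[1], xyz[2], xyz[3]))
  }
  writeLines(c(lines, "END"), path)
  path
}
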