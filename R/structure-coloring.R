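#' Encode residue difference categories into a PDB B-factor column
#'
#' Writes a copy of the structure with the per-residue difference category
#' coded in the B-factor column — `major_decrease` -2, `modest_decrease`
#' -1, `none` 0, `modest_increase` 1, `major_increase` 2 — plus a
#' companion PyMOL script that colors by the code (dark/light blue for
#' protection, light/dark green for increased exchange), reproducing the
#' standard HDX structural-mapping view. Residues absent from the
#' annotations keep a code of 0; annotated residues missing from the
#' structure are logged and skipped.
#'
#' @param annotations Tibble from [consolidate_residues()].
#' @param pdb_path Input PDB file.
#' @param out_pdb Output PDB path.
#' @param chain Chain identifier to annotate.
#' @param script_path Output path of the PyMOL coloring script; default
#'   `out_pdb` with a `.pml` extension.
#'
#' @return Invisibly, a list with `pdb`, `script` and `n_colored` (number
#'   of annotated residues found in the structure).
#' @export
write_structure_coloring <- function(annotations, pdb_path, out_pdb,
                                     chain = "A",
                                     script_path = sub("\\.pdb$", ".pml",
                                                       out_pdb)) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("package 'bio3d' is required for structure coloring", call. = FALSE)
  }
  stopifnot(file.exists(pdb_path))
  pdb <- bio3d::read.pdb(pdb_path)
  if (!chain %in% unique(pdb$atom$chain)) {
    stop("chain '", chain, "' not present in ", pdb_path, call. = FALSE)
  }
  codes <- c(major_decrease = -2, modest_decrease = -1, none = 0,
             modest_increase = 1, major_increase = 2)
  pdb$atom$b <- 0
  in_chain <- pdb$atom$chain == chain
  present <- unique(pdb$atom$resno[in_chain])
  n_colored <- 0L
  for (i in seq_len(nrow(annotations))) {
    res <- annotations$residue[i]
    if (!res %in% present) {
      message("residue ", res, " not in structure chain ", chain,
              "; skipped")
      next
    }
    sel <- in_chain & pdb$atom$resno == res
    pdb$atom$b[sel] <- codes[[as.character(annotations$category[i])]]
    n_colored <- n_colored + 1L
  }
  bio3d::write.pdb(pdb, file = out_pdb)
  script <- c(
    sprintf("load %s, hdxmap", out_pdb),
    "color grey80, hdxmap",
    "color density,  hdxmap and b < -1.5",
    "color lightblue, hdxmap and b > -1.5 and b < -0.5",
    "color palegreen, hdxmap and b > 0.5 and b < 1.5",
    "color forest,    hdxmap and b > 1.5",
    "show surface, hdxmap"
  )
  writeLines(script, script_path)
  invisible(list(pdb = out_pdb, script = script_path, n_colored = n_colored))
}
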