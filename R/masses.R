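# Monoisotopic mass chemistry for derivatized N-glycan compositions.
#
# Residue masses are the dehydrated (in-chain) monosaccharide masses built
# from CODATA atomic monoisotopic masses. Sialic acids carry the
# linkage-specific derivatization: alpha-2,6-linked carboxyls are ethyl
# esterified (+C2H4), alpha-2,3-linked ones form lactones (-H2O), which makes
# the two linkage isomers mass-distinguishable in MS1.

# atomic monoisotopic masses (Da)
.mass_H <- 1.00782503207
.mass_D <- 2.01410177785
.mass_C <- 12.0
.mass_N <- 14.0030740048
.mass_O <- 15.9949146196
.mass_Na <- 22.9897692809
.mass_e <- 0.00054857991

.mass_water <- 2 * .mass_H + .mass_O          # 18.010565
.mass_c2h4 <- 2 * .mass_C + 4 * .mass_H       # ethyl ester shift, 28.031300
.mass_acetyl <- 2 * .mass_C + 2 * .mass_H + .mass_O # O-acetyl, 42.010565

# underivatized residue masses
.res_hex <- 6 * .mass_C + 10 * .mass_H + 5 * .mass_O          # 162.052824
.res_hexnac <- 8 * .mass_C + 13 * .mass_H + .mass_N + 5 * .mass_O # 203.079373
.res_dhex <- 6 * .mass_C + 10 * .mass_H + 4 * .mass_O         # 146.057909
.res_neu5ac <- 11 * .mass_C + 17 * .mass_H + .mass_N + 8 * .mass_O # 291.095417
.res_neu5gc <- .res_neu5ac + .mass_O                          # 307.090331

#' Residue and constant masses used by the mass calculator
#'
#' Returns the monoisotopic residue masses (Da) for the composition symbols
#' `H` (hexose), `N` (HexNAc), `F` (deoxyhexose/fucose), `E` (ethyl-esterified
#' alpha-2,6 Neu5Ac), `L` (lactonized alpha-2,3 Neu5Ac), `Ge` (ethyl-esterified
#' alpha-2,6 Neu5Gc) and `Gl` (lactonized alpha-2,3 Neu5Gc), together with the
#' O-acetyl modification mass (`Ac`), the mass of water, the electron-corrected
#' sodium-cation adduct mass, and the heavy-label mass added by borodeuteride
#' reduction of the reducing end (one H plus one D).
#'
#' @return A tibble with columns `symbol`, `mass` and `role`
#'   (`"residue"`, `"modification"` or `"constant"`).
#' @examples
#' monosaccharide_masses()
#' @export
monosaccharide_masses <- function() {
  tibble::tibble(
    symbol = c("H", "N", "F", "E", "L", "Ge", "Gl",
               "Ac", "water", "sodium", "heavy_label"),
    mass = c(.res_hex, .res_hexnac, .res_dhex,
             .res_neu5ac + .mass_c2h4,   # E: ethyl ester
             .res_neu5ac - .mass_water,  # L: lactone
             .res_neu5gc + .mass_c2h4,   # Ge
             .res_neu5gc - .mass_water,  # Gl
             .mass_acetyl,
             .mass_water,
             .mass_Na - .mass_e,
             .mass_H + .mass_D),
    role = c(rep("residue", 7), "modification", rep("constant", 3))
  )
}

.residue_masses <- function() {
  m <- monosaccharide_masses()
  stats::setNames(m$mass, m$symbol)
}

# instrument acquisition window (m/z), reflectron positive mode
.mz_window <- c(700, 3500)
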