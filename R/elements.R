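# Periodic-table data used for bond perception and metal stripping.
#
# Covalent radii in Angstrom (single-bond values; for elements with spin-state
# dependent radii the low-spin value is used). The `strip` flag marks elements
# removed by strip_metal_atoms(): all metals plus the metalloids Ge, As, Sb,
# Te, Po. B and Si are deliberately NOT stripped — both occur as covalent
# centers of ordinary organic ligands (boronic acids, silanes), whereas the
# stripping rule targets coordination-complex metal cores.

element_table <- local({
  def <- function(symbol, radius, strip) {
    data.frame(symbol = symbol, radius = radius, strip = strip,
               stringsAsFactors = FALSE)
  }
  organic <- def(
    c("H", "He", "B", "C", "N", "O", "F", "Ne", "Si", "P", "S", "Cl",
      "Ar", "Se", "Br", "Kr", "I", "Xe"),
    c(0.31, 0.28, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58, 1.11, 1.07, 1.05, 1.02,
      1.06, 1.20, 1.20, 1.16, 1.39, 1.40),
    FALSE)
  metals <- def(
    c("Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
      "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Rb", "Sr", "Y", "Zr",
      "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te",
      "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho",
      "Er", "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
      "Tl", "Pb", "Bi", "Po", "Th", "U"),
    c(1.28, 0.96, 1.66, 1.41, 1.21, 2.03, 1.76, 1.70, 1.60, 1.53, 1.39, 1.39,
      1.32, 1.26, 1.24, 1.32, 1.22, 1.22, 1.20, 1.19, 2.20, 1.95, 1.90, 1.75,
      1.64, 1.54, 1.47, 1.46, 1.42, 1.39, 1.45, 1.44, 1.42, 1.39, 1.39, 1.38,
      2.44, 2.15, 2.07, 2.04, 2.03, 2.01, 1.98, 1.98, 1.96, 1.94, 1.92, 1.92,
      1.89, 1.87, 1.87, 1.75, 1.70, 1.62, 1.51, 1.44, 1.41, 1.36, 1.36, 1.32,
      1.45, 1.46, 1.48, 1.40, 2.06, 1.96),
    TRUE)
  rbind(organic, metals)
})

covalent_radius <- function(element) {
  r <- element_table$radius[match(element, element_table$symbol)]
  # unknown elements get a permissive generic radius
  r[is.na(r)] <- 1.5
  r
}

is_strippable_metal <- function(element) {
  element %in% element_table$symbol[element_table$strip]
}
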