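# Monoisotopic mass data: mass of the most naturally abundant isotope of
# each element, in Da (NIST atomic mass data snapshot).  The table is
# versioned so that trained models can refuse feature vectors built from a
# different snapshot.

.ISOTOPE_TABLE_VERSION <- "nist-2018.1"

.ISOTOPE_MASSES <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Li = 7.01600455,
  B  = 11.0093054,
  F  = 18.99840322,
  Na = 22.9897692809,
  Mg = 23.9850417,
  Al = 26.98153863,
  Si = 27.9769265325,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Ti = 47.9479463,
  V  = 50.9439595,
  Cr = 51.9405075,
  Mn = 54.9380451,
  Fe = 55.9349375,
  Co = 58.9331950,
  Ni = 57.9353429,
  Cu = 62.9295975,
  Zn = 63.9291422,
  Ga = 68.9255736,
  Ge = 73.9211778,
  As = 74.9215965,
  Se = 79.9165213,
  Br = 78.9183371,
  Rb = 84.911789738,
  Sr = 87.9056121,
  Zr = 89.9047044,
  Mo = 97.9054082,
  Ag = 106.905097,
  Cd = 113.9033585,
  Sn = 119.9021947,
  Sb = 120.9038157,
  Te = 129.9062244,
  I  = 126.904473,
  Cs = 132.905451933,
  Ba = 137.9052472,
  W  = 183.9509312,
  Pt = 194.9647911,
  Au = 196.9665687,
  Hg = 201.970643,
  Pb = 207.9766521,
  Bi = 208.9803987
)

# Full periodic-table symbol set used for parser validation.  A symbol may be
# parseable but absent from the mass table; mass lookup then errors.
.PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' Monoisotopic isotope mass table
#'
#' Returns the bundled table of most-abundant-isotope masses (Da), one entry
#' per element symbol.  The table carries a `version` attribute; feature
#' vectors record the version they were built with and trained models refuse
#' mismatched versions.
#'
#' @param version Requested table version; only the bundled snapshot is
#'   available.
#' @return Named numeric vector of isotope masses in Da, with a `version`
#'   attribute.
#' @examples
#' t <- isotopeMassTable()
#' t[["O"]]
#' @export
isotopeMassTable <- function(version = .ISOTOPE_TABLE_VERSION) {
  if (!identical(version, .ISOTOPE_TABLE_VERSION)) {
    stop("unknown isotope mass table version: ", version,
         " (bundled: ", .ISOTOPE_TABLE_VERSION, ")")
  }
  structure(.ISOTOPE_MASSES, version = .ISOTOPE_TABLE_VERSION)
}

.tableVersion <- function(table) {
  v <- attr(table, "version")
  if (is.null(v)) "unversioned" else v
}
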