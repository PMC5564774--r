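# Element property tables used by the descriptor engine.
# Masses: IUPAC standard atomic weights rounded to 2 decimals.
# Zv: valence electron count; Z: atomic number; L: principal quantum number.
# default valence: used to assign implicit hydrogens on neutral atoms.

.ELEMENTS <- data.frame(
  symbol  = c("H",  "B",   "C",   "N",   "O",   "F",   "Si",  "P",   "S",   "Cl",  "Br",  "I"),
  mass    = c(1.01, 10.81, 12.01, 14.01, 16.00, 19.00, 28.09, 30.97, 32.07, 35.45, 79.90, 126.90),
  Z       = c(1,    5,     6,     7,     8,     9,     14,    15,    16,    17,    35,    53),
  Zv      = c(1,    3,     4,     5,     6,     7,     4,     5,     6,     7,     7,     7),
  L       = c(1,    2,     2,     2,     2,     2,     3,     3,     3,     3,     4,     5),
  valence = c(1,    3,     4,     3,     2,     1,     4,     3,     2,     1,     1,     1),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

# Covalent radii (Angstrom) by element and hybridisation, relative to sp3
# carbon (0.77) for the Kier alpha correction of the kappa shape indices.
.COV_RADII <- list(
  C  = c(sp3 = 0.77, sp2 = 0.67, sp = 0.60),
  N  = c(sp3 = 0.74, sp2 = 0.62, sp = 0.55),
  O  = c(sp3 = 0.74, sp2 = 0.62, sp = 0.62),
  F  = c(sp3 = 0.72, sp2 = 0.72, sp = 0.72),
  Cl = c(sp3 = 0.99, sp2 = 0.99, sp = 0.99),
  Br = c(sp3 = 1.14, sp2 = 1.14, sp = 1.14),
  I  = c(sp3 = 1.33, sp2 = 1.33, sp = 1.33),
  P  = c(sp3 = 1.10, sp2 = 1.00, sp = 1.00),
  S  = c(sp3 = 1.04, sp2 = 0.94, sp = 0.94),
  Si = c(sp3 = 1.17, sp2 = 1.17, sp = 1.17),
  B  = c(sp3 = 0.88, sp2 = 0.88, sp = 0.88)
)

.element_info <- function(symbol) {
  sym <- as.character(symbol)
  bad <- !(sym %in% rownames(.ELEMENTS))
  if (any(bad)) {
    stop("unsupported element symbol: ", paste(unique(sym[bad]), collapse = ", "),
         call. = FALSE)
  }
  .ELEMENTS[sym, , drop = FALSE]
}

# Effective valence for implicit-H assignment, adjusted for formal charge.
# Cationic N/O/S/P gain a bond; anions lose one per unit charge.
.effective_valence <- function(element, charge) {
  v <- .element_info(element)$valence
  ifelse(charge > 0 & element %in% c("N", "O", "S", "P"), v + charge,
         ifelse(charge < 0, pmax(0L, v + charge), v))
}
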