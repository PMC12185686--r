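# Element data used by the molecular core.
#
# Average atomic masses (2021 IUPAC standard weights, conventional values).
# The dummy/link atom "*" has mass zero so synthon masses are additive.

.ELEMENT_MASS <- c(
  "*" = 0,
  H  = 1.008,   He = 4.003,
  Li = 6.94,    Be = 9.012,  B  = 10.81,  C  = 12.011, N  = 14.007,
  O  = 15.999,  F  = 18.998, Ne = 20.180,
  Na = 22.990,  Mg = 24.305, Al = 26.982, Si = 28.085, P  = 30.974,
  S  = 32.06,   Cl = 35.45,  Ar = 39.95,
  K  = 39.098,  Ca = 40.078, Sc = 44.956, Ti = 47.867, V  = 50.942,
  Cr = 51.996,  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546,  Zn = 65.38,  Ga = 69.723, Ge = 72.630, As = 74.922,
  Se = 78.971,  Br = 79.904, Kr = 83.798,
  Rb = 85.468,  Sr = 87.62,  Y  = 88.906, Zr = 91.224, Nb = 92.906,
  Mo = 95.95,   Ru = 101.07, Rh = 102.91, Pd = 106.42, Ag = 107.87,
  Cd = 112.41,  In = 114.82, Sn = 118.71, Sb = 121.76, Te = 127.60,
  I  = 126.90,  Xe = 131.29,
  Cs = 132.91,  Ba = 137.33, W  = 183.84, Pt = 195.08, Au = 196.97,
  Hg = 200.59,  Pb = 207.2,  Bi = 208.98
)

.ELEMENT_NUMBER <- c(
  "*" = 0, H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
  F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16,
  Cl = 17, Ar = 18, K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24,
  Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31,
  Ge = 32, As = 33, Se = 34, Br = 35, Kr = 36, Rb = 37, Sr = 38,
  Y = 39, Zr = 40, Nb = 41, Mo = 42, Ru = 44, Rh = 45, Pd = 46,
  Ag = 47, Cd = 48, In = 49, Sn = 50, Sb = 51, Te = 52, I = 53,
  Xe = 54, Cs = 55, Ba = 56, W = 74, Pt = 78, Au = 79, Hg = 80,
  Pb = 82, Bi = 83
)

# Metals whose carbon bonds flag a building block as organometallic.
# Boron, silicon and tin are deliberately absent: boronic acids must survive
# standardization (Suzuki-type transforms consume them), and Si/Sn reagents
# are treated as main-group organics. The set is a configuration default.
.DEFAULT_METAL_SET <- c(
  "Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba", "Al",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu",
  "Y", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd",
  "W", "Pt", "Au", "Hg", "Pb", "Bi", "Ga", "In"
)

# Default SMILES organic-subset valences, used for implicit-hydrogen
# assignment on atoms written without brackets.
.ORGANIC_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

#' Default allowed-valence table
#'
#' The organic valence-state model used by [check_valence()]: a data frame of
#' allowed (element, charge, total bond order) triples, loosely following the
#' NAOMI valence model for neutral organic chemistry. A carbon with total
#' order 5 or an uncharged nitrogen with total order 4 is absent, so such
#' atoms fail the check. Users may pass an extended table to
#' [check_valence()].
#'
#' @return A data frame with columns `element`, `charge`, `order`.
#' @export
#' @examples
#' head(default_valence_table())
default_valence_table <- function() {
  tab <- rbind(
    data.frame(element = "H",  charge = 0L,  order = 1L),
    data.frame(element = "B",  charge = 0L,  order = 3L),
    data.frame(element = "B",  charge = -1L, order = 4L),
    data.frame(element = "C",  charge = 0L,  order = c(2L, 3L, 4L)),
    data.frame(element = "N",  charge = 0L,  order = c(1L, 2L, 3L)),
    data.frame(element = "N",  charge = 1L,  order = 4L),
    data.frame(element = "N",  charge = -1L, order = 2L),
    data.frame(element = "O",  charge = 0L,  order = c(1L, 2L)),
    data.frame(element = "O",  charge = -1L, order = 1L),
    data.frame(element = "O",  charge = 1L,  order = 3L),
    data.frame(element = "P",  charge = 0L,  order = c(3L, 5L)),
    data.frame(element = "S",  charge = 0L,  order = c(1L, 2L, 4L, 6L)),
    data.frame(element = "S",  charge = 1L,  order = 3L),
    data.frame(element = "Se", charge = 0L,  order = 2L),
    data.frame(element = "Si", charge = 0L,  order = 4L),
    data.frame(element = "F",  charge = 0L,  order = 1L),
    data.frame(element = "Cl", charge = 0L,  order = 1L),
    data.frame(element = "Br", charge = 0L,  order = 1L),
    data.frame(element = "I",  charge = 0L,  order = 1L),
    data.frame(element = "*",  charge = 0L,  order = c(1L, 2L, 3L, 4L))
  )
  rownames(tab) <- NULL
  tab
}

element_mass <- function(element) {
  m <- .ELEMENT_MASS[element]
  if (anyNA(m)) {
    stop("no mass tabulated for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

element_number <- function(element) {
  n <- .ELEMENT_NUMBER[element]
  ifelse(is.na(n), -1L, unname(n))
}

is_metal <- function(element, metal_set = .DEFAULT_METAL_SET) {
  element %in% metal_set
}

is_heteroatom <- function(element) {
  !(element %in% c("C", "H", "*"))
}
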