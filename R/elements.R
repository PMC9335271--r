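#' Chemical element registry
#'
#' The registry of valid element symbols together with their modern (IUPAC
#' conventional) atomic weights `W(e)`, in unified atomic mass units. Weights
#' drive the atomic-weight node ranks of similarity networks and the
#' rescaling of formulae to historical weight systems, where all ratios are
#' taken relative to hydrogen.
#'
#' @return `element_registry()` returns a `data.frame` with columns `symbol`
#'   and `weight`; `element_weights()` the same information as a named numeric
#'   vector; `is_element_symbol()` a logical vector.
#' @examples
#' element_weights()[c("H", "O", "Fe")]
#' is_element_symbol(c("Fe", "Xx"))
#' @export
element_registry <- function() {
  .element_registry
}

.element_registry <- local({
  sym <- c("H","He","Li","Be","B","C","N","O","F","Ne",
           "Na","Mg","Al","Si","P","S","Cl","Ar","K","Ca",
           "Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn",
           "Ga","Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr",
           "Nb","Mo","Tc","Ru","Rh","Pd","Ag","Cd","In","Sn",
           "Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd",
           "Pm","Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb",
           "Lu","Hf","Ta","W","Re","Os","Ir","Pt","Au","Hg",
           "Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th",
           "Pa","U")
  wt <- c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
          22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.95, 39.098, 40.078,
          44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
          69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
          92.906, 95.95, 98, 101.07, 102.91, 106.42, 107.87, 112.41, 114.82, 118.71,
          121.76, 127.60, 126.90, 131.29, 132.91, 137.33, 138.91, 140.12, 140.91, 144.24,
          145, 150.36, 151.96, 157.25, 158.93, 162.50, 164.93, 167.26, 168.93, 173.05,
          174.97, 178.49, 180.95, 183.84, 186.21, 190.23, 192.22, 195.08, 196.97, 200.59,
          204.38, 207.2, 208.98, 209, 210, 222, 223, 226, 227, 232.04,
          231.04, 238.03)
  data.frame(symbol = sym, weight = wt, stringsAsFactors = FALSE)
})

#' @rdname element_registry
#' @export
element_weights <- function() {
  w <- .element_registry$weight
  names(w) <- .element_registry$symbol
  w
}

#' @rdname element_registry
#' @param symbol character vector of candidate symbols.
#' @export
is_element_symbol <- function(symbol) {
  symbol %in% .element_registry$symbol
}
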