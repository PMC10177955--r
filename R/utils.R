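# Shared small helpers.

# Element symbols accepted in XYZ files (periodic table through Og).
PERIODIC_TABLE <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
  "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am",
  "Cm", "Bk", "Cf", "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg",
  "Bh", "Hs", "Mt", "Ds", "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Atom labels from element symbols
#'
#' Builds the `H1, H2, C1, ...` naming convention used throughout:
#' element symbol plus 1-based per-element ordinal in file order.
#'
#' @param elements character vector of element symbols in atom order.
#' @return character vector of unique atom labels, same length.
#' @examples
#' atom_labels(c("C", "H", "H", "H"))
#' @export
atom_labels <- function(elements) {
  ord <- integer(length(elements))
  for (el in unique(elements)) {
    idx <- which(elements == el)
    ord[idx] <- seq_along(idx)
  }
  paste0(elements, ord)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Stable small integer hash of a string (for per-fit seed derivation);
# result in [0, 2^20).
label_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 1048576L
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
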