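# Monoisotopic atomic masses (u), CODATA/IUPAC values.  "D" (deuterium) and
# "C13" are carried as distinct symbols so isotope-labelled internal standards
# can be described explicitly.
.ELEMENT_MASSES <- c(
  C   = 12.0,
  H   = 1.0078250319,
  N   = 14.0030740052,
  O   = 15.9949146221,
  P   = 30.97376151,
  S   = 31.97207069,
  Na  = 22.98976928,
  Cl  = 34.96885271,
  D   = 2.0141017780,
  C13 = 13.0033548378
)

.PROTON_MASS <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990946

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector of atom counts
#' (e.g. `c(C = 42, H = 82, N = 1, O = 8, P = 1)`).  All counts must be
#' non-negative and every symbol must be a supported element.
#'
#' @param ... named integer atom counts, or a single named vector.
#' @return a named integer vector of class `elemental_composition`.
#' @examples
#' elemental_composition(C = 42, H = 82, N = 1, O = 8, P = 1)
#' @export
elemental_composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1L]]))) {
    x <- args[[1L]]
  } else {
    x <- unlist(args)
  }
  if (length(x) == 0L) {
    out <- integer(0)
    class(out) <- "elemental_composition"
    return(out)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("all atom counts must be named by element symbol")
  }
  bad <- setdiff(names(x), names(.ELEMENT_MASSES))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(x < 0) || any(x != round(x))) stop("atom counts must be non-negative integers")
  out <- tapply(as.integer(x), names(x), sum)
  out <- out[out > 0]
  out <- out[order(names(out))]
  storage.mode(out) <- "integer"
  out <- stats::setNames(as.integer(out), names(out))
  class(out) <- "elemental_composition"
  out
}

# composition arithmetic: add/subtract atom count vectors
comp_add <- function(a, b) {
  syms <- union(names(a), names(b))
  va <- stats::setNames(integer(length(syms)), syms)
  va[names(a)] <- va[names(a)] + as.integer(a)
  va[names(b)] <- va[names(b)] + as.integer(b)
  if (any(va < 0)) stop("composition arithmetic produced negative atom counts")
  elemental_composition(va[va > 0])
}

comp_subtract <- function(a, b) {
  nb <- stats::setNames(-as.integer(b), names(b))
  syms <- union(names(a), names(nb))
  va <- stats::setNames(integer(length(syms)), syms)
  va[names(a)] <- va[names(a)] + as.integer(a)
  va[names(nb)] <- va[names(nb)] + nb
  if (any(va < 0)) stop("composition arithmetic produced negative atom counts")
  elemental_composition(va[va > 0])
}

#' Format an elemental composition as a Hill-order formula string
#' @param x an `elemental_composition`.
#' @param ... ignored.
#' @export
format.elemental_composition <- function(x, ...) {
  if (length(x) == 0L) return("")
  syms <- names(x)
  ord <- c(intersect(c("C", "C13", "H", "D"), syms),
           sort(setdiff(syms, c("C", "C13", "H", "D"))))
  paste0(ord, ifelse(x[ord] == 1L, "", x[ord]), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition> ", format(x),
      sprintf("  (%.4f Da)\n", monoisotopic_mass(x)), sep = "")
  invisible(x)
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums per-element monoisotopic masses.  The empty composition has mass 0.
#'
#' @param composition named integer atom counts (see [elemental_composition()]).
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(elemental_composition(C = 42, H = 82, N = 1, O = 8, P = 1))
#' @export
monoisotopic_mass <- function(composition) {
  if (length(composition) == 0L) return(0)
  bad <- setdiff(names(composition), names(.ELEMENT_MASSES))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  sum(as.numeric(composition) * .ELEMENT_MASSES[names(composition)])
}

# Supported singly charged ESI adducts.  delta is the m/z shift relative to
# the neutral monoisotopic mass (electron mass included).
.ADDUCT_TABLE <- data.frame(
  adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+Cl]-"),
  charge = c(1L, 1L, 1L, -1L, -1L),
  delta  = c(
    .PROTON_MASS,
    14.0030740052 + 4 * 1.0078250319 - .ELECTRON_MASS,
    22.98976928 - .ELECTRON_MASS,
    -.PROTON_MASS,
    34.96885271 + .ELECTRON_MASS
  ),
  stringsAsFactors = FALSE
)

#' Supported adducts
#' @return data frame with columns `adduct`, `charge`, `delta` (m/z shift, Da).
#' @export
adduct_table <- function() .ADDUCT_TABLE

#' Adduct m/z from a neutral monoisotopic mass
#'
#' @param neutral_mass neutral monoisotopic mass in Da.
#' @param adduct one of `"[M+H]+"`, `"[M+NH4]+"`, `"[M+Na]+"`, `"[M-H]-"`,
#'   `"[M+Cl]-"` (all singly charged).
#' @return m/z in Th.
#' @examples
#' adduct_mz(759.5778, "[M+H]+")
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  i <- match(adduct, .ADDUCT_TABLE$adduct)
  if (anyNA(i)) {
    stop("unsupported adduct: ", paste(adduct[is.na(i)], collapse = ", "))
  }
  (neutral_mass + .ADDUCT_TABLE$delta[i]) / abs(.ADDUCT_TABLE$charge[i])
}
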