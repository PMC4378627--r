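# Monoisotopic atomic masses (Da), IUPAC 2021 values, >= 6 decimals.
.ATOMIC_MASS <- c(
  C = 12.000000,
  H = 1.007825,
  N = 14.003074,
  O = 15.994915,
  P = 30.973762,
  S = 31.972071
)

# mass of a proton (H minus one electron), for charged adducts
.PROTON_MASS <- 1.007276

.ELEMENTS <- names(.ATOMIC_MASS)

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector over the elements
#' C, H, N, O, P, S with non-negative counts. It is the unit of all
#' mass arithmetic in the package.
#'
#' @param C,H,N,O,P,S non-negative integer element counts.
#' @return An object of class `elemental_formula`.
#' @examples
#' elemental_formula(H = 2, O = 1)  # water
#' @export
elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0) {
  counts <- c(C = C, H = H, N = N, O = O, P = P, S = S)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(counts), names = .ELEMENTS,
            class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  nz <- x[x > 0]
  if (length(nz) == 0) {
    cat("<empty formula>\n")
  } else {
    cat(paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = ""), "\n")
  }
  invisible(x)
}

#' Add two elemental formulas
#' @param f1,f2 `elemental_formula` objects.
#' @return Their elementwise sum, an `elemental_formula`.
#' @export
formula_add <- function(f1, f2) {
  structure(as.integer(unclass(f1) + unclass(f2)), names = .ELEMENTS,
            class = "elemental_formula")
}

#' Subtract one elemental formula from another
#'
#' Subtraction that would drive any element count below zero is an error:
#' formulas describe real molecules, not bookkeeping deficits.
#' @param f1,f2 `elemental_formula` objects; `f2` is removed from `f1`.
#' @return An `elemental_formula`.
#' @export
formula_subtract <- function(f1, f2) {
  res <- unclass(f1) - unclass(f2)
  if (any(res < 0)) {
    stop("formula subtraction yields a negative element count", call. = FALSE)
  }
  structure(as.integer(res), names = .ELEMENTS, class = "elemental_formula")
}

#' Scale a formula by a non-negative integer
#' @param f an `elemental_formula`.
#' @param k non-negative integer multiplier.
#' @return An `elemental_formula`.
#' @export
formula_multiply <- function(f, k) {
  stopifnot(length(k) == 1, k >= 0, k == round(k))
  structure(as.integer(unclass(f) * k), names = .ELEMENTS,
            class = "elemental_formula")
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum over elements of count times the monoisotopic atomic mass. The empty
#' formula has mass 0.
#'
#' @param formula an `elemental_formula`.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(elemental_formula(H = 2, O = 1))  # 18.01056
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(inherits(formula, "elemental_formula"))
  sum(unclass(formula) * .ATOMIC_MASS)
}

#' Relative mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values; `theoretical_mz` must be
#'   positive.
#' @return `|observed - theoretical| / theoretical * 1e6`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  abs(observed_mz - theoretical_mz) / theoretical_mz * 1e6
}
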