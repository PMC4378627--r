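# Lipid classes, species, adducts and the annotation library.
#
# A lipid species is a class plus total acyl carbons : double bonds
# (e.g. "DGDG 36:6"); isomeric compounds sharing that triple are isobaric
# and quantified as one unit.

# Head-group elemental deltas relative to the bare glycerolipid skeleton
# (glycerol + acyl chains - n_acyl H2O). Validated once against external
# mass references (e.g. PC 34:2 -> C42H80NO8P, 757.562155 Da). Data, not code.
.LIPID_CLASSES <- data.frame(
  class    = c("PC", "PE", "PS", "PG", "MGDG", "DGDG", "SQDG", "DAG", "TAG"),
  category = c("phospholipid", "phospholipid", "phospholipid", "phospholipid",
               "glycolipid", "glycolipid", "glycolipid", "neutral", "neutral"),
  n_acyl   = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 3L),
  stringsAsFactors = FALSE
)

.HEADGROUP_DELTA <- list(
  PC   = c(C = 5, H = 12, N = 1, O = 3, P = 1, S = 0),
  PE   = c(C = 2, H = 6, N = 1, O = 3, P = 1, S = 0),
  PS   = c(C = 3, H = 6, N = 1, O = 5, P = 1, S = 0),
  PG   = c(C = 3, H = 7, N = 0, O = 5, P = 1, S = 0),
  MGDG = c(C = 6, H = 10, N = 0, O = 5, P = 0, S = 0),
  DGDG = c(C = 12, H = 20, N = 0, O = 10, P = 0, S = 0),
  SQDG = c(C = 6, H = 10, N = 0, O = 7, P = 0, S = 1),
  DAG  = c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0),
  TAG  = c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
)

# Singly charged adducts of the positive-mode, ammonium-acetate-buffered
# platform. mass_shift is the signed m/z shift from the neutral species.
.ADDUCTS <- data.frame(
  name = c("+H", "+NH4", "-H"),
  mass_shift = c(1.007276, 18.033826, -1.007276),
  charge = c(1L, 1L, -1L),
  stringsAsFactors = FALSE
)

# Default adduct per class: ammoniated for neutral and glycolipids,
# protonated for phospholipids (overridable in any library file).
.DEFAULT_ADDUCT <- c(
  PC = "+H", PE = "+H", PS = "+H", PG = "+H",
  MGDG = "+NH4", DGDG = "+NH4", SQDG = "+NH4", DAG = "+NH4", TAG = "+NH4"
)

#' Lipid class definitions
#'
#' The nine quantified glycerolipid classes: the phospholipids PC, PE, PS,
#' PG, the glycolipids MGDG, DGDG, SQDG, and the neutral lipids DAG and TAG.
#'
#' @return A data.frame with columns `class`, `category` and `n_acyl`
#'   (number of acyl chains: 3 for TAG, 2 otherwise).
#' @export
lipid_classes <- function() .LIPID_CLASSES

#' Known adducts
#' @return A data.frame with columns `name`, `mass_shift` (Da) and `charge`.
#' @export
adducts <- function() .ADDUCTS

.class_info <- function(class) {
  i <- match(class, .LIPID_CLASSES$class)
  if (any(is.na(i))) {
    stop("unknown lipid class: ",
         paste(unique(class[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .LIPID_CLASSES[i, , drop = FALSE]
}

.adduct_info <- function(name) {
  i <- match(name, .ADDUCTS$name)
  if (any(is.na(i))) {
    stop("unknown adduct: ", paste(unique(name[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  .ADDUCTS[i, , drop = FALSE]
}

#' Construct a lipid species
#'
#' @param class one of the nine class names (see [lipid_classes()]).
#' @param acyl_carbons total carbons in all acyl chains.
#' @param double_bonds total double bonds in all acyl chains.
#' @return An object of class `lipid_species`.
#' @examples
#' lipid_species("DGDG", 36, 6)
#' @export
lipid_species <- function(class, acyl_carbons, double_bonds) {
  info <- .class_info(class)
  if (acyl_carbons < info$n_acyl * 2) {
    stop("acyl_carbons must be >= ", info$n_acyl * 2, " for ", class,
         call. = FALSE)
  }
  if (double_bonds < 0) stop("double_bonds must be >= 0", call. = FALSE)
  structure(
    list(class = class, acyl_carbons = as.integer(acyl_carbons),
         double_bonds = as.integer(double_bonds), n_acyl = info$n_acyl),
    class = "lipid_species"
  )
}

#' Canonical species name, e.g. "DGDG 36:6"
#' @param species a `lipid_species`, or vectors via `class`/`acyl_carbons`/
#'   `double_bonds` columns with [species_name_vec()].
#' @return Character scalar.
#' @export
species_name <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  sprintf("%s %d:%d", species$class, species$acyl_carbons,
          species$double_bonds)
}

# vectorized variant for table columns
species_name_vec <- function(class, acyl_carbons, double_bonds) {
  sprintf("%s %d:%d", class, as.integer(acyl_carbons),
          as.integer(double_bonds))
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(species_name(x), "\n")
  invisible(x)
}

#' Elemental formula of a lipid species
#'
#' Glycerol (C3H8O3) plus the summed acyl-chain composition (a chain c:d
#' contributes C_c H_(2c-2d) O2), minus one water per ester bond, plus the
#' class head-group delta (zero for DAG and TAG).
#'
#' @param species a `lipid_species`.
#' @return An `elemental_formula`.
#' @examples
#' species_formula(lipid_species("DAG", 4, 0))  # C7H12O5
#' @export
species_formula <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  n <- species$n_acyl
  ac <- species$acyl_carbons
  db <- species$double_bonds
  h_acyl <- 2L * ac - 2L * db
  if (h_acyl < 0) {
    stop("double bonds inconsistent with acyl carbon count", call. = FALSE)
  }
  glycerol <- elemental_formula(C = 3, H = 8, O = 3)
  chains <- elemental_formula(C = ac, H = h_acyl, O = 2L * n)
  water <- elemental_formula(H = 2, O = 1)
  delta <- do.call(elemental_formula, as.list(.HEADGROUP_DELTA[[species$class]]))
  formula_add(
    formula_subtract(formula_add(glycerol, chains), formula_multiply(water, n)),
    delta
  )
}

#' Theoretical m/z of a species under a singly charged adduct
#'
#' @param species a `lipid_species`.
#' @param adduct adduct name (`"+H"`, `"+NH4"`, `"-H"`).
#' @return m/z = neutral monoisotopic mass + adduct mass shift.
#' @export
theoretical_mz <- function(species, adduct) {
  ai <- .adduct_info(adduct)
  if (abs(ai$charge) != 1) {
    stop("only singly charged adducts are supported", call. = FALSE)
  }
  monoisotopic_mass(species_formula(species)) + ai$mass_shift
}

#' Build an annotation library table
#'
#' One row per (species, adduct) with its theoretical m/z, a reference
#' retention time, and a per-entry RT tolerance. RT tolerances outside the
#' 0.05-0.2 min window are rejected.
#'
#' @param class,acyl_carbons,double_bonds parallel vectors defining species.
#' @param reference_rt_min reference retention times (min).
#' @param rt_tolerance_min per-entry RT tolerance (min), in [0.05, 0.2].
#' @param adduct adduct names; defaults to the per-class platform default.
#' @param theoretical_mz optional explicit m/z values; where given they win
#'   over the computed value.
#' @return A data.frame with columns `species`, `class`, `acyl_carbons`,
#'   `double_bonds`, `adduct`, `theoretical_mz`, `reference_rt_min`,
#'   `rt_tolerance_min`.
#' @export
build_library <- function(class, acyl_carbons, double_bonds,
                          reference_rt_min,
                          rt_tolerance_min = 0.1,
                          adduct = NULL,
                          theoretical_mz = NULL) {
  n <- length(class)
  stopifnot(length(acyl_carbons) == n, length(double_bonds) == n,
            length(reference_rt_min) == n)
  rt_tolerance_min <- rep_len(rt_tolerance_min, n)
  if (any(rt_tolerance_min < 0.05 | rt_tolerance_min > 0.2)) {
    stop("rt_tolerance_min must lie in [0.05, 0.2] min", call. = FALSE)
  }
  if (is.null(adduct)) adduct <- unname(.DEFAULT_ADDUCT[class])
  adduct <- rep_len(adduct, n)
  mz <- vapply(seq_len(n), function(i) {
    theoretical_mz(lipid_species(class[i], acyl_carbons[i], double_bonds[i]),
                   adduct[i])
  }, numeric(1))
  if (!is.null(theoretical_mz)) {
    explicit <- !is.na(theoretical_mz)
    mz[explicit] <- theoretical_mz[explicit]
  }
  if (any(mz <= 0)) stop("theoretical m/z must be positive", call. = FALSE)
  data.frame(
    species = species_name_vec(class, acyl_carbons, double_bonds),
    class = class,
    acyl_carbons = as.integer(acyl_carbons),
    double_bonds = as.integer(double_bonds),
    adduct = adduct,
    theoretical_mz = mz,
    reference_rt_min = reference_rt_min,
    rt_tolerance_min = rt_tolerance_min,
    stringsAsFactors = FALSE
  )
}

.validate_library <- function(library) {
  req <- c("species", "class", "acyl_carbons", "double_bonds", "adduct",
           "theoretical_mz", "reference_rt_min", "rt_tolerance_min")
  missing <- setdiff(req, names(library))
  if (length(missing)) {
    stop("library is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(library) == 0) stop("library is empty", call. = FALSE)
  if (any(library$rt_tolerance_min < 0.05 | library$rt_tolerance_min > 0.2)) {
    stop("library rt_tolerance_min outside [0.05, 0.2] min", call. = FALSE)
  }
  if (any(library$theoretical_mz <= 0)) {
    stop("library theoretical_mz must be positive", call. = FALSE)
  }
  .class_info(library$class)
  invisible(library)
}
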