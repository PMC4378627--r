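# TAG acyl-chain composition from all-ion-fragmentation scans: neutral-loss
# fragments co-eluting with the TAG precursor identify the lost chain.

#' Construct an acyl chain
#' @param carbons chain length (>= 2; even by default).
#' @param double_bonds number of double bonds (>= 0).
#' @param allow_odd allow odd-chain fatty acids, default FALSE.
#' @return An `acyl_chain` object; renders as `"c:d"`.
#' @export
acyl_chain <- function(carbons, double_bonds, allow_odd = FALSE) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (carbons < 2) stop("acyl chain needs >= 2 carbons", call. = FALSE)
  if (!allow_odd && carbons %% 2 != 0) {
    stop("odd-chain fatty acid; pass allow_odd = TRUE to permit",
         call. = FALSE)
  }
  if (double_bonds < 0) stop("double_bonds must be >= 0", call. = FALSE)
  structure(list(carbons = carbons, double_bonds = double_bonds),
            class = "acyl_chain")
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat(chain_name(x), "\n")
  invisible(x)
}

#' Render an acyl chain as "c:d"
#' @param chain an `acyl_chain`.
#' @return Character scalar.
#' @export
chain_name <- function(chain) {
  sprintf("%d:%d", chain$carbons, chain$double_bonds)
}

# free fatty acid formula of a chain c:d -> C_c H_(2c-2d) O2
.fatty_acid_formula <- function(chain) {
  elemental_formula(C = chain$carbons,
                    H = 2L * chain$carbons - 2L * chain$double_bonds,
                    O = 2)
}

#' Candidate acyl triples for a TAG species
#'
#' All unordered triples (multisets) from the chain pool whose total
#' carbons and double bonds match the species.
#'
#' @param species a TAG `lipid_species`.
#' @param chain_pool data.frame with columns `carbons`, `double_bonds`.
#' @return A list of triples; each triple is a list of three `acyl_chain`s
#'   ordered by (carbons, double_bonds).
#' @export
candidate_acyls <- function(species, chain_pool = default_chain_pool()) {
  stopifnot(inherits(species, "lipid_species"))
  if (species$class != "TAG") stop("species must be TAG", call. = FALSE)
  if (nrow(chain_pool) == 0) stop("chain pool is empty", call. = FALSE)
  n <- nrow(chain_pool)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) for (k in j:n) {
    if (chain_pool$carbons[i] + chain_pool$carbons[j] +
        chain_pool$carbons[k] != species$acyl_carbons) next
    if (chain_pool$double_bonds[i] + chain_pool$double_bonds[j] +
        chain_pool$double_bonds[k] != species$double_bonds) next
    out[[length(out) + 1]] <- list(
      acyl_chain(chain_pool$carbons[i], chain_pool$double_bonds[i]),
      acyl_chain(chain_pool$carbons[j], chain_pool$double_bonds[j]),
      acyl_chain(chain_pool$carbons[k], chain_pool$double_bonds[k])
    )
  }
  out
}

#' Neutral-loss fragment m/z for a TAG losing one acyl chain
#'
#' Diacyl fragment of the ammoniated precursor: neutral TAG monoisotopic
#' mass minus the free fatty acid mass of the lost chain, plus a proton.
#'
#' @param tag a TAG `lipid_species`.
#' @param lost_chain the `acyl_chain` lost.
#' @return Fragment m/z (Da).
#' @export
fragment_mz <- function(tag, lost_chain) {
  stopifnot(inherits(tag, "lipid_species"), inherits(lost_chain, "acyl_chain"))
  if (tag$class != "TAG") stop("precursor must be TAG", call. = FALSE)
  if (lost_chain$carbons > tag$acyl_carbons - 4 ||
      lost_chain$double_bonds > tag$double_bonds) {
    stop("lost chain infeasible for this TAG", call. = FALSE)
  }
  monoisotopic_mass(species_formula(tag)) -
    monoisotopic_mass(.fatty_acid_formula(lost_chain)) + .PROTON_MASS
}

#' Assign acyl composition to an annotated TAG from fragment scans
#'
#' A chain is "supported" when some fragment peak matches its neutral-loss
#' m/z within `ppm_tol` and co-elutes with the TAG within `rt_tol`
#' (default +/- 0.01 min). Candidate triples are filtered to those whose
#' every distinct chain is supported; when nothing is supported, all
#' candidates are kept but flagged unconfirmed.
#'
#' @param species a TAG `lipid_species`.
#' @param tag_rt the TAG precursor's RT (min), in the same timeframe as the
#'   scans.
#' @param scans fragment-scan data.frame (`rt_min`, `mz`, `intensity`).
#' @param chain_pool candidate chain pool.
#' @param rt_tol co-elution window (min), default 0.01.
#' @param ppm_tol mass tolerance (ppm), default 10.
#' @return A `tag_composition` list: `species`, `supported` (data.frame of
#'   supported chains with evidence), `triples` (filtered candidate
#'   triples), `confirmed` (logical).
#' @export
assign_composition <- function(species, tag_rt, scans,
                               chain_pool = default_chain_pool(),
                               rt_tol = 0.01, ppm_tol = 10) {
  stopifnot(inherits(species, "lipid_species"), species$class == "TAG",
            is.finite(tag_rt), rt_tol > 0, ppm_tol > 0)
  if (is.null(scans) || nrow(scans) == 0) {
    stop("fragment scans are empty", call. = FALSE)
  }
  cands <- candidate_acyls(species, chain_pool)
  # distinct chains appearing in any candidate triple
  chains <- unique(do.call(rbind, lapply(cands, function(tr) {
    do.call(rbind, lapply(tr, function(ch)
      data.frame(carbons = ch$carbons, double_bonds = ch$double_bonds)))
  })))
  supported <- list()
  if (!is.null(chains) && nrow(chains)) {
    near <- abs(scans$rt_min - tag_rt) <= rt_tol
    for (r in seq_len(nrow(chains))) {
      ch <- acyl_chain(chains$carbons[r], chains$double_bonds[r])
      fmz <- fragment_mz(species, ch)
      hit <- near & (abs(scans$mz - fmz) / fmz * 1e6 <= ppm_tol)
      if (any(hit)) {
        best <- which(hit)[which.max(scans$intensity[hit])]
        supported[[length(supported) + 1]] <- data.frame(
          chain = chain_name(ch), carbons = ch$carbons,
          double_bonds = ch$double_bonds,
          fragment_mz = fmz, observed_mz = scans$mz[best],
          rt_delta = scans$rt_min[best] - tag_rt,
          intensity = scans$intensity[best]
        )
      }
    }
  }
  supported <- if (length(supported)) do.call(rbind, supported) else
    data.frame(chain = character(0), carbons = integer(0),
               double_bonds = integer(0), fragment_mz = numeric(0),
               observed_mz = numeric(0), rt_delta = numeric(0),
               intensity = numeric(0))
  confirmed <- nrow(supported) > 0
  triples <- if (confirmed) {
    Filter(function(tr) {
      all(vapply(tr, function(ch)
        chain_name(ch) %in% supported$chain, logical(1)))
    }, cands)
  } else cands
  structure(list(species = species_name(species), supported = supported,
                 triples = triples, confirmed = confirmed),
            class = "tag_composition")
}

#' @export
print.tag_composition <- function(x, ...) {
  cat(sprintf("%s: %d supported chains (%s), %d candidate triple(s)\n",
              x$species, nrow(x$supported),
              paste(x$supported$chain, collapse = ", "),
              length(x$triples)))
  invisible(x)
}

# render a triple as "16:0/18:1/18:2"
.triple_name <- function(tr) {
  paste(vapply(tr, chain_name, character(1)), collapse = "/")
}
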