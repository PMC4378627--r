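# Targeted annotation of a detected-peak matrix: marker-based RT
# correction, m/z + RT library matching, and isomer collapse into
# isobaric species.

#' Construct a peak matrix
#'
#' @param peaks data.frame with columns `peak_id`, `rt_min`, `mz`.
#' @param intensities numeric matrix, peaks x samples, non-negative.
#' @param samples data.frame with columns `sample_id`, `organ`, `condition`,
#'   `genotype`, `replicate`.
#' @return A `peak_matrix` object.
#' @export
peak_matrix <- function(peaks, intensities, samples) {
  stopifnot(all(c("peak_id", "rt_min", "mz") %in% names(peaks)),
            is.matrix(intensities),
            nrow(intensities) == nrow(peaks),
            ncol(intensities) == nrow(samples),
            "sample_id" %in% names(samples))
  if (anyDuplicated(peaks$peak_id)) {
    stop("peak ids must be unique", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(peaks = peaks, intensities = intensities,
                 samples = samples),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d peaks x %d samples (RT %.2f-%.2f min)\n",
              nrow(x$peaks), nrow(x$samples),
              min(x$peaks$rt_min), max(x$peaks$rt_min)))
  invisible(x)
}

#' Build a retention-time correction map from markers
#'
#' Piecewise-linear interpolation through the (observed, reference) marker
#' points, with constant-offset extrapolation beyond the terminal markers.
#' Marker peaks map exactly onto their reference RTs.
#'
#' @param markers data.frame with columns `observed_rt` and `reference_rt`;
#'   at least two rows, both columns strictly increasing after sorting by
#'   `observed_rt`.
#' @return A function mapping observed RT (min) to corrected RT (min).
#' @export
rt_map <- function(markers) {
  stopifnot(all(c("observed_rt", "reference_rt") %in% names(markers)))
  if (nrow(markers) < 2) {
    stop("at least 2 RT markers are required", call. = FALSE)
  }
  m <- markers[order(markers$observed_rt), ]
  if (any(diff(m$observed_rt) <= 0) || any(diff(m$reference_rt) <= 0)) {
    stop("markers must be strictly increasing in both observed and ",
         "reference RT", call. = FALSE)
  }
  obs <- m$observed_rt
  ref <- m$reference_rt
  n <- length(obs)
  function(t) {
    out <- stats::approx(obs, ref, xout = t, rule = 1)$y
    lo <- t < obs[1]
    hi <- t > obs[n]
    out[lo] <- t[lo] + (ref[1] - obs[1])
    out[hi] <- t[hi] + (ref[n] - obs[n])
    out
  }
}

#' Marker-based retention-time correction of a peak matrix
#'
#' @param peaks a `peak_matrix`.
#' @param markers marker data.frame, see [rt_map()].
#' @return The `peak_matrix` with corrected `rt_min`; the original values
#'   are kept in a `rt_observed` column.
#' @export
correct_rt <- function(peaks, markers) {
  stopifnot(inherits(peaks, "peak_matrix"))
  f <- rt_map(markers)
  peaks$peaks$rt_observed <- peaks$peaks$rt_min
  peaks$peaks$rt_min <- f(peaks$peaks$rt_min)
  peaks
}

#' Match peaks against an annotation library
#'
#' A peak matches an entry when its ppm error is at most `ppm_tol` and its
#' absolute RT deviation is at most the entry's own tolerance (both bounds
#' inclusive, so the printed 10 ppm and 0.05-0.2 min are meaningful
#' boundaries). A peak annotates at most one species: among competing
#' entries the smallest ppm error wins, ties broken by smallest RT
#' deviation, then by species name. Multiple peaks may annotate the same
#' species (isomers).
#'
#' @param peaks an RT-corrected `peak_matrix`.
#' @param library annotation library data.frame.
#' @param ppm_tol mass tolerance in ppm, default 10.
#' @return data.frame of raw annotations: `peak_id`, `species`, `class`,
#'   `acyl_carbons`, `double_bonds`, `adduct`, `ppm_error`, `rt_deviation`,
#'   `rt_min`.
#' @export
match_library <- function(peaks, library, ppm_tol = 10) {
  stopifnot(inherits(peaks, "peak_matrix"), ppm_tol > 0)
  .validate_library(library)
  p <- peaks$peaks
  out <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    ppm <- ppm_error(p$mz[i], library$theoretical_mz)
    rtdev <- abs(p$rt_min[i] - library$reference_rt_min)
    ok <- ppm <= ppm_tol & rtdev <= library$rt_tolerance_min
    if (!any(ok)) next
    cand <- which(ok)
    ord <- order(ppm[cand], rtdev[cand], library$species[cand])
    j <- cand[ord[1]]
    out[[i]] <- data.frame(
      peak_id = p$peak_id[i], species = library$species[j],
      class = library$class[j], acyl_carbons = library$acyl_carbons[j],
      double_bonds = library$double_bonds[j], adduct = library$adduct[j],
      ppm_error = ppm[j], rt_deviation = rtdev[j], rt_min = p$rt_min[i],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peak_id = character(0), species = character(0),
                      class = character(0), acyl_carbons = integer(0),
                      double_bonds = integer(0), adduct = character(0),
                      ppm_error = numeric(0), rt_deviation = numeric(0),
                      rt_min = numeric(0))
  }
  res
}

#' Collapse isomeric peaks into isobaric species
#'
#' Per species and sample, intensities of all contributing peaks are summed;
#' provenance records every contributing peak with its match metrics.
#'
#' @param peaks the `peak_matrix` the annotations refer to.
#' @param annotations raw annotations from [match_library()].
#' @return An `annotated_matrix`: list with `rows` (species metadata),
#'   `intensities` (species x samples), `samples`, and `provenance`.
#' @export
collapse_isomers <- function(peaks, annotations) {
  stopifnot(inherits(peaks, "peak_matrix"))
  if (nrow(annotations) == 0) {
    stop("no annotations to collapse", call. = FALSE)
  }
  sp <- unique(annotations[, c("species", "class", "acyl_carbons",
                               "double_bonds", "adduct")])
  sp <- sp[order(sp$class, sp$acyl_carbons, sp$double_bonds), ]
  rownames(sp) <- NULL
  idx <- match(annotations$peak_id, peaks$peaks$peak_id)
  if (anyNA(idx)) stop("annotation refers to unknown peak id", call. = FALSE)
  mat <- matrix(0, nrow = nrow(sp), ncol = ncol(peaks$intensities),
                dimnames = list(sp$species, colnames(peaks$intensities)))
  for (r in seq_len(nrow(annotations))) {
    s <- match(annotations$species[r], sp$species)
    mat[s, ] <- mat[s, ] + peaks$intensities[idx[r], ]
  }
  structure(list(rows = sp, intensities = mat, samples = peaks$samples,
                 provenance = annotations),
            class = "annotated_matrix")
}

#' @export
print.annotated_matrix <- function(x, ...) {
  cat(sprintf("annotated_matrix: %d species x %d samples (%d peaks)\n",
              nrow(x$rows), nrow(x$samples), nrow(x$provenance)))
  invisible(x)
}

#' Annotate a peak matrix end to end
#'
#' Convenience wrapper: RT correction (when markers are given), library
#' matching and isomer collapse.
#'
#' @param peaks a `peak_matrix`.
#' @param library annotation library.
#' @param markers optional RT markers; when `NULL` no correction is applied.
#' @param ppm_tol mass tolerance in ppm, default 10.
#' @return An `annotated_matrix`.
#' @export
annotate_peaks <- function(peaks, library = default_library(),
                           markers = NULL, ppm_tol = 10) {
  if (!is.null(markers)) peaks <- correct_rt(peaks, markers)
  ann <- match_library(peaks, library, ppm_tol = ppm_tol)
  collapse_isomers(peaks, ann)
}
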