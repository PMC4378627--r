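# CV-based normalization and the three quantification levels
# (class, acyl-carbon group, species), composition percentages and fold
# changes.

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean.
#'
#' @param values numeric vector of at least 2 values with positive mean.
#' @return CV as a fraction.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be positive", call. = FALSE)
  stats::sd(values) / m
}

# row-wise CVs of a matrix; rows with non-positive mean come back NA
.row_cv <- function(mat) {
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  cv <- s / m
  cv[m <= 0] <- NA_real_
  cv
}

# core of the normalization: given a compounds x samples matrix of raw
# intensities and a logical mask of rows eligible for the factor
# (non-TAG, positive mean), select the half with CV at or below the median
# CV, sum their per-sample intensities, rescale the factor to mean 1
.normalization_factors <- function(mat, eligible) {
  if (sum(eligible) < 2) {
    stop("need >= 2 eligible (non-TAG) compounds for normalization",
         call. = FALSE)
  }
  cv <- .row_cv(mat)
  zero_mean <- eligible & is.na(cv)
  if (any(zero_mean)) {
    warning(sum(zero_mean),
            " compound(s) with zero mean excluded from the normalizer set")
    eligible <- eligible & !is.na(cv)
  }
  med <- stats::median(cv[eligible])
  selected <- eligible & cv <= med  # ties at the median included
  raw <- colSums(mat[selected, , drop = FALSE])
  if (any(raw <= 0)) stop("zero normalization factor", call. = FALSE)
  factors <- raw / mean(raw)
  list(factors = factors, selected = which(selected), cv = cv,
       median_cv = med)
}

#' CV-based normalization of an annotated matrix
#'
#' The coefficient of variation is computed from raw intensities for each
#' compound; the compounds with the 50% lower variation, excluding TAGs,
#' form the normalizer set. The per-sample factor is the sum of the selected
#' compounds' intensities, rescaled to mean 1; every compound is divided by
#' its sample's factor.
#'
#' By default the factor is computed from the annotated species themselves.
#' Supplying `factor_peaks` (a `peak_matrix`, typically the full detected-
#' peak matrix the annotation came from) computes the factor from all
#' detected compounds instead — excluding peaks annotated as TAG — which is
#' the appropriate choice when most identified lipids are condition-
#' responsive and the stable background anchors the factor.
#'
#' @param matrix an `annotated_matrix`.
#' @param factor_peaks optional `peak_matrix` used for factor computation.
#' @return A `normalized_matrix`: the annotated matrix with normalized
#'   intensities plus `factors`, `normalizer` (selected row indices /
#'   peak ids) and `median_cv`.
#' @export
normalize_intensities <- function(matrix, factor_peaks = NULL) {
  stopifnot(inherits(matrix, "annotated_matrix"))
  if (is.null(factor_peaks)) {
    eligible <- matrix$rows$class != "TAG"
    nf <- .normalization_factors(matrix$intensities, eligible)
    normalizer <- matrix$rows$species[nf$selected]
  } else {
    stopifnot(inherits(factor_peaks, "peak_matrix"))
    if (!identical(colnames(factor_peaks$intensities),
                   colnames(matrix$intensities))) {
      stop("factor_peaks samples do not match the annotated matrix",
           call. = FALSE)
    }
    tag_peaks <- matrix$provenance$peak_id[matrix$provenance$class == "TAG"]
    eligible <- !(factor_peaks$peaks$peak_id %in% tag_peaks)
    nf <- .normalization_factors(factor_peaks$intensities, eligible)
    normalizer <- factor_peaks$peaks$peak_id[nf$selected]
  }
  out <- matrix
  out$intensities <- sweep(matrix$intensities, 2, nf$factors, "/")
  out$factors <- nf$factors
  out$normalizer <- normalizer
  out$median_cv <- nf$median_cv
  class(out) <- c("normalized_matrix", "annotated_matrix")
  out
}

#' Aggregate an annotated/normalized matrix to a quantification level
#'
#' Class level sums all species of a class; the acyl-carbon group level
#' sums species of a class sharing the same total acyl carbons; the species
#' level is the identity. The hierarchy is exactly additive.
#'
#' @param matrix an `annotated_matrix` (normalized or not).
#' @param level `"class"`, `"acyl_group"` or `"species"`.
#' @return An `aggregated_table`: list with `level`, `keys` (data.frame)
#'   and `values` (keys x samples matrix), plus `samples`.
#' @export
aggregate_lipids <- function(matrix,
                             level = c("class", "acyl_group", "species")) {
  stopifnot(inherits(matrix, "annotated_matrix"))
  level <- match.arg(level)
  rows <- matrix$rows
  key <- switch(level,
    class = rows$class,
    acyl_group = paste(rows$class, rows$acyl_carbons),
    species = rows$species
  )
  uk <- unique(key)
  vals <- matrix(0, nrow = length(uk), ncol = ncol(matrix$intensities),
                 dimnames = list(uk, colnames(matrix$intensities)))
  for (i in seq_along(key)) {
    vals[key[i], ] <- vals[key[i], ] + matrix$intensities[i, ]
  }
  keys <- switch(level,
    class = data.frame(key = uk, class = uk),
    acyl_group = {
      cls <- rows$class[match(uk, key)]
      ac <- rows$acyl_carbons[match(uk, key)]
      data.frame(key = uk, class = cls, acyl_carbons = ac)
    },
    species = data.frame(key = uk, class = rows$class[match(uk, key)],
                         acyl_carbons = rows$acyl_carbons[match(uk, key)],
                         double_bonds = rows$double_bonds[match(uk, key)])
  )
  structure(list(level = level, keys = keys, values = vals,
                 samples = matrix$samples),
            class = "aggregated_table")
}

#' @export
print.aggregated_table <- function(x, ...) {
  cat(sprintf("aggregated_table (%s level): %d keys x %d samples\n",
              x$level, nrow(x$keys), ncol(x$values)))
  invisible(x)
}

#' Percentage composition of each class
#'
#' For a table at the acyl-group or species level: per class and sample,
#' 100 x value / class total. Percentages sum to 100 within a class.
#'
#' @param table an `aggregated_table` at `acyl_group` or `species` level.
#' @return A data.frame `key`, `class`, one percentage column per sample.
#' @export
class_composition <- function(table) {
  stopifnot(inherits(table, "aggregated_table"))
  if (table$level == "class") {
    stop("composition needs the acyl_group or species level", call. = FALSE)
  }
  cls <- table$keys$class
  totals <- rowsum(table$values, cls)
  if (any(totals <= 0)) stop("zero class total", call. = FALSE)
  pct <- 100 * table$values / totals[match(cls, rownames(totals)), ,
                                     drop = FALSE]
  cbind(table$keys[, c("key", "class")], as.data.frame(pct))
}

#' Median fold change between two sample groups
#'
#' @param table an `aggregated_table`.
#' @param key a row key (e.g. `"DGDG"`, `"TAG 52"`, `"DGDG 36:6"`).
#' @param group_a,group_b logical or integer sample selectors (numerator A,
#'   denominator B).
#' @param stat `"median"` (default, matching the reported median bars) or
#'   `"mean"`.
#' @return `stat(A) / stat(B)`.
#' @export
fold_change <- function(table, key, group_a, group_b,
                        stat = c("median", "mean")) {
  stopifnot(inherits(table, "aggregated_table"))
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  i <- match(key, rownames(table$values))
  if (is.na(i)) stop("unknown key: ", key, call. = FALSE)
  a <- table$values[i, group_a]
  b <- table$values[i, group_b]
  if (length(a) < 1 || length(b) < 1) {
    stop("both groups need >= 1 sample", call. = FALSE)
  }
  denom <- f(b)
  if (denom <= 0) stop("non-positive denominator", call. = FALSE)
  f(a) / denom
}

#' Condition fold change (P-starved over P-replete)
#'
#' @param table an `aggregated_table` whose samples carry `condition` (and
#'   optionally `genotype`) metadata.
#' @param key row key.
#' @param genotype genotype to restrict to, default `"WT"`.
#' @param stat passed to [fold_change()].
#' @return Median (or mean) -P / +P ratio.
#' @export
condition_fold <- function(table, key, genotype = "WT",
                           stat = c("median", "mean")) {
  s <- table$samples
  sel_g <- if ("genotype" %in% names(s)) s$genotype == genotype else TRUE
  fold_change(table, key,
              group_a = sel_g & s$condition == "P_starved",
              group_b = sel_g & s$condition == "P_replete",
              stat = match.arg(stat))
}
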