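# Group statistics: ANOVA, pairwise Welch t-tests with compact letter
# displays, and qPCR 40-minus-delta-CT expression with fold inductions.

#' Fixed-effects ANOVA of a response over one or two factors
#'
#' Two-way ANOVA (with interaction) when two factors are given, one-way
#' otherwise. When all observations are equal the decomposition is
#' degenerate; p-values are reported as 1 with `degenerate = TRUE`.
#'
#' @param values numeric response.
#' @param factors data.frame (or list) of 1 or 2 factor columns, each with
#'   at least 2 levels and at least 2 replicates per cell.
#' @return A data.frame with columns `term`, `df`, `F`, `p`, and an
#'   attribute `degenerate`.
#' @export
lipid_anova <- function(values, factors) {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (ncol(factors) < 1 || ncol(factors) > 2) {
    stop("one or two factors required", call. = FALSE)
  }
  for (nm in names(factors)) {
    factors[[nm]] <- factor(factors[[nm]])
    if (nlevels(factors[[nm]]) < 2) {
      stop("factor ", nm, " has fewer than 2 levels", call. = FALSE)
    }
  }
  cells <- table(factors)
  if (any(cells == 0)) stop("empty design cells", call. = FALSE)
  if (any(cells < 2)) stop("need >= 2 replicates per cell", call. = FALSE)
  dat <- cbind(data.frame(.y = values), factors)
  fml <- stats::as.formula(paste(".y ~", paste(names(factors),
                                               collapse = " * ")))
  if (stats::var(values) == 0) {
    terms <- attr(stats::terms(fml), "term.labels")
    out <- data.frame(term = terms, df = NA_integer_, F = NA_real_, p = 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::lm(fml, data = dat)
  tab <- stats::anova(fit)
  keep <- rownames(tab) != "Residuals"
  out <- data.frame(term = rownames(tab)[keep], df = tab$Df[keep],
                    F = tab$`F value`[keep], p = tab$`Pr(>F)`[keep])
  attr(out, "degenerate") <- FALSE
  out
}

#' Pairwise Welch t-tests
#'
#' Two-sided Welch tests for every unordered pair of groups; no multiplicity
#' correction by default (set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 values per group).
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return A symmetric p-value matrix with 1 on the diagonal.
#' @export
pairwise_ttests <- function(values, groups, adjust = "none") {
  groups <- as.character(groups)
  lev <- unique(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 values", call. = FALSE)
  k <- length(lev)
  p <- matrix(1, k, k, dimnames = list(lev, lev))
  ps <- c(); is <- c(); js <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- values[groups == lev[i]]
    b <- values[groups == lev[j]]
    pv <- if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = FALSE)$p.value
    }
    ps <- c(ps, pv); is <- c(is, i); js <- c(js, j)
  }
  ps <- stats::p.adjust(ps, method = adjust)
  for (q in seq_along(ps)) {
    p[is[q], js[q]] <- ps[q]
    p[js[q], is[q]] <- ps[q]
  }
  p
}

#' Compact letter display from a pairwise p-value table
#'
#' Insert-and-absorb algorithm: groups are processed in a fixed order
#' (descending group mean when `means` is given, otherwise table order) and
#' letters maintained so that two groups share a letter exactly when their
#' pairwise p-value is at or above `alpha`.
#'
#' @param p_table symmetric p-value matrix with group names.
#' @param alpha significance level, default 0.05.
#' @param means optional named group means fixing the processing order.
#' @return Named character vector of letter strings, one per group.
#' @export
letter_groups <- function(p_table, alpha = 0.05, means = NULL) {
  stopifnot(is.matrix(p_table), nrow(p_table) == ncol(p_table))
  groups <- rownames(p_table)
  ord <- if (!is.null(means)) {
    groups[order(-means[groups])]
  } else groups
  # letter sets: list of character vectors of group names; invariant: two
  # groups share a set iff no significant difference separates them
  sets <- list(ord)
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      g1 <- ord[i]; g2 <- ord[j]
      if (p_table[g1, g2] >= alpha) next
      # significant pair: split every set containing both
      s <- 1
      while (s <= length(sets)) {
        if (g1 %in% sets[[s]] && g2 %in% sets[[s]]) {
          a <- setdiff(sets[[s]], g2)
          b <- setdiff(sets[[s]], g1)
          sets[[s]] <- a
          sets[[length(sets) + 1]] <- b
        }
        s <- s + 1
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(sets))
      for (u in seq_along(sets)) for (v in seq_along(sets)) {
        if (u != v && keep[u] && keep[v] &&
            all(sets[[u]] %in% sets[[v]]) &&
            !(all(sets[[v]] %in% sets[[u]]) && u < v)) {
          keep[u] <- FALSE
        }
      }
      sets <- sets[keep]
    }
  }
  # order sets by first occurrence in the processing order, assign a, b, c..
  first <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(first)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) {
      letters_out[g] <- paste0(letters_out[g], letters[s])
    }
  }
  if (any(letters_out == "")) {
    # isolated groups (significant against everything) still need a letter
    for (g in names(letters_out)[letters_out == ""]) {
      letters_out[g] <- letters[length(sets) + 1]
      sets[[length(sets) + 1]] <- g
    }
  }
  letters_out
}

#' Group comparison: pairwise tests plus compact letters
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha significance level, default 0.05.
#' @param adjust p-adjustment method for the pairwise tests.
#' @return A list with `p_table`, `letters`, `means`, `alpha`.
#' @export
group_comparison <- function(values, groups, alpha = 0.05, adjust = "none") {
  p <- pairwise_ttests(values, groups, adjust = adjust)
  means <- tapply(values, as.character(groups), mean)
  list(p_table = p,
       letters = letter_groups(p, alpha = alpha, means = means),
       means = means, alpha = alpha)
}

#' qPCR expression as 40 minus delta-CT
#'
#' Per sample and gene, `40 - (CT_gene - CT_ref)`; technical replicates of
#' the same (sample, gene) are averaged at the CT level first. 40 is the
#' cycle cap of a run, so a target detected as late as the reference scores
#' 40.
#'
#' @param ct_table data.frame with columns `sample`, `gene`, `CT` (extra
#'   metadata columns such as `condition` are carried through).
#' @param reference_gene reference transcript, default `"UBQ10"`.
#' @return A data.frame `sample`, (metadata), `gene`, `expression`.
#' @export
qpcr_expression <- function(ct_table, reference_gene = "UBQ10") {
  req <- c("sample", "gene", "CT")
  if (!all(req %in% names(ct_table))) {
    stop("ct_table needs columns sample, gene, CT", call. = FALSE)
  }
  meta_cols <- setdiff(names(ct_table), c("gene", "CT"))
  # average technical replicates at the CT level
  agg <- stats::aggregate(CT ~ sample + gene, data = ct_table, FUN = mean)
  refs <- agg[agg$gene == reference_gene, ]
  if (nrow(refs) == 0) {
    stop("reference gene ", reference_gene, " not measured", call. = FALSE)
  }
  targets <- agg[agg$gene != reference_gene, ]
  ref_ct <- stats::setNames(refs$CT, refs$sample)
  if (any(!targets$sample %in% names(ref_ct))) {
    stop("reference gene missing for sample(s): ",
         paste(setdiff(unique(targets$sample), names(ref_ct)),
               collapse = ", "), call. = FALSE)
  }
  targets$expression <- 40 - (targets$CT - ref_ct[targets$sample])
  meta <- unique(ct_table[, meta_cols, drop = FALSE])
  out <- merge(targets[, c("sample", "gene", "expression")], meta,
               by = "sample", sort = FALSE)
  out[order(out$gene, out$sample), c("sample",
                                     setdiff(meta_cols, "sample"),
                                     "gene", "expression")]
}

#' Fold induction from 40 minus delta-CT values
#'
#' `2 ^ (mean expression in A - mean expression in B)`: a difference of one
#' 40-delta-CT unit is a 2-fold change.
#'
#' @param expression data.frame from [qpcr_expression()].
#' @param gene gene to evaluate.
#' @param group_a,group_b logical selectors over the expression rows
#'   (numerator A, denominator B).
#' @return Fold induction of A over B.
#' @export
fold_induction <- function(expression, gene, group_a, group_b) {
  e <- expression[expression$gene == gene, , drop = FALSE]
  ga <- group_a[expression$gene == gene]
  gb <- group_b[expression$gene == gene]
  a <- e$expression[ga]
  b <- e$expression[gb]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be measured for ", gene, call. = FALSE)
  }
  2^(mean(a) - mean(b))
}
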