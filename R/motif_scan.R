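# P1BS (PHR1-binding site) scanning: the degenerate 8-mer GNATATNC, located
# within gene-model features (promoter = 1 kb upstream of the 5' UTR).

#' Find P1BS motif instances in a sequence
#'
#' Reports every 0-based start position where the 8-mer matches
#' G, any, A, T, A, T, any, C on the given (sense) strand. Overlapping
#' matches are all reported. The ambiguity code N in the subject never
#' matches, including at the two wildcard positions. The motif is its own
#' reverse complement, so a sense-strand scan covers both strands.
#'
#' @param sequence character scalar over A/C/G/T/N (case-insensitive).
#' @return Integer vector of 0-based start positions (empty for sequences
#'   shorter than 8).
#' @export
find_p1bs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) {
    stop("sequence must be over A/C/G/T/N", call. = FALSE)
  }
  if (nchar(s) < 8) return(integer(0))
  # lookahead regex so overlapping instances are all found
  m <- gregexpr("(?=G[ACGT]ATAT[ACGT]C)", s, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Validate a gene model feature table
#'
#' @param model data.frame with columns `gene`, `feature`, `start`, `end`
#'   (0-based half-open, sense strand); features must not overlap within a
#'   gene and promoters must be at most 1000 bases.
#' @return The model, invisibly; errors on violations.
#' @export
validate_gene_model <- function(model) {
  req <- c("gene", "feature", "start", "end")
  if (!all(req %in% names(model))) {
    stop("gene model needs columns gene, feature, start, end", call. = FALSE)
  }
  if (any(model$end <= model$start)) {
    stop("features must have end > start", call. = FALSE)
  }
  prom <- model$feature == "promoter"
  if (any(model$end[prom] - model$start[prom] > 1000)) {
    stop("promoter longer than 1000 bases", call. = FALSE)
  }
  for (g in unique(model$gene)) {
    f <- model[model$gene == g, ]
    f <- f[order(f$start), ]
    if (any(f$start[-1] < f$end[-nrow(f)])) {
      stop("overlapping features in gene ", g, call. = FALSE)
    }
  }
  invisible(model)
}

#' Locate motif hits within gene-model features
#'
#' Each hit is labeled by the feature containing its start coordinate;
#' hits whose 8-mer spans a feature boundary keep the start-containing
#' feature and are flagged.
#'
#' @param hits integer vector of 0-based hit starts (from [find_p1bs()]).
#' @param model single-gene feature table (see [validate_gene_model()]).
#' @param sequence optional sequence, to report the matched 8-mer.
#' @return data.frame `gene`, `start`, `feature`, `spans_boundary`,
#'   `matched` (NA when no sequence given).
#' @export
locate_hits <- function(hits, model, sequence = NULL) {
  validate_gene_model(model)
  gene <- unique(model$gene)
  if (length(gene) != 1) {
    stop("locate_hits expects a single gene's model", call. = FALSE)
  }
  span <- c(min(model$start), max(model$end))
  if (length(hits) == 0) {
    return(data.frame(gene = character(0), start = integer(0),
                      feature = character(0), spans_boundary = logical(0),
                      matched = character(0)))
  }
  if (any(hits < span[1] | hits + 8 > span[2])) {
    stop("hit outside the gene-model span", call. = FALSE)
  }
  feature <- character(length(hits))
  spans <- logical(length(hits))
  for (i in seq_along(hits)) {
    j <- which(model$start <= hits[i] & hits[i] < model$end)
    if (length(j) != 1) {
      stop("hit at ", hits[i], " not contained in any feature", call. = FALSE)
    }
    feature[i] <- model$feature[j]
    spans[i] <- hits[i] + 8 > model$end[j]
  }
  matched <- if (!is.null(sequence)) {
    substring(toupper(sequence), hits + 1, hits + 8)
  } else NA_character_
  data.frame(gene = gene, start = as.integer(hits), feature = feature,
             spans_boundary = spans, matched = matched,
             stringsAsFactors = FALSE)
}

#' Scan a set of gene sequences for P1BS sites and localize them
#'
#' @param sequences named character vector of gene sequences.
#' @param models combined feature table for all genes.
#' @return data.frame of located hits over all genes.
#' @export
scan_genes <- function(sequences, models) {
  out <- lapply(names(sequences), function(g) {
    locate_hits(find_p1bs(sequences[[g]]),
                models[models$gene == g, , drop = FALSE],
                sequence = sequences[[g]])
  })
  do.call(rbind, out)
}
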