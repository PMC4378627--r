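# Shared fixtures, built in code at test time.

# a minimal 2-condition wild-type design
tiny_design <- function(organ = "root", replicates = 3) {
  study_design(organ, replicates = replicates)
}

# one noiseless generated dataset (decoys kept: they must never annotate)
noiseless_dataset <- function(organ = "root", replicates = 3, seed = 7,
                              ...) {
  generate_peak_matrix(tiny_design(organ, replicates),
                       remodeling_profile(organ),
                       default_library(),
                       noiseless_config(seed = seed, ...))
}

# brute-force CLD invariant check: two groups share a letter iff their
# pairwise p-value is >= alpha
cld_invariant_holds <- function(letters_vec, p_table, alpha) {
  gs <- names(letters_vec)
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (i >= j) next
    shared <- length(intersect(strsplit(letters_vec[[gs[i]]], "")[[1]],
                               strsplit(letters_vec[[gs[j]]], "")[[1]])) > 0
    if (shared != (p_table[gs[i], gs[j]] >= alpha)) return(FALSE)
  }
  TRUE
}

# independent sliding-window P1BS oracle (no regex)
p1bs_oracle <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n < 8) return(integer(0))
  hits <- integer(0)
  for (i in 1:(n - 7)) {
    w <- s[i:(i + 7)]
    if (w[1] == "G" && w[3] == "A" && w[4] == "T" && w[5] == "A" &&
        w[6] == "T" && w[8] == "C" &&
        w[2] %in% c("A", "C", "G", "T") && w[7] %in% c("A", "C", "G", "T")) {
      hits <- c(hits, i - 1L)
    }
  }
  hits
}

# independent brute-force TAG triple oracle: all ordered triples, then
# canonicalized to unordered multisets
triple_oracle <- function(carbons, dbs, pool) {
  out <- character(0)
  n <- nrow(pool)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (pool$carbons[i] + pool$carbons[j] + pool$carbons[k] != carbons) next
    if (pool$double_bonds[i] + pool$double_bonds[j] +
        pool$double_bonds[k] != dbs) next
    tr <- sort(sprintf("%02d:%d.%d", pool$carbons[c(i, j, k)],
                       pool$double_bonds[c(i, j, k)],
                       pool$double_bonds[c(i, j, k)]))
    out <- c(out, paste(tr, collapse = "|"))
  }
  sort(unique(out))
}

# canonical string form of candidate_acyls output, comparable to the oracle
triples_as_strings <- function(triples) {
  sort(unique(vapply(triples, function(tr) {
    s <- sort(vapply(tr, function(ch)
      sprintf("%02d:%d.%d", ch$carbons, ch$double_bonds, ch$double_bonds),
      character(1)))
    paste(s, collapse = "|")
  }, character(1))))
}
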