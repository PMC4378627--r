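# ANOVA, pairwise Welch tests, compact letter display, qPCR expression.

test_that("one-factor ANOVA with two groups equals the pooled t-test", {
  set.seed(1)
  y <- c(rnorm(6, 10), rnorm(6, 11))
  g <- rep(c("A", "B"), each = 6)
  a <- lipid_anova(y, data.frame(group = g))
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("two-factor ANOVA returns main effects and interaction", {
  set.seed(2)
  d <- expand.grid(geno = c("WT", "phr1"), cond = c("plus", "minus"),
                   rep = 1:4)
  y <- rnorm(nrow(d)) + 2 * (d$cond == "minus") +
    1 * (d$cond == "minus") * (d$geno == "WT")
  a <- lipid_anova(y, d[, c("geno", "cond")])
  expect_setequal(a$term, c("geno", "cond", "geno:cond"))
  expect_lt(a$p[a$term == "cond"], 0.01)
  # a cell reduced to one replicate is rejected
  keep <- !(d$geno == "WT" & d$cond == "plus" & d$rep > 1)
  expect_error(lipid_anova(y[keep], d[keep, c("geno", "cond")]),
               "replicates")
})

test_that("degenerate all-equal data is flagged, not an error", {
  a <- lipid_anova(rep(5, 8), data.frame(g = rep(c("A", "B"), each = 4)))
  expect_true(attr(a, "degenerate"))
  expect_equal(a$p, 1)
})

test_that("pairwise_ttests is symmetric with unit diagonal and detects
           separated groups", {
  set.seed(3)
  y <- c(rnorm(6, 0), rnorm(6, 0.2), rnorm(6, 5))
  g <- rep(c("a", "b", "c"), each = 6)
  p <- pairwise_ttests(y, g)
  expect_equal(p, t(p))
  expect_equal(unname(diag(p)), rep(1, 3))
  expect_lt(p["a", "c"], 0.001)
  # identical constant groups compare at p = 1
  p2 <- pairwise_ttests(rep(c(1, 1, 2, 2), 2),
                        rep(c("x", "y"), each = 4))
  expect_error(pairwise_ttests(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})

test_that("power: N(0,1) vs N(5,1) at n = 6 is significant in >= 99% of
           seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    p <- pairwise_ttests(c(rnorm(6, 0), rnorm(6, 5)),
                         rep(c("A", "B"), each = 6))
    p["A", "B"] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("letter displays match the known small cases", {
  mk <- function(vals, groups) {
    p <- matrix(1, length(groups), length(groups),
                dimnames = list(groups, groups))
    for (v in vals) p[v[[1]], v[[2]]] <- p[v[[2]], v[[1]]] <- v[[3]]
    p
  }
  g3 <- c("g1", "g2", "g3")
  # all non-significant -> single letter
  expect_equal(unname(letter_groups(mk(list(), g3))), rep("a", 3))
  # all significant -> a, b, c
  p_all <- mk(list(list("g1", "g2", 0.01), list("g1", "g3", 0.01),
                   list("g2", "g3", 0.01)), g3)
  expect_setequal(unname(letter_groups(p_all)), c("a", "b", "c"))
  # only (1,3) significant -> a / ab / b
  p13 <- mk(list(list("g1", "g3", 0.01)), g3)
  l <- letter_groups(p13, means = c(g1 = 3, g2 = 2, g3 = 1))
  expect_identical(unname(l[c("g1", "g2", "g3")]), c("a", "ab", "b"))
})

test_that("CLD invariant holds by brute force on random p-tables", {
  set.seed(10)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    gs <- paste0("g", 1:k)
    p <- matrix(1, k, k, dimnames = list(gs, gs))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      p[i, j] <- p[j, i] <- sample(c(0.001, 0.2), 1)
    }
    l <- letter_groups(p, alpha = 0.05)
    expect_true(cld_invariant_holds(l, p, 0.05))
    expect_true(all(nchar(l) >= 1))
  }
})

test_that("group_comparison on generated class data satisfies the CLD
           invariant", {
  gen <- generate_peak_matrix(
    study_design("root", genotypes = c("WT", "phr1"), replicates = 4),
    remodeling_profile("root"), default_library(),
    generator_config(seed = 77))
  res <- run_lipid_pipeline(gen$peaks, markers = gen$truth$markers)
  s <- res$tables$class$samples
  grp <- paste(s$condition, s$genotype, sep = ".")
  for (k in c("DGDG", "TAG", "PC")) {
    gc <- group_comparison(res$tables$class$values[k, ], grp)
    expect_true(cld_invariant_holds(gc$letters, gc$p_table, gc$alpha))
  }
})

test_that("40-minus-delta-CT arithmetic and technical averaging", {
  ct <- data.frame(sample = c("s1", "s1", "s2", "s2"),
                   condition = "P_replete",
                   gene = c("UBQ10", "NPC4", "UBQ10", "NPC4"),
                   CT = c(20, 20, 20, 25))
  e <- qpcr_expression(ct)
  expect_equal(e$expression, c(40, 35))  # equal CTs score the 40 cap
  # technical replicates are averaged at the CT level first
  ct2 <- rbind(ct, data.frame(sample = "s1", condition = "P_replete",
                              gene = "NPC4", CT = 22))
  e2 <- qpcr_expression(ct2)
  expect_equal(e2$expression[e2$sample == "s1"], 40 - (21 - 20))
  expect_error(qpcr_expression(ct[ct$gene != "UBQ10", ]), "reference")
})

test_that("fold induction is exponential in the expression difference and
           antisymmetric", {
  e <- data.frame(sample = paste0("s", 1:4),
                  condition = rep(c("A", "B"), each = 2),
                  gene = "G",
                  expression = c(33.0875, 33.0875, 30, 30))
  f <- fold_induction(e, "G", e$condition == "A", e$condition == "B")
  expect_equal(f, 8.5, tolerance = 0.01)  # 2^3.0875
  expect_equal(fold_induction(e, "G", e$condition == "B",
                              e$condition == "A"), 1 / f)
  expect_equal(fold_induction(e, "G", e$condition == "A",
                              e$condition == "A"), 1)
})

test_that("type-I error under the simulator null is calibrated", {
  # null CT data (fold 1 everywhere): t-test on 40-dCT at alpha 0.05.
  # 200 seeded repetitions (reduced from the 1000-rep design for runtime).
  rejections <- vapply(1:200, function(s) {
    ct <- generate_ct_table(c(G = 1), replicates = 4, seed = s)
    e <- qpcr_expression(ct)
    p <- pairwise_ttests(e$expression, e$condition)
    p["P_replete", "P_starved"] < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.09)
})
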