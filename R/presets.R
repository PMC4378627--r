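# Packaged default library and the "remodeling-profile" presets: the transcribed
# class-level fold changes, composition weights, genotype modifiers and gene
# inductions that define the synthetic stated world. Reference RTs are
# synthetic (the platform's compound library is not public) but consistent
# between library and simulator.

.DEFAULT_SPECIES <- local({
  x <- rbind(
    data.frame(class = "PC",
               acyl_carbons = c(34, 34, 34, 36, 36, 36, 36, 36),
               double_bonds = c(1, 2, 3, 1, 2, 3, 4, 5),
               reference_rt_min = c(7.3, 7.0, 6.6, 8.5, 8.2, 7.9, 7.6, 7.3)),
    data.frame(class = "PE",
               acyl_carbons = c(34, 34, 34, 36, 36, 36, 36),
               double_bonds = c(1, 2, 3, 2, 3, 4, 5),
               reference_rt_min = c(7.1, 6.8, 6.45, 8.0, 7.7, 7.4, 7.15)),
    data.frame(class = "PS",
               acyl_carbons = c(34, 34, 36, 36, 42, 42),
               double_bonds = c(2, 3, 2, 4, 2, 3),
               reference_rt_min = c(7.2, 6.9, 8.3, 7.75, 10.5, 10.2)),
    data.frame(class = "PG",
               acyl_carbons = c(32, 34, 34, 34, 36, 36),
               double_bonds = c(1, 1, 2, 3, 2, 4),
               reference_rt_min = c(6.0, 6.75, 6.5, 6.2, 7.45, 7.1)),
    data.frame(class = "MGDG",
               acyl_carbons = c(34, 34, 34, 36, 36, 36),
               double_bonds = c(3, 4, 6, 4, 5, 6),
               reference_rt_min = c(8.6, 8.45, 7.9, 8.75, 8.3, 8.1)),
    data.frame(class = "DGDG",
               acyl_carbons = c(34, 34, 34, 34, 36, 36, 36, 36),
               double_bonds = c(1, 2, 3, 4, 3, 4, 5, 6),
               reference_rt_min = c(8.9, 8.5, 8.2, 8.05, 9.1, 8.8,
                                    8.45, 8.35)),
    data.frame(class = "SQDG",
               acyl_carbons = c(32, 34, 34, 34, 36, 36),
               double_bonds = c(1, 1, 2, 3, 4, 6),
               reference_rt_min = c(5.6, 6.3, 6.1, 5.9, 6.7, 6.45)),
    data.frame(class = "DAG",
               acyl_carbons = c(34, 34, 34, 36, 36, 36),
               double_bonds = c(1, 2, 3, 2, 4, 6),
               reference_rt_min = c(9.7, 9.5, 9.2, 10.0, 9.8, 9.0)),
    data.frame(class = "TAG",
               acyl_carbons = c(50, 50, 50, 52, 52, 52, 54, 54, 54, 54),
               double_bonds = c(1, 2, 3, 2, 3, 4, 3, 5, 6, 7),
               reference_rt_min = c(15.1, 14.8, 14.5, 15.4, 15.15, 14.9,
                                    15.8, 15.3, 15.0, 14.7))
  )
  x
})

#' Packaged default annotation library
#'
#' 39 species across the nine classes with synthetic reference retention
#' times inside the 1-17 min chromatographic window and the platform's
#' default adducts.
#'
#' @param rt_tolerance_min per-entry RT tolerance (min), default 0.1.
#' @return A library data.frame (see [build_library()]).
#' @export
default_library <- function(rt_tolerance_min = 0.1) {
  s <- .DEFAULT_SPECIES
  build_library(s$class, s$acyl_carbons, s$double_bonds,
                s$reference_rt_min, rt_tolerance_min = rt_tolerance_min)
}

# species composition weights per (organ, condition, class); sum to 1 per key
.weights_df <- function(class, carbons, dbs, w_replete, w_starved) {
  stopifnot(abs(sum(w_replete) - 1) < 1e-9, abs(sum(w_starved) - 1) < 1e-9)
  rbind(
    data.frame(class = class, acyl_carbons = carbons, double_bonds = dbs,
               condition = "P_replete", weight = w_replete),
    data.frame(class = class, acyl_carbons = carbons, double_bonds = dbs,
               condition = "P_starved", weight = w_starved)
  )
}

.SHARED_WEIGHTS <- local({
  rbind(
    .weights_df("PC", c(34, 34, 34, 36, 36, 36, 36, 36),
                c(1, 2, 3, 1, 2, 3, 4, 5),
                c(0.10, 0.22, 0.16, 0.06, 0.14, 0.12, 0.12, 0.08),
                c(0.08, 0.17, 0.13, 0.06, 0.16, 0.14, 0.15, 0.11)),
    .weights_df("PE", c(34, 34, 34, 36, 36, 36, 36),
                c(1, 2, 3, 2, 3, 4, 5),
                c(0.12, 0.25, 0.23, 0.12, 0.10, 0.11, 0.07),
                c(0.09, 0.19, 0.17, 0.15, 0.13, 0.16, 0.11)),
    .weights_df("PS", c(34, 34, 36, 36, 42, 42), c(2, 3, 2, 4, 2, 3),
                c(0.28, 0.16, 0.16, 0.14, 0.16, 0.10),
                c(0.22, 0.12, 0.20, 0.18, 0.17, 0.11)),
    .weights_df("PG", c(32, 34, 34, 34, 36, 36), c(1, 1, 2, 3, 2, 4),
                c(0.12, 0.14, 0.24, 0.22, 0.14, 0.14),
                c(0.09, 0.11, 0.19, 0.17, 0.21, 0.23)),
    .weights_df("MGDG", c(34, 34, 34, 36, 36, 36), c(3, 4, 6, 4, 5, 6),
                c(0.14, 0.12, 0.28, 0.10, 0.14, 0.22),
                c(0.10, 0.09, 0.21, 0.14, 0.19, 0.27)),
    .weights_df("SQDG", c(32, 34, 34, 34, 36, 36), c(1, 1, 2, 3, 4, 6),
                c(0.12, 0.14, 0.26, 0.20, 0.16, 0.12),
                c(0.09, 0.11, 0.21, 0.17, 0.23, 0.19)),
    .weights_df("DAG", c(34, 34, 34, 36, 36, 36), c(1, 2, 3, 2, 4, 6),
                c(0.12, 0.22, 0.18, 0.14, 0.20, 0.14),
                c(0.16, 0.27, 0.22, 0.11, 0.15, 0.09))
  )
})

# DGDG composition is strongly organ-specific: in roots the 36:5 + 36:6
# share moves from ~68% (+P) to ~21% (-P); in shoots the 36-C loss is
# milder. TAG 52-C share rises by ~17 (shoot) / ~12 (root) percentage
# points under starvation; 52-C + 54-C stay > 80% of total TAG throughout.
.ORGAN_WEIGHTS <- local({
  root <- rbind(
    .weights_df("DGDG", c(34, 34, 34, 34, 36, 36, 36, 36),
                c(1, 2, 3, 4, 3, 4, 5, 6),
                c(0.04, 0.08, 0.10, 0.03, 0.03, 0.04, 0.34, 0.34),
                c(0.08, 0.26, 0.28, 0.07, 0.04, 0.06, 0.10, 0.11)),
    .weights_df("TAG", c(50, 50, 50, 52, 52, 52, 54, 54, 54, 54),
                c(1, 2, 3, 2, 3, 4, 3, 5, 6, 7),
                c(0.05, 0.04, 0.03, 0.12, 0.13, 0.10, 0.12, 0.15, 0.14, 0.12),
                c(0.05, 0.04, 0.03, 0.16, 0.17, 0.14, 0.09, 0.11, 0.11, 0.10))
  )
  shoot <- rbind(
    .weights_df("DGDG", c(34, 34, 34, 34, 36, 36, 36, 36),
                c(1, 2, 3, 4, 3, 4, 5, 6),
                c(0.03, 0.06, 0.12, 0.04, 0.05, 0.07, 0.30, 0.33),
                c(0.05, 0.14, 0.22, 0.07, 0.05, 0.08, 0.17, 0.22)),
    .weights_df("TAG", c(50, 50, 50, 52, 52, 52, 54, 54, 54, 54),
                c(1, 2, 3, 2, 3, 4, 3, 5, 6, 7),
                c(0.05, 0.04, 0.03, 0.12, 0.13, 0.10, 0.12, 0.15, 0.14, 0.12),
                c(0.05, 0.04, 0.03, 0.17, 0.19, 0.16, 0.08, 0.10, 0.10, 0.08))
  )
  root$organ <- "root"
  shoot$organ <- "shoot"
  rbind(root, shoot)
})

# class-level fold change of the P-starved total relative to P-replete
.CLASS_FOLDS <- data.frame(
  class = c("PC", "PE", "PS", "PG", "MGDG", "DGDG", "SQDG", "DAG", "TAG"),
  shoot = c(0.50, 0.45, 0.50, 0.25, 1.75, 4.0, 10.0, 2.2, 20.0),
  root  = c(0.90, 0.65, 0.95, 1.80, 2.30, 17.0, 8.0, 2.2, 13.0),
  stringsAsFactors = FALSE
)

# per-class base intensity of the P-replete class total (arbitrary units)
.CLASS_BASE <- c(PC = 1e6, PE = 5e5, PS = 1e5, PG = 4e5, MGDG = 2e6,
                 DGDG = 8e5, SQDG = 3e5, DAG = 2e5, TAG = 1.5e5)

# genotype modifier: ratio of the P-starved class level in a mutant to the
# P-starved wild-type level (wild type = 1); P-replete levels are wild-type-
# like for all genotypes in this stated world.
.GENOTYPE_MODIFIER <- local({
  g <- expand.grid(organ = c("shoot", "root"),
                   genotype = c("WT", "phr1", "pho2", "miR399d_OX"),
                   class = .CLASS_FOLDS$class,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$modifier <- 1
  set_mod <- function(g, organ, genotype, class, value) {
    i <- g$organ == organ & g$genotype == genotype & g$class == class
    g$modifier[i] <- value
    g
  }
  root_phr1 <- c(PC = 0.80, PE = 1.00, PS = 1.00, PG = 0.55, MGDG = 0.50,
                 DGDG = 0.35, SQDG = 0.40, DAG = 0.50, TAG = 0.25)
  shoot_phr1 <- c(PC = 1.50, PE = 1.40, PS = 1.30, PG = 1.80, MGDG = 0.60,
                  DGDG = 0.50, SQDG = 0.45, DAG = 1.20, TAG = 1.20)
  for (cl in names(root_phr1)) g <- set_mod(g, "root", "phr1", cl, root_phr1[[cl]])
  for (cl in names(shoot_phr1)) g <- set_mod(g, "shoot", "phr1", cl, shoot_phr1[[cl]])
  g
})

#' remodeling-profile effect preset for one organ
#'
#' The planted synthetic effects: class-level fold changes of the P-starved
#' class total relative to the P-replete total, per-condition species
#' composition weights, base class intensities, and genotype modifiers
#' (ratio of the mutant's P-starved class level to wild type; the
#' P-starved phr1 root retains 25% of wild-type TAG).
#'
#' @param organ `"shoot"` or `"root"`.
#' @return A list of class `effect_profile` with elements `organ`,
#'   `class_fold` (named numeric), `class_base` (named numeric),
#'   `species_weights` (data.frame keyed by class/species/condition) and
#'   `genotype_modifier` (data.frame organ/genotype/class/modifier).
#' @export
remodeling_profile <- function(organ = c("shoot", "root")) {
  organ <- match.arg(organ)
  shared <- .SHARED_WEIGHTS
  shared$organ <- organ
  w <- rbind(shared, .ORGAN_WEIGHTS[.ORGAN_WEIGHTS$organ == organ, ])
  w$species <- species_name_vec(w$class, w$acyl_carbons, w$double_bonds)
  folds <- stats::setNames(.CLASS_FOLDS[[organ]], .CLASS_FOLDS$class)
  effect_profile(organ = organ, class_fold = folds, class_base = .CLASS_BASE,
                 species_weights = w,
                 genotype_modifier =
                   .GENOTYPE_MODIFIER[.GENOTYPE_MODIFIER$organ == organ, ])
}

#' Construct an effect profile
#'
#' @param organ organ label.
#' @param class_fold named numeric, fold change (P-starved / P-replete) per
#'   class; all > 0.
#' @param class_base named numeric, P-replete class totals; all > 0.
#' @param species_weights data.frame with columns `organ`, `class`,
#'   `acyl_carbons`, `double_bonds`, `species`, `condition`, `weight`;
#'   weights sum to 1 within (organ, condition, class).
#' @param genotype_modifier data.frame with columns `organ`, `genotype`,
#'   `class`, `modifier` (> 0).
#' @return An `effect_profile` list.
#' @export
effect_profile <- function(organ, class_fold, class_base, species_weights,
                           genotype_modifier) {
  stopifnot(all(class_fold > 0), all(class_base > 0),
            all(genotype_modifier$modifier > 0))
  sums <- tapply(species_weights$weight,
                 interaction(species_weights$condition, species_weights$class,
                             drop = TRUE),
                 sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("species weights must sum to 1 within (condition, class)",
         call. = FALSE)
  }
  structure(list(organ = organ, class_fold = class_fold,
                 class_base = class_base, species_weights = species_weights,
                 genotype_modifier = genotype_modifier),
            class = "effect_profile")
}

# plant-typical acyl chain pool for TAG composition work
.DEFAULT_CHAIN_POOL <- data.frame(
  carbons = c(16, 16, 16, 16, 18, 18, 18, 18),
  double_bonds = c(0, 1, 2, 3, 0, 1, 2, 3)
)

#' Default plant acyl-chain pool (16:0-16:3, 18:0-18:3)
#' @return A data.frame with columns `carbons` and `double_bonds`.
#' @export
default_chain_pool <- function() .DEFAULT_CHAIN_POOL

# planted TAG acyl triples for the default library's TAG species
.DEFAULT_TAG_TRIPLES <- list(
  "TAG 50:1" = list(c(16, 0), c(16, 0), c(18, 1)),
  "TAG 50:2" = list(c(16, 0), c(16, 1), c(18, 1)),
  "TAG 50:3" = list(c(16, 0), c(16, 1), c(18, 2)),
  "TAG 52:2" = list(c(16, 0), c(18, 1), c(18, 1)),
  "TAG 52:3" = list(c(16, 0), c(18, 1), c(18, 2)),
  "TAG 52:4" = list(c(16, 0), c(18, 2), c(18, 2)),
  "TAG 54:3" = list(c(18, 1), c(18, 1), c(18, 1)),
  "TAG 54:5" = list(c(18, 1), c(18, 2), c(18, 2)),
  "TAG 54:6" = list(c(18, 2), c(18, 2), c(18, 2)),
  "TAG 54:7" = list(c(18, 1), c(18, 3), c(18, 3))
)

# wild-type fold induction (-P / +P) of lipid-remodeling transcripts; the
# phr1 induction is halved in log2 space in the shoot and abolished in the
# root except for four transcripts that stay slightly (< 2-fold) induced.
.GENE_FOLDS <- local({
  genes <- c("NPC4", "NPC5", "PLDZ2", "PAH1", "PAH2", "PLA2A", "GDPD5",
             "GDPD6", "MGD2", "MGD3", "DGD1", "DGD2", "SQD1", "SQD2")
  shoot <- c(8.5, 3, 4, 2.5, 2, 3.5, 4, 6, 5, 6, 1.8, 7, 4, 5)
  root  <- c(2.4, 2, 2.5, 1.8, 1.5, 2.2, 2.5, 3, 3.5, 3, 1.5, 3.5, 2.5, 3)
  data.frame(gene = genes, shoot = shoot, root = root,
             stringsAsFactors = FALSE)
})

#' remodeling-profile qPCR gene-effect preset
#'
#' Fold inductions (P-starved over P-replete) of the lipid-remodeling
#' transcript panel; NPC4 is induced ~8.5-fold in the shoot and ~2.4-fold in
#' the root in the wild type.
#'
#' @param organ `"shoot"` or `"root"`.
#' @param genotype `"WT"` or `"phr1"`.
#' @return Named numeric vector of fold inductions per gene.
#' @export
remodeling_gene_effects <- function(organ = c("shoot", "root"),
                               genotype = c("WT", "phr1")) {
  organ <- match.arg(organ)
  genotype <- match.arg(genotype)
  folds <- stats::setNames(.GENE_FOLDS[[organ]], .GENE_FOLDS$gene)
  if (genotype == "phr1") {
    if (organ == "shoot") {
      folds <- 2^(0.5 * log2(folds))
    } else {
      residual <- c(PLDZ2 = 1.5, PLA2A = 1.5, MGD3 = 1.5, SQD1 = 1.5)
      folds[] <- 1
      folds[names(residual)] <- residual
    }
  }
  folds
}
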