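# Synthetic-data generator: emulates the study's detected-peak matrices,
# all-ion-fragmentation scans, qPCR CT tables and gene sequences with known
# planted ground truth. The pipeline never sees the truth; tests do.

# run code under a local RNG state so generators are deterministic without
# clobbering the caller's stream
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# multiplicative log-normal noise with mean exactly 1 at coefficient of
# variation cv (MS intensities vary multiplicatively)
.lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Construct a study design
#'
#' @param organ `"shoot"` or `"root"` (one organ per dataset; organs were
#'   always analysed separately).
#' @param conditions character, subset of `c("P_replete", "P_starved")`.
#' @param genotypes character, subset of
#'   `c("WT", "phr1", "pho2", "miR399d_OX")`.
#' @param replicates biological replicates per cell, default 6.
#' @return A `study_design` list with a `samples` data.frame.
#' @export
study_design <- function(organ = c("shoot", "root"),
                         conditions = c("P_replete", "P_starved"),
                         genotypes = "WT",
                         replicates = 6) {
  organ <- match.arg(organ)
  conditions <- match.arg(conditions, c("P_replete", "P_starved"),
                          several.ok = TRUE)
  genotypes <- match.arg(genotypes,
                         c("WT", "phr1", "pho2", "miR399d_OX"),
                         several.ok = TRUE)
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  samples <- expand.grid(replicate = seq_len(replicates),
                         genotype = genotypes,
                         condition = conditions,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$organ <- organ
  samples$sample_id <- sprintf("%s_%s_%s_r%d", organ, samples$condition,
                               samples$genotype, samples$replicate)
  samples <- samples[, c("sample_id", "organ", "condition", "genotype",
                         "replicate")]
  structure(list(organ = organ, conditions = conditions,
                 genotypes = genotypes, replicates = replicates,
                 samples = samples),
            class = "study_design")
}

#' Generator configuration
#'
#' @param seed integer RNG seed; a fixed seed gives identical output.
#' @param intensity_cv per-peak multiplicative intensity noise
#'   (coefficient of variation), default 0.15.
#' @param sample_scale_sd per-sample loading-factor noise (log-normal CV),
#'   default 0.10; this is the variation that CV-based normalization removes.
#' @param mz_ppm_sd m/z noise in ppm, default 2.
#' @param rt_jitter_sd per-peak RT jitter (min), default 0.01.
#' @param rt_drift_amplitude amplitude (min) of the smooth monotone RT drift
#'   applied to the whole matrix, default 0.1.
#' @param decoy_peaks number of background peaks not matching any library
#'   entry, default 150.
#' @param housekeeping_compounds number of condition-stable non-lipid peaks
#'   with `intensity_cv / 3` noise that anchor normalization, default 20.
#' @param isomer_species species names split into two RT-separated peaks to
#'   exercise isomer collapsing.
#' @param isomer_share intensity fraction of the first isomer peak.
#' @param fragment_decoys decoy fragments per TAG in fragment scans.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 42,
                             intensity_cv = 0.15,
                             sample_scale_sd = 0.10,
                             mz_ppm_sd = 2,
                             rt_jitter_sd = 0.01,
                             rt_drift_amplitude = 0.1,
                             decoy_peaks = 150,
                             housekeeping_compounds = 20,
                             isomer_species = c("PC 34:2", "DGDG 34:3",
                                                "TAG 52:3"),
                             isomer_share = 0.6,
                             fragment_decoys = 2) {
  stopifnot(intensity_cv >= 0, sample_scale_sd >= 0, mz_ppm_sd >= 0,
            rt_jitter_sd >= 0, rt_drift_amplitude >= 0,
            decoy_peaks >= 0, housekeeping_compounds >= 0,
            isomer_share > 0, isomer_share < 1, fragment_decoys >= 0)
  structure(list(seed = as.integer(seed), intensity_cv = intensity_cv,
                 sample_scale_sd = sample_scale_sd, mz_ppm_sd = mz_ppm_sd,
                 rt_jitter_sd = rt_jitter_sd,
                 rt_drift_amplitude = rt_drift_amplitude,
                 decoy_peaks = as.integer(decoy_peaks),
                 housekeeping_compounds = as.integer(housekeeping_compounds),
                 isomer_species = isomer_species,
                 isomer_share = isomer_share,
                 fragment_decoys = as.integer(fragment_decoys)),
            class = "generator_config")
}

#' A noiseless generator configuration (closed-loop testing)
#' @param seed RNG seed (still used for decoy placement).
#' @param ... overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
noiseless_config <- function(seed = 42, ...) {
  args <- list(seed = seed, intensity_cv = 0, sample_scale_sd = 0,
               mz_ppm_sd = 0, rt_jitter_sd = 0, rt_drift_amplitude = 0)
  utils::modifyList(do.call(generator_config, args), list(...))
}

# chromatographic window of the platform (spectra recorded 1-17 min)
.RT_WINDOW <- c(1, 17)

# default RT landmark compounds with known reference RTs; m/z values sit
# below the glycerolipid mass range so they can never match the library
.DEFAULT_MARKERS <- data.frame(
  marker_id = paste0("M", 1:8),
  reference_rt_min = c(1.5, 3.0, 5.0, 7.0, 9.0, 11.0, 13.0, 16.5),
  mz = c(187.0754, 231.1023, 275.1289, 319.1554, 363.1820, 407.2086,
         451.2351, 495.2617)
)

# smooth monotone drift map applied to consensus RTs; amplitude amp
.make_drift <- function(amp) {
  if (amp <= 0) return(function(t) t)
  a <- stats::runif(1, -amp / 2, amp / 2)
  b <- stats::runif(1, -amp / 2, amp / 2)
  function(t) t + a + b * sin(2 * pi * t / 34)
}

#' Generate a synthetic detected-peak matrix with ground truth
#'
#' Emulates the aligned detected-peak hand-off of the UPLC-MS platform: one
#' row per detected peak (consensus RT, m/z) with per-sample intensities.
#' Lipid peaks are placed at the library's theoretical m/z (ppm noise) and
#' drifted reference RT; intensities follow
#' `class_base * species_weight * fold * modifier` for P-starved samples,
#' times per-sample loading factors and log-normal peak noise. Decoy peaks
#' are kept >= 20 ppm away from every library m/z so they can never be
#' annotated; housekeeping peaks are condition-stable with a third of the
#' peak noise; marker peaks carry known reference RTs for RT correction.
#'
#' @param design a [study_design()].
#' @param effects an [effect_profile()] for the design's organ.
#' @param library an annotation library data.frame.
#' @param config a [generator_config()].
#' @return A list with elements `peaks` (a `peak_matrix`) and `truth`
#'   (ground-truth list: `true_intensity` species-by-sample matrix before
#'   noise, `markers`, `peak_map`, `tag_rt`, `tag_triples`, `config`).
#' @export
generate_peak_matrix <- function(design, effects, library = default_library(),
                                 config = generator_config()) {
  stopifnot(inherits(design, "study_design"),
            inherits(effects, "effect_profile"),
            inherits(config, "generator_config"))
  .validate_library(library)
  if (design$organ != effects$organ) {
    stop("design organ and effect-profile organ differ", call. = FALSE)
  }
  missing_cls <- setdiff(unique(library$class), names(effects$class_fold))
  if (length(missing_cls)) {
    stop("effect profile missing classes: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  samples <- design$samples
  ns <- nrow(samples)

  .with_seed(config$seed, {
    drift <- .make_drift(config$rt_drift_amplitude)

    # per-species true levels (before any noise): base x weight x fold
    w <- effects$species_weights
    w <- w[w$organ == design$organ, ]
    gm <- effects$genotype_modifier
    lib <- library
    true <- matrix(0, nrow = nrow(lib), ncol = ns,
                   dimnames = list(lib$species, samples$sample_id))
    for (j in seq_len(ns)) {
      cond <- samples$condition[j]
      geno <- samples$genotype[j]
      for (i in seq_len(nrow(lib))) {
        wi <- w$weight[w$species == lib$species[i] & w$condition == cond]
        if (length(wi) != 1) {
          stop("effect profile has no weight for ", lib$species[i],
               " under ", cond, call. = FALSE)
        }
        level <- effects$class_base[[lib$class[i]]] * wi
        if (cond == "P_starved") {
          mod <- gm$modifier[gm$genotype == geno & gm$class == lib$class[i]]
          if (length(mod) != 1) mod <- 1
          level <- level * effects$class_fold[[lib$class[i]]] * mod
        }
        true[i, j] <- level
      }
    }

    sample_scale <- .lognormal_noise(ns, config$sample_scale_sd)

    # lipid peaks, splitting configured species into two isomer peaks
    peak_rows <- list()
    intens <- list()
    peak_map <- list()
    k <- 0
    for (i in seq_len(nrow(lib))) {
      shares <- if (lib$species[i] %in% config$isomer_species) {
        c(config$isomer_share, 1 - config$isomer_share)
      } else 1
      for (p in seq_along(shares)) {
        k <- k + 1
        rt_ref <- lib$reference_rt_min[i] + if (p == 2) 0.06 else 0
        rt_obs <- drift(rt_ref) + stats::rnorm(1, 0, config$rt_jitter_sd)
        mz_obs <- lib$theoretical_mz[i] *
          (1 + stats::rnorm(1, 0, config$mz_ppm_sd) * 1e-6)
        row_int <- true[i, ] * shares[p] * sample_scale *
          .lognormal_noise(ns, config$intensity_cv)
        peak_rows[[k]] <- data.frame(peak_id = sprintf("P%04d", k),
                                     rt_min = rt_obs, mz = mz_obs)
        intens[[k]] <- row_int
        peak_map[[k]] <- data.frame(peak_id = sprintf("P%04d", k),
                                    kind = "lipid", species = lib$species[i],
                                    isomer = p)
      }
    }

    # housekeeping compounds: stable, low-noise, non-lipid m/z (< 600 Da,
    # below every library entry)
    for (h in seq_len(config$housekeeping_compounds)) {
      k <- k + 1
      mz_obs <- stats::runif(1, 150, 560)
      rt_obs <- stats::runif(1, .RT_WINDOW[1], .RT_WINDOW[2])
      base <- stats::rlnorm(1, log(2e5), 0.5)
      row_int <- base * sample_scale *
        .lognormal_noise(ns, config$intensity_cv / 3)
      peak_rows[[k]] <- data.frame(peak_id = sprintf("P%04d", k),
                                   rt_min = rt_obs, mz = mz_obs)
      intens[[k]] <- row_int
      peak_map[[k]] <- data.frame(peak_id = sprintf("P%04d", k),
                                  kind = "housekeeping", species = NA,
                                  isomer = NA)
    }

    # decoys: condition-stable background peaks rejected within 20 ppm of
    # any library m/z, so they can never be annotated at the 10 ppm tolerance
    n_dec <- 0
    while (n_dec < config$decoy_peaks) {
      mz_try <- stats::runif(1, 150, 1500)
      if (any(abs(mz_try - lib$theoretical_mz) / lib$theoretical_mz * 1e6 <
              20)) next
      n_dec <- n_dec + 1
      k <- k + 1
      rt_obs <- stats::runif(1, .RT_WINDOW[1], .RT_WINDOW[2])
      base <- stats::rlnorm(1, log(5e4), 1)
      row_int <- base * sample_scale *
        .lognormal_noise(ns, config$intensity_cv)
      peak_rows[[k]] <- data.frame(peak_id = sprintf("P%04d", k),
                                   rt_min = rt_obs, mz = mz_try)
      intens[[k]] <- row_int
      peak_map[[k]] <- data.frame(peak_id = sprintf("P%04d", k),
                                  kind = "decoy", species = NA, isomer = NA)
    }

    # RT marker peaks at drifted positions of their known reference RTs
    markers <- .DEFAULT_MARKERS
    markers$observed_rt <- drift(markers$reference_rt_min) +
      stats::rnorm(nrow(markers), 0, config$rt_jitter_sd)
    for (m in seq_len(nrow(markers))) {
      k <- k + 1
      row_int <- 1e6 * sample_scale *
        .lognormal_noise(ns, config$intensity_cv / 3)
      peak_rows[[k]] <- data.frame(peak_id = sprintf("P%04d", k),
                                   rt_min = markers$observed_rt[m],
                                   mz = markers$mz[m])
      intens[[k]] <- row_int
      peak_map[[k]] <- data.frame(peak_id = sprintf("P%04d", k),
                                  kind = "marker", species = markers$marker_id[m],
                                  isomer = NA)
    }

    peaks_df <- do.call(rbind, peak_rows)
    intensity <- do.call(rbind, intens)
    rownames(intensity) <- peaks_df$peak_id
    colnames(intensity) <- samples$sample_id

    pm <- peak_matrix(peaks_df, intensity, samples)

    # observed (drifted) RTs of TAG precursors (first peak per species),
    # for fragment-scan generation
    map_df <- do.call(rbind, peak_map)
    lib_tag <- lib$class == "TAG"
    tag_rt <- stats::setNames(
      vapply(lib$species[lib_tag], function(sp) {
        pid <- map_df$peak_id[map_df$kind == "lipid" &
                                map_df$species == sp][1]
        peaks_df$rt_min[match(pid, peaks_df$peak_id)]
      }, numeric(1)),
      lib$species[lib_tag])

    truth <- list(
      true_intensity = true,
      sample_scale = sample_scale,
      markers = data.frame(observed_rt = markers$observed_rt,
                           reference_rt = markers$reference_rt_min),
      peak_map = map_df,
      tag_rt = tag_rt,
      tag_triples = .DEFAULT_TAG_TRIPLES[
        intersect(names(.DEFAULT_TAG_TRIPLES), lib$species[lib_tag])],
      effects = effects,
      config = config
    )
    list(peaks = pm, truth = truth)
  })
}

#' Generate all-ion-fragmentation scans for planted TAG compositions
#'
#' For each TAG with a planted acyl triple, emits one fragment peak per
#' distinct chain at the diacyl neutral-loss m/z, co-eluting within
#' +/- 0.005 min of the TAG precursor, plus decoy fragments placed at least
#' 0.05 min away.
#'
#' @param truth ground truth from [generate_peak_matrix()] (needs `tag_rt`
#'   and `tag_triples`).
#' @param config a [generator_config()].
#' @return A data.frame with columns `rt_min`, `mz`, `intensity`.
#' @export
generate_fragment_scans <- function(truth, config = generator_config()) {
  if (is.null(truth$tag_triples) || length(truth$tag_triples) == 0) {
    stop("ground truth contains no planted TAG compositions", call. = FALSE)
  }
  .with_seed(config$seed + 1L, {
    rows <- list()
    k <- 0
    for (sp in names(truth$tag_triples)) {
      triple <- truth$tag_triples[[sp]]
      rt0 <- truth$tag_rt[[sp]]
      if (is.null(rt0) || is.na(rt0)) {
        stop("TAG without an observed RT: ", sp, call. = FALSE)
      }
      parts <- strsplit(sub("^TAG ", "", sp), ":")[[1]]
      tag <- lipid_species("TAG", as.integer(parts[1]), as.integer(parts[2]))
      chains <- unique(lapply(triple, function(ch) ch))
      for (ch in chains) {
        k <- k + 1
        mz <- fragment_mz(tag, acyl_chain(ch[1], ch[2])) *
          (1 + stats::rnorm(1, 0, config$mz_ppm_sd) * 1e-6)
        rows[[k]] <- data.frame(rt_min = rt0 + stats::runif(1, -0.005, 0.005),
                                mz = mz,
                                intensity = stats::rlnorm(1, log(1e4), 0.3))
      }
      # decoys: right m/z class but far in RT (>= 0.05 min), must be ignored
      for (d in seq_len(config$fragment_decoys)) {
        k <- k + 1
        ch <- triple[[1 + (d - 1) %% length(triple)]]
        mz <- fragment_mz(tag, acyl_chain(ch[1], ch[2]))
        off <- sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.5)
        rows[[k]] <- data.frame(rt_min = rt0 + off, mz = mz,
                                intensity = stats::rlnorm(1, log(5e3), 0.3))
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic qPCR CT table
#'
#' The reference transcript (UBQ10 by default) cycles near a constant;
#' each target gene's CT is `CT_ref + baseline_dct - log2(fold)` for induced
#' samples, plus Gaussian cycle noise, capped at the 40-cycle run limit.
#'
#' @param gene_effects named numeric vector, fold induction (P-starved over
#'   P-replete) per gene; all > 0.
#' @param replicates biological replicates per condition, default 4.
#' @param tech_replicates technical qPCR replicates per biological sample
#'   (rows sharing a sample id; averaged at the CT level downstream),
#'   default 2, matching the platform's two-technical-replicate design.
#' @param ct_noise_sd Gaussian CT noise in cycles per technical measurement,
#'   default 0.15.
#' @param baseline_dct baseline `CT_gene - CT_ref` in the P-replete state
#'   (recycled over genes), default 5.
#' @param reference_gene reference transcript name, default `"UBQ10"`.
#' @param ref_ct mean reference CT, default 20.
#' @param conditions condition labels, default both P conditions.
#' @param seed RNG seed.
#' @return A data.frame with columns `sample`, `condition`, `gene`, `CT`.
#' @export
generate_ct_table <- function(gene_effects, replicates = 4,
                              tech_replicates = 2,
                              ct_noise_sd = 0.15, baseline_dct = 5,
                              reference_gene = "UBQ10", ref_ct = 20,
                              conditions = c("P_replete", "P_starved"),
                              seed = 42) {
  stopifnot(all(gene_effects > 0), replicates >= 1, tech_replicates >= 1,
            ct_noise_sd >= 0)
  genes <- names(gene_effects)
  baseline_dct <- rep_len(baseline_dct, length(genes))
  .with_seed(seed, {
    rows <- list()
    k <- 0
    for (cond in conditions) {
      for (r in seq_len(replicates)) {
        sample_id <- sprintf("%s_r%d", cond, r)
        for (t in seq_len(tech_replicates)) {
          ctr <- ref_ct + stats::rnorm(1, 0, ct_noise_sd)
          k <- k + 1
          rows[[k]] <- data.frame(sample = sample_id, condition = cond,
                                  gene = reference_gene, CT = min(ctr, 40))
        }
        for (g in seq_along(genes)) {
          fold <- if (cond == "P_starved") gene_effects[[g]] else 1
          for (t in seq_len(tech_replicates)) {
            ct <- ref_ct + baseline_dct[g] - log2(fold) +
              stats::rnorm(1, 0, ct_noise_sd)
            k <- k + 1
            rows[[k]] <- data.frame(sample = sample_id, condition = cond,
                                    gene = genes[g], CT = min(ct, 40))
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate gene sequences with planted P1BS motifs
#'
#' Random background sequence in which the degenerate 8-mer GNATATNC is
#' eliminated everywhere by rejection, then exact motif instances are
#' inserted at recorded coordinates inside the requested features. Gene
#' models follow the convention promoter (1 kb upstream of the 5' UTR),
#' then UTR5, alternating exons and introns, then UTR3; coordinates are
#' 0-based half-open on the sense strand.
#'
#' @param motif_plants data.frame with columns `gene`, `feature`
#'   (promoter/UTR5/UTR3/exon/intron), `count`.
#' @param feature_lengths named lengths for generated features.
#' @param n_exons exons per gene (introns = n_exons - 1), default 3.
#' @param seed RNG seed.
#' @return A list with `sequences` (named character), `models` (data.frame
#'   gene/feature/start/end) and `truth` (data.frame of planted hits:
#'   gene/feature/start).
#' @export
generate_gene_sequences <- function(motif_plants,
                                    feature_lengths = c(promoter = 1000,
                                                        UTR5 = 150,
                                                        exon = 400,
                                                        intron = 250,
                                                        UTR3 = 200),
                                    n_exons = 3,
                                    seed = 42) {
  stopifnot(all(motif_plants$count >= 0))
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    genes <- unique(motif_plants$gene)
    seqs <- character(0)
    models <- list()
    planted <- list()
    for (g in genes) {
      feats <- c("promoter", "UTR5")
      for (e in seq_len(n_exons)) {
        feats <- c(feats, sprintf("exon%d", e))
        if (e < n_exons) feats <- c(feats, sprintf("intron%d", e))
      }
      feats <- c(feats, "UTR3")
      # exon1/intron2 -> exon/intron for length lookup; UTR5/UTR3 stay
      base_of <- function(f) sub("^(exon|intron)[0-9]+$", "\\1", f)
      lens <- unname(feature_lengths[base_of(feats)])
      starts <- cumsum(c(0, lens[-length(lens)]))
      model <- data.frame(gene = g, feature = feats, start = starts,
                          end = starts + lens)
      total <- sum(lens)
      s <- sample(bases, total, replace = TRUE)
      # rejection: mutate any background occurrence of the motif away
      repeat {
        hits <- .p1bs_scan_chr(s)
        if (length(hits) == 0) break
        for (h in hits) s[h] <- setdiff(bases, s[h])[1]  # break the G anchor
      }
      # plant exact instances inside requested features
      plants <- motif_plants[motif_plants$gene == g, , drop = FALSE]
      occupied <- integer(0)
      for (r in seq_len(nrow(plants))) {
        feat <- plants$feature[r]
        cnt <- plants$count[r]
        if (cnt == 0) next
        frows <- model[base_of(model$feature) == feat |
                         model$feature == feat, , drop = FALSE]
        if (nrow(frows) == 0) stop("unknown feature: ", feat, call. = FALSE)
        for (ci in seq_len(cnt)) {
          placed <- FALSE
          for (try in 1:200) {
            frow <- frows[sample(nrow(frows), 1), ]
            if (frow$end - frow$start < 8) next
            pos <- sample(frow$start:(frow$end - 8), 1)  # 0-based
            if (any(abs(pos - occupied) < 8)) next
            inst <- c("G", sample(bases, 1), "A", "T", "A", "T",
                      sample(bases, 1), "C")
            s[(pos + 1):(pos + 8)] <- inst
            # inserting may create no second overlapping background match
            # because flanks were motif-free and instances don't overlap
            occupied <- c(occupied, pos)
            planted[[length(planted) + 1]] <-
              data.frame(gene = g, feature = frow$feature, start = pos)
            placed <- TRUE
            break
          }
          if (!placed) stop("could not place motif in ", feat, " of ", g,
                            call. = FALSE)
        }
      }
      # planting can create chance overlaps spanning instance flanks; re-check
      # and mutate any hit that is not a planted start
      repeat {
        hits <- .p1bs_scan_chr(s)
        extra <- setdiff(hits - 1L, occupied)  # hits are 1-based here
        if (length(extra) == 0) break
        for (h in extra) {
          # mutate a position not inside any planted instance
          win <- h + 1L + 0:7
          free <- win[!vapply(win, function(p)
            any(p - 1L >= occupied & p - 1L < occupied + 8), logical(1))]
          if (length(free) == 0) stop("cannot repair overlap", call. = FALSE)
          p <- free[1]
          s[p] <- setdiff(bases, s[p])[1]
        }
      }
      seqs[g] <- paste(s, collapse = "")
      models[[g]] <- model
    }
    truth <- if (length(planted)) do.call(rbind, planted) else
      data.frame(gene = character(0), feature = character(0),
                 start = integer(0))
    list(sequences = seqs, models = do.call(rbind, models), truth = truth)
  })
}

# 1-based start positions of GNATATNC in a character vector of bases
.p1bs_scan_chr <- function(s) {
  n <- length(s)
  if (n < 8) return(integer(0))
  idx <- which(s == "G")
  idx <- idx[idx <= n - 7]
  idx[s[idx + 2] == "A" & s[idx + 3] == "T" & s[idx + 4] == "A" &
        s[idx + 5] == "T" & s[idx + 7] == "C" &
        s[idx + 1] != "N" & s[idx + 6] != "N"]
}
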