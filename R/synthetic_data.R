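# Ground-truth generators for every input the pipeline consumes: screening
# plates, dose-response series, arrayed libraries, insertion count tables,
# compound libraries with a planted structure-activity rule, and community
# profiles. Every generator is a pure function of its arguments (seed
# included); fixed per-generator seed offsets keep the generators'
# random-number substreams independent of one another.

.SEED_OFFSETS <- c(screen = 101L, dose = 202L, tnseq = 303L,
                   library = 404L, community = 505L, arrayed = 606L)

.lognormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

# canonical 96-well layout: 8 interspersed vehicle controls, rest treatments
.screenLayout <- function() {
  all_wells <- as.vector(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0))
  dmso <- c("A01", "B04", "C08", "D12", "E01", "F05", "G09", "H12")
  list(all = all_wells, dmso = dmso, treat = setdiff(all_wells, dmso))
}

#' Simulate a monoculture growth screen with planted inhibition
#'
#' Emulates the study conditions of a single-dose chemical-bacteria screen:
#' 96-well plates with 8 interspersed vehicle-control wells, starting OD600
#' of 0.05, hourly reads for 24 h, three biological replicates, logistic
#' growth with multiplicative lognormal noise (a per-well biological factor
#' and per-read measurement noise, both at \code{noise_cv}). Each
#' compound-strain pair is planted as an inhibition hit with probability
#' \code{hit_fraction}; a planted hit scales the growth portion of the curve
#' so the baseline-corrected AUC is reduced by a fraction drawn uniformly
#' from \code{effect_range}. Optional multiplicative row/column edge effects.
#'
#' @param n_compounds number of library compounds.
#' @param n_strains number of bacterial strains.
#' @param n_replicates biological replicates, default 3.
#' @param hit_fraction probability a compound-strain pair is a planted hit.
#' @param effect_range AUC reduction range of planted hits, default
#'   \code{c(0.5, 0.95)}.
#' @param noise_cv coefficient of variation of the lognormal noise,
#'   default 0.05.
#' @param edge_amplitude amplitude of multiplicative row/column effects
#'   (0 disables), default 0.
#' @param planted_effects optional compound x strain matrix of AUC-reduction
#'   fractions to reuse (e.g. to re-simulate a validation run of the same
#'   planted truth under fresh noise); overrides \code{hit_fraction}.
#' @param seed integer seed.
#' @return list with \code{curves} (\linkS4class{GrowthCurveSet}),
#'   \code{maps} (named list of \linkS4class{PlateMap}s) and \code{truth}
#'   (data.frame of planted compound x strain effects).
#' @export
simScreen <- function(n_compounds, n_strains, n_replicates = 3L,
                      hit_fraction = 0.1, effect_range = c(0.5, 0.95),
                      noise_cv = 0.05, edge_amplitude = 0,
                      planted_effects = NULL, seed = 1L) {
  set.seed(seed + .SEED_OFFSETS[["screen"]])
  layout <- .screenLayout()
  n_treat <- length(layout$treat)
  times <- 0:24
  n0 <- 0.05
  strains <- sprintf("strain%02d", seq_len(n_strains))
  compounds <- sprintf("cmpd%04d", seq_len(n_compounds))
  K <- runif(n_strains, 0.6, 1.2)
  r <- runif(n_strains, 0.4, 0.8)

  if (is.null(planted_effects)) {
    truth <- matrix(0, n_compounds, n_strains,
                    dimnames = list(compounds, strains))
    planted <- matrix(runif(n_compounds * n_strains) < hit_fraction,
                      n_compounds, n_strains)
    truth[planted] <- runif(sum(planted), effect_range[1L], effect_range[2L])
    if (hit_fraction > 0 && sum(planted) < 1L) {
      warning("hit_fraction too small for library size; pure-null plates")
    }
  } else {
    .stopIfNot(all(dim(planted_effects) == c(n_compounds, n_strains)),
               "planted_effects must be n_compounds x n_strains")
    truth <- planted_effects
    dimnames(truth) <- list(compounds, strains)
  }

  n_plates <- ceiling(n_compounds / n_treat)
  maps <- list()
  od_list <- list()
  cd_list <- list()
  for (s in seq_len(n_strains)) {
    base <- K[s] / (1 + ((K[s] - n0) / n0) * exp(-r[s] * times))
    grow <- base - n0
    for (pl in seq_len(n_plates)) {
      idx <- ((pl - 1L) * n_treat + 1L):min(pl * n_treat, n_compounds)
      pid <- sprintf("%s_P%02d", strains[s], pl)
      tw <- layout$treat[seq_along(idx)]
      empty <- setdiff(layout$treat, tw)
      maps[[pid]] <- PlateMap(
        pid,
        c(tw, layout$dmso, empty),
        c(compounds[idx], rep("DMSO", 8L), rep("", length(empty))),
        c(rep(20, length(tw)), rep(0, 8L), rep(0, length(empty))),
        c(rep("treatment", length(tw)), rep("vehicle_control", 8L),
          rep("empty", length(empty))))
      scale_by_well <- setNames(rep(1, 96L), layout$all)
      scale_by_well[tw] <- 1 - truth[idx, s]
      scale_by_well[empty] <- 0
      for (rep_i in seq_len(n_replicates)) {
        rowf <- setNames(exp(edge_amplitude * runif(8L, -1, 1)), LETTERS[1:8])
        colf <- setNames(exp(edge_amplitude * runif(12L, -1, 1)),
                         sprintf("%02d", 1:12))
        wellf <- .lognormNoise(96L, noise_cv)  # per-well biological factor
        edge <- rowf[.wellRow(layout$all)] *
          colf[sprintf("%02d", .wellCol(layout$all))]
        amp <- unname(scale_by_well[layout$all] * wellf * edge)
        odm <- n0 + outer(amp, grow)
        odm <- odm * matrix(.lognormNoise(length(odm), noise_cv), nrow(odm))
        od_list[[length(od_list) + 1L]] <- odm
        cd_list[[length(cd_list) + 1L]] <- data.frame(
          plate_id = pid, well = layout$all, strain_id = strains[s],
          replicate = rep_i)
      }
    }
  }
  curves <- GrowthCurveSet(times, do.call(rbind, od_list),
                           do.call(rbind, cd_list))
  truth_df <- data.frame(
    compound_id = rep(compounds, n_strains),
    strain_id = rep(strains, each = n_compounds),
    effect = as.vector(truth),
    is_hit = as.vector(truth) > 0)
  list(curves = curves, maps = maps, truth = truth_df)
}

#' Simulate dose-response series with planted MICs
#'
#' Hill-type normalized-AUC response per compound-strain pair, constructed
#' so that in the noiseless limit the normalized AUC is below 0.1 exactly
#' for tested doses at and above the planted MIC (Hill coefficient 4; the
#' response at the MIC itself is 0.09). Planted MICs above the highest
#' tested dose yield censored series.
#'
#' @param planted_mic named numeric vector of planted MICs (names are
#'   \code{compound:strain} pair labels); may exceed the tested range.
#' @param concentrations ascending tested doses, default a twofold series
#'   from 0.15625 to 20 micromolar.
#' @param noise_cv multiplicative noise on the response, default 0.
#' @param seed integer seed.
#' @return list with \code{doses} (data.frame: pair, concentration,
#'   norm_auc) and \code{truth} (planted MICs).
#' @export
simDoseResponse <- function(planted_mic,
                            concentrations = 20 / 2^(7:0),
                            noise_cv = 0, seed = 1L) {
  set.seed(seed + .SEED_OFFSETS[["dose"]])
  .stopIfNot(!is.unsorted(concentrations, strictly = TRUE),
             "concentrations must be ascending")
  h <- 4
  rows <- lapply(names(planted_mic), function(pair) {
    mic <- planted_mic[[pair]]
    ec50 <- mic / ((1 - 0.09) / 0.09)^(1 / h)
    resp <- 1 / (1 + (concentrations / ec50)^h)
    resp <- resp * .lognormNoise(length(resp), noise_cv)
    data.frame(pair = pair, concentration = concentrations, norm_auc = resp)
  })
  list(doses = do.call(rbind, rows), truth = planted_mic)
}

#' Simulate a pooled transposon insertion experiment
#'
#' Genes tiled along a chromosome with uniformly placed insertion sites;
#' site read counts are negative binomial around a per-gene mean (sites
#' within a gene share the mean, so observations are exchangeable under the
#' null), with treatment-arm means scaled by \code{2^effect} for planted
#' genes. A fraction of sites is intergenic.
#'
#' @param n_genes number of genes.
#' @param sites_per_gene insertion sites per gene, default 10.
#' @param n_cond,n_ctrl samples per arm, defaults 3 and 3.
#' @param dispersion negative-binomial dispersion (1/size), default 0.2.
#' @param planted named numeric vector of log2 fitness effects (names are
#'   gene ids such as \code{"gene0001"}); empty for a null experiment.
#' @param mean_count baseline mean reads per site, default 100.
#' @param doublings_cond,doublings_ctrl population doublings per arm,
#'   default 6 each.
#' @param frac_intergenic fraction of additional intergenic sites,
#'   default 0.05.
#' @param seed integer seed.
#' @return list with \code{ie} (\linkS4class{InsertionExperiment}),
#'   \code{geneTable} and \code{truth} (planted effects).
#' @export
simTnseq <- function(n_genes, sites_per_gene = 10L, n_cond = 3L, n_ctrl = 3L,
                     dispersion = 0.2, planted = numeric(0),
                     mean_count = 100, doublings_cond = 6, doublings_ctrl = 6,
                     frac_intergenic = 0.05, seed = 1L) {
  set.seed(seed + .SEED_OFFSETS[["tnseq"]])
  gene_len <- 900L
  gap <- 100L
  genes <- sprintf("gene%04d", seq_len(n_genes))
  start <- (seq_len(n_genes) - 1L) * (gene_len + gap) + 1L
  geneTable <- data.frame(gene_id = genes, start = start,
                          end = start + gene_len - 1L,
                          strand = rep_len(c("+", "-"), n_genes))
  pos <- unlist(lapply(seq_len(n_genes), function(g)
    sort(sample.int(gene_len, sites_per_gene)) + start[g] - 1L))
  gene_of_site <- rep(genes, each = sites_per_gene)
  n_inter <- ceiling(frac_intergenic * length(pos))
  if (n_inter > 0L) {
    inter_gene <- sample.int(n_genes, n_inter, replace = TRUE)
    inter_pos <- start[inter_gene] + gene_len - 1L +
      sample.int(gap, n_inter, replace = TRUE)
    pos <- c(pos, inter_pos)
    gene_of_site <- c(gene_of_site, rep(NA_character_, n_inter))
  }
  n_sites <- length(pos)
  gene_mu <- exp(rnorm(n_genes, log(mean_count), 0.3))
  names(gene_mu) <- genes
  mu <- ifelse(is.na(gene_of_site), mean_count, gene_mu[gene_of_site])
  n_samp <- n_cond + n_ctrl
  condition <- c(rep("treated", n_cond), rep("control", n_ctrl))
  eff <- setNames(rep(0, n_genes), genes)
  eff[names(planted)] <- planted
  fold <- 2^ifelse(is.na(gene_of_site), 0, eff[gene_of_site])
  counts <- matrix(0L, n_sites, n_samp)
  for (j in seq_len(n_samp)) {
    mj <- if (condition[j] == "treated") mu * fold else mu
    counts[, j] <- rnbinom(n_sites, size = 1 / dispersion, mu = mj)
  }
  colnames(counts) <- sprintf("%s_r%d", condition,
                              c(seq_len(n_cond), seq_len(n_ctrl)))
  ie <- InsertionExperiment(
    counts, position = pos, gene_id = gene_of_site,
    barcode_id = sprintf("bc%06d", seq_len(n_sites)),
    condition = condition,
    replicate = c(seq_len(n_cond), seq_len(n_ctrl)),
    doublings = ifelse(condition == "treated", doublings_cond,
                       doublings_ctrl))
  list(ie = ie, geneTable = geneTable,
       truth = data.frame(gene_id = genes, log2_effect = unname(eff)))
}

#' Simulate a compound library with a planted structure-activity rule
#'
#' Random sparse binary fingerprints in which a compound is active iff all
#' \code{rule_bits} are set (plus optional label noise). The rule bits' set
#' probability is chosen so the expected prevalence of actives matches
#' \code{prevalence}. Features are the fingerprint bits plus an embedding
#' block formed by a noisy random linear projection of the bits.
#'
#' @param n_compounds library size.
#' @param n_bits fingerprint length, default 64.
#' @param rule_bits indices (1-based) of the bits defining activity,
#'   default \code{c(7, 13)}.
#' @param prevalence target fraction of active compounds, default 0.15.
#' @param background_density set probability of non-rule bits, default 0.1.
#' @param label_noise probability of flipping a label, default 0.
#' @param n_embed embedding block width, default 16.
#' @param seed integer seed.
#' @return list with \code{dataset} (\linkS4class{ToxDataset}),
#'   \code{fingerprints} (\linkS4class{FingerprintSet}) and \code{truth}.
#' @export
simCompoundLibrary <- function(n_compounds, n_bits = 64L,
                               rule_bits = c(7L, 13L), prevalence = 0.15,
                               background_density = 0.1, label_noise = 0,
                               n_embed = 16L, seed = 1L) {
  set.seed(seed + .SEED_OFFSETS[["library"]])
  .stopIfNot(all(rule_bits >= 1L & rule_bits <= n_bits),
             "rule_bits must index into the fingerprint")
  p_rule <- prevalence^(1 / length(rule_bits))
  .stopIfNot(p_rule <= 1, "unattainable prevalence")
  ids <- sprintf("cmpd%04d", seq_len(n_compounds))
  B <- matrix(rbinom(n_compounds * n_bits, 1L, background_density),
              n_compounds, n_bits, dimnames = list(ids, NULL))
  B[, rule_bits] <- rbinom(n_compounds * length(rule_bits), 1L, p_rule)
  y <- as.integer(rowSums(B[, rule_bits, drop = FALSE]) == length(rule_bits))
  if (label_noise > 0) {
    flip <- runif(n_compounds) < label_noise
    y[flip] <- 1L - y[flip]
  }
  proj <- matrix(rnorm(n_bits * n_embed, sd = 1 / sqrt(n_bits)),
                 n_bits, n_embed)
  emb <- B %*% proj + matrix(rnorm(n_compounds * n_embed, sd = 0.1),
                             n_compounds, n_embed)
  feats <- cbind(B, emb)
  colnames(feats) <- c(sprintf("bit%03d", seq_len(n_bits)),
                       sprintf("emb%03d", seq_len(n_embed)))
  labels <- matrix(y, ncol = 1L, dimnames = list(ids, "species1"))
  fps <- FingerprintSet(
    setNames(lapply(seq_len(n_compounds), function(i) which(B[i, ] == 1L) - 1L),
             ids),
    nbits = n_bits)
  list(dataset = ToxDataset(feats, labels), fingerprints = fps,
       truth = list(rule_bits = rule_bits, prevalence = prevalence,
                    labels = setNames(y, ids)))
}

#' Simulate community profiles with planted sensitivity shifts
#'
#' Dirichlet-multinomial read counts for a multi-species community: latent
#' absolute abundances per species, scaled in the treated arm by the
#' planted per-species sensitivity (fold change of absolute abundance);
#' culture OD is the summed latent abundance with multiplicative noise.
#'
#' @param n_species community size, default 20.
#' @param n_replicates replicates per arm, default 3.
#' @param depth reads per sample, default 20000.
#' @param sensitivity named numeric vector of fold changes for planted
#'   species (default none; unnamed species are neutral, fold 1).
#' @param overdispersion Dirichlet concentration parameter, default 500
#'   (larger is closer to multinomial).
#' @param noise_cv OD noise, default 0.02.
#' @param seed integer seed.
#' @return list with \code{treated}/\code{control} (lists of named count
#'   vectors), \code{od_treated}/\code{od_control} and \code{truth}.
#' @export
simCommunity <- function(n_species = 20L, n_replicates = 3L, depth = 20000L,
                         sensitivity = numeric(0), overdispersion = 500,
                         noise_cv = 0.02, seed = 1L) {
  set.seed(seed + .SEED_OFFSETS[["community"]])
  species <- sprintf("sp%02d", seq_len(n_species))
  base <- exp(rnorm(n_species, 0, 0.8))
  names(base) <- species
  fold <- setNames(rep(1, n_species), species)
  fold[names(sensitivity)] <- sensitivity
  drawArm <- function(latent) {
    reps <- vector("list", n_replicates)
    ods <- numeric(n_replicates)
    for (i in seq_len(n_replicates)) {
      rel <- latent / sum(latent)
      p <- .rdirichlet(overdispersion * rel)
      reps[[i]] <- setNames(as.integer(rmultinom(1L, depth, p)), species)
      ods[i] <- sum(latent) * .lognormNoise(1L, noise_cv) * 0.1
    }
    list(counts = reps, od = ods)
  }
  ctrl <- drawArm(base)
  trt <- drawArm(base * fold)
  list(treated = trt$counts, control = ctrl$counts,
       od_treated = trt$od, od_control = ctrl$od,
       truth = data.frame(species = species, fold = unname(fold)))
}

#' Simulate an arrayed mutant library screen
#'
#' Per-plate mutant AUCs under a treatment and a vehicle control:
#' neutral mutants share the plate's typical AUC, planted conditional
#' mutants have their treatment-arm growth scaled by the planted fold;
#' multiplicative lognormal noise on every well.
#'
#' @param n_mutants mutants in the library.
#' @param n_replicates biological (plate) replicates per arm, default 2.
#' @param n_tech technical replicates per well, default 2.
#' @param planted named numeric vector of treatment-arm growth folds
#'   (e.g. \code{c(mut0001 = 0.5)}); others are neutral.
#' @param noise_cv per-well noise level, default 0.05.
#' @param base_auc typical mutant AUC, default 10.
#' @param seed integer seed.
#' @return list with \code{records} (data.frame: mutant_id, condition, arm,
#'   replicate, tech_replicate, auc) and \code{truth}.
#' @export
simArrayed <- function(n_mutants, n_replicates = 2L, n_tech = 2L,
                       planted = numeric(0),
                       noise_cv = 0.05, base_auc = 10, seed = 1L) {
  set.seed(seed + .SEED_OFFSETS[["arrayed"]])
  mutants <- sprintf("mut%04d", seq_len(n_mutants))
  fold <- setNames(rep(1, n_mutants), mutants)
  fold[names(planted)] <- planted
  rows <- list()
  for (arm in c("treatment", "control")) {
    for (i in seq_len(n_replicates)) {
      for (j in seq_len(n_tech)) {
        f <- if (arm == "treatment") fold else rep(1, n_mutants)
        auc <- base_auc * f * .lognormNoise(n_mutants, noise_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          mutant_id = mutants, condition = "chemical", arm = arm,
          replicate = i, tech_replicate = j, auc = auc)
      }
    }
  }
  list(records = do.call(rbind, rows),
       truth = data.frame(mutant_id = mutants, fold = unname(fold)))
}
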