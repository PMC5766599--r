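#' @include AllGenerics.R
NULL

#' Construct a simulation configuration
#'
#' Builds a validated [SimulationConfig-class]. Defaults mirror the study
#' design the generator emulates: a 3-pair matched discovery cohort with
#' low-abundance lncRNAs (baseline mean count below 10), a large unpaired
#' confirmation cohort (682 tumors, 41 normals), planted |log2FC| drawn
#' from \[3, 8\], and a latent factor linking one target lncRNA to a planted
#' protein-coding gene set in tumor samples.
#'
#' @param nPairsDiscovery matched tumor/normal pairs in the discovery cohort
#' @param nTumorConfirm,nNormalConfirm confirmation-cohort group sizes
#' @param nFeatures total features simulated
#' @param fracLncRNA fraction of features that are lncRNAs
#' @param nTrueDE features with a planted nonzero log2 fold change
#' @param logfcRange interval the planted |log2FC| is drawn from (log2 scale)
#' @param lncMeanCount,pcgMeanCount baseline mean counts for lncRNA and
#'   protein-coding features at the reference depth
#' @param dispersion NB dispersion \eqn{\phi} (variance \eqn{\mu+\phi\mu^2})
#' @param patientEffectSd SD of the shared per-patient log-scale effect
#' @param latentFactorLoading log-scale loading of the tumor-only latent
#'   factor shared by the target lncRNA and the planted gene set
#' @param plantedSetSize protein-coding genes in the planted set
#' @param libsizeVariation draw log-normal per-sample depth factors?
#' @param seed integer seed
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' simulationConfig(nFeatures = 500, nTrueDE = 20, seed = 7)
#' @export
simulationConfig <- function(nPairsDiscovery = 3L, nTumorConfirm = 682L,
                             nNormalConfirm = 41L, nFeatures = 2000L,
                             fracLncRNA = 0.3, nTrueDE = 60L,
                             logfcRange = c(3, 8), lncMeanCount = 5,
                             pcgMeanCount = 200, dispersion = 0.2,
                             patientEffectSd = 0.5,
                             latentFactorLoading = 1,
                             plantedSetSize = 40L,
                             libsizeVariation = TRUE, seed = 1L) {
  new("SimulationConfig",
      nPairsDiscovery = as.integer(nPairsDiscovery),
      nTumorConfirm = as.integer(nTumorConfirm),
      nNormalConfirm = as.integer(nNormalConfirm),
      nFeatures = as.integer(nFeatures),
      fracLncRNA = as.numeric(fracLncRNA),
      nTrueDE = as.integer(nTrueDE),
      logfcRange = as.numeric(logfcRange),
      lncMeanCount = as.numeric(lncMeanCount),
      pcgMeanCount = as.numeric(pcgMeanCount),
      dispersion = as.numeric(dispersion),
      patientEffectSd = as.numeric(patientEffectSd),
      latentFactorLoading = as.numeric(latentFactorLoading),
      plantedSetSize = as.integer(plantedSetSize),
      libsizeVariation = isTRUE(libsizeVariation),
      seed = as.integer(seed))
}

#' Construct a count experiment
#'
#' Assembles a [LncCountExperiment-class] from a count matrix, a sample
#' sheet and a feature annotation table, cross-checking identifiers.
#'
#' @param counts integer feature-by-sample matrix with row and column names
#' @param sampleSheet `data.frame` with columns `sample_id`, `patient_id`,
#'   `condition` (tumor/normal) and `stage`
#' @param annotation `data.frame` with columns `feature_id`, `symbol`,
#'   `biotype`, `is_lncRNA`
#' @return A validated [LncCountExperiment-class].
#' @examples
#' cnt <- matrix(0:5, 2, 3, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' sheet <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                     patient_id = c("p1", "p1", "p2"),
#'                     condition = c("tumor", "normal", "tumor"),
#'                     stage = c("II", NA, "III"))
#' ann <- data.frame(feature_id = c("f1", "f2"), symbol = c("A", "B"),
#'                   biotype = c("lincRNA", "protein_coding"),
#'                   is_lncRNA = c(TRUE, FALSE))
#' LncCountExperiment(cnt, sheet, ann)
#' @export
LncCountExperiment <- function(counts, sampleSheet, annotation) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature ids as rownames and sample ids as colnames")
  missSamp <- setdiff(colnames(counts), sampleSheet$sample_id)
  if (length(missSamp))
    stop("samples in counts missing from sample sheet: ",
         paste(missSamp, collapse = ", "))
  missFeat <- setdiff(rownames(counts), annotation$feature_id)
  if (length(missFeat))
    stop("features in counts missing from annotation: ",
         paste(head(missFeat, 5), collapse = ", "))
  ss <- sampleSheet[match(colnames(counts), sampleSheet$sample_id), ,
                    drop = FALSE]
  an <- annotation[match(rownames(counts), annotation$feature_id), ,
                   drop = FALSE]
  cd <- DataFrame(patient_id = ss$patient_id,
                  condition = ss$condition,
                  stage = as.character(ss$stage),
                  row.names = colnames(counts))
  rd <- DataFrame(symbol = an$symbol, biotype = an$biotype,
                  is_lncRNA = an$is_lncRNA, row.names = rownames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd)
  new("LncCountExperiment", se)
}

## sample() semantics are unsafe for length-1 integer pools
.sampleFrom <- function(pool, n) pool[sample.int(length(pool), n)]

## NB draws with the phi -> 0 Poisson limit.
.rnb <- function(n, mu, phi) {
  if (phi < 1e-10) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

.stages <- function(n) sample(c("I", "II", "III", "IV"), n, replace = TRUE)

#' Simulate the matched discovery cohort
#'
#' Draws an `nPairsDiscovery`-pair matched tumor/normal count matrix from a
#' negative-binomial model with log-mean
#' `baseline + patient effect + condition * true_log2fc * log(2)` and
#' dispersion `phi`. lncRNA features sit at the low `lncMeanCount` baseline,
#' protein-coding features at `pcgMeanCount`; per-sample depth factors are
#' log-normal when `libsizeVariation` is on. Planted log2 fold changes are
#' uniform on `logfcRange` with random sign. One up-regulated differentially
#' expressed lncRNA is designated the co-expression target (`is_target`),
#' and `plantedSetSize` protein-coding genes (preferentially the planted DE
#' ones) form the planted co-expression set.
#'
#' @param cfg a [SimulationConfig-class]
#' @return A list with elements `experiment` (a
#'   [LncCountExperiment-class]) and `truth` (a `data.frame` with columns
#'   `feature_id`, `is_de`, `true_log2fc`, `is_lncRNA`, `in_planted_set`,
#'   `is_target`).
#' @examples
#' sim <- simulateDiscoveryCohort(simulationConfig(nFeatures = 100,
#'                                                 nTrueDE = 10, seed = 1))
#' sim$experiment
#' @export
simulateDiscoveryCohort <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)

  nF <- cfg@nFeatures
  nLnc <- round(cfg@fracLncRNA * nF)
  isLnc <- c(rep(TRUE, nLnc), rep(FALSE, nF - nLnc))
  featureId <- sprintf(ifelse(isLnc, "LNC%05d", "PCG%05d"),
                       ave(seq_len(nF), isLnc, FUN = seq_along))
  biotype <- ifelse(isLnc,
                    sample(c("lincRNA", "antisense", "retained_intron",
                             "sense_intronic"), nF, replace = TRUE,
                           prob = c(0.45, 0.3, 0.2, 0.05)),
                    "protein_coding")
  annotation <- data.frame(feature_id = featureId, symbol = featureId,
                           biotype = biotype, is_lncRNA = isLnc)

  ## planted DE signal, allocated across both classes
  nDELnc <- min(nLnc, round(cfg@nTrueDE * cfg@fracLncRNA))
  nDEPcg <- min(nF - nLnc, cfg@nTrueDE - nDELnc)
  deIdx <- c(if (nDELnc) .sampleFrom(which(isLnc), nDELnc),
             if (nDEPcg) .sampleFrom(which(!isLnc), nDEPcg))
  trueLfc <- numeric(nF)
  if (length(deIdx)) {
    mag <- runif(length(deIdx), cfg@logfcRange[1], cfg@logfcRange[2])
    sgn <- sample(c(-1, 1), length(deIdx), replace = TRUE)
    trueLfc[deIdx] <- mag * sgn
  }

  ## designated co-expression target: an up-regulated DE lncRNA if one exists
  isTarget <- rep(FALSE, nF)
  upLnc <- which(isLnc & trueLfc > 0)
  targetIdx <- if (length(upLnc)) upLnc[1] else which(isLnc)[1]
  if (length(targetIdx) && !is.na(targetIdx)) isTarget[targetIdx] <- TRUE

  ## planted co-expression set: protein-coding, preferring planted DE genes
  inSet <- rep(FALSE, nF)
  dePcg <- setdiff(which(!isLnc & trueLfc != 0), targetIdx)
  pool <- c(dePcg, setdiff(which(!isLnc), dePcg))
  inSet[pool[seq_len(min(cfg@plantedSetSize, length(pool)))]] <- TRUE

  nP <- cfg@nPairsDiscovery
  patient <- sprintf("P%02d", seq_len(nP))
  sampleId <- c(paste0(patient, "_T"), paste0(patient, "_N"))
  sheet <- data.frame(sample_id = sampleId,
                      patient_id = rep(patient, 2L),
                      condition = rep(c("tumor", "normal"), each = nP),
                      stage = c(.stages(nP), rep(NA_character_, nP)))

  patEff <- rnorm(nP, 0, cfg@patientEffectSd)
  libFac <- if (cfg@libsizeVariation)
    exp(rnorm(2L * nP, 0, 0.15)) else rep(1, 2L * nP)
  base <- ifelse(isLnc, log(cfg@lncMeanCount), log(cfg@pcgMeanCount))

  logMu <- outer(base, log(libFac), `+`) +
    matrix(rep(patEff, 2L), nF, 2L * nP, byrow = TRUE) +
    outer(trueLfc * log(2), as.numeric(sheet$condition == "tumor"))
  counts <- matrix(.rnb(length(logMu), exp(logMu), cfg@dispersion),
                   nF, 2L * nP, dimnames = list(featureId, sampleId))

  truth <- data.frame(feature_id = featureId, is_de = trueLfc != 0,
                      true_log2fc = trueLfc, is_lncRNA = isLnc,
                      in_planted_set = inSet, is_target = isTarget)
  list(experiment = LncCountExperiment(counts, sheet, annotation),
       truth = truth)
}

#' Simulate the unpaired confirmation cohort
#'
#' Draws a large unpaired tumor/normal cohort with the same feature
#' baselines and the same planted effects (hence the same directions) as
#' the discovery truth table. Across tumor samples only, a standard-normal
#' latent factor with loading `latentFactorLoading` is added on the log-mean
#' scale to the designated target lncRNA and to every planted-set
#' protein-coding gene, inducing the co-expression structure the enrichment
#' and network modules look for.
#'
#' @param cfg a [SimulationConfig-class]
#' @param truth the truth table returned by [simulateDiscoveryCohort()]
#' @return A [LncCountExperiment-class].
#' @examples
#' cfg <- simulationConfig(nFeatures = 100, nTrueDE = 10,
#'                         nTumorConfirm = 30, nNormalConfirm = 10, seed = 1)
#' sim <- simulateDiscoveryCohort(cfg)
#' simulateConfirmationCohort(cfg, sim$truth)
#' @export
simulateConfirmationCohort <- function(cfg, truth) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  need <- c("feature_id", "is_de", "true_log2fc", "is_lncRNA",
            "in_planted_set", "is_target")
  if (!all(need %in% colnames(truth)))
    stop("truth must have columns: ", paste(need, collapse = ", "))
  set.seed(cfg@seed + 1L)

  nF <- nrow(truth)
  nT <- cfg@nTumorConfirm
  nN <- cfg@nNormalConfirm
  sampleId <- c(sprintf("T%04d", seq_len(nT)), sprintf("N%04d", seq_len(nN)))
  sheet <- data.frame(sample_id = sampleId,
                      patient_id = sampleId,
                      condition = rep(c("tumor", "normal"), c(nT, nN)),
                      stage = c(.stages(nT), rep(NA_character_, nN)))

  base <- ifelse(truth$is_lncRNA, log(cfg@lncMeanCount),
                 log(cfg@pcgMeanCount))
  libFac <- if (cfg@libsizeVariation)
    exp(rnorm(nT + nN, 0, 0.15)) else rep(1, nT + nN)
  logMu <- outer(base, log(libFac), `+`) +
    outer(truth$true_log2fc * log(2),
          as.numeric(sheet$condition == "tumor"))

  coexpr <- truth$is_target | truth$in_planted_set
  z <- rnorm(nT)
  logMu[coexpr, seq_len(nT)] <- logMu[coexpr, seq_len(nT)] +
    cfg@latentFactorLoading * matrix(z, sum(coexpr), nT, byrow = TRUE)

  counts <- matrix(.rnb(length(logMu), exp(logMu), cfg@dispersion),
                   nF, nT + nN, dimnames = list(truth$feature_id, sampleId))
  annotation <- data.frame(feature_id = truth$feature_id,
                           symbol = truth$feature_id,
                           biotype = ifelse(truth$is_lncRNA, "lincRNA",
                                            "protein_coding"),
                           is_lncRNA = truth$is_lncRNA)
  LncCountExperiment(counts, sheet, annotation)
}

#' Simulate a paired qPCR Ct cohort
#'
#' Generates duplicate-well Ct measurements for a target lncRNA and a
#' reference gene in matched tumor/normal pairs. The tumor delta-Ct
#' (Ct target minus Ct reference) is shifted by `-effectDeltaCt` relative
#' to the matched normal, so `effectDeltaCt = 1` doubles the tumor
#' `2^-deltaCt` relative expression. Optional `stageEffects` add a further
#' per-stage delta-Ct shift to tumors of that stage.
#'
#' @param nPairs matched pairs to simulate
#' @param stageDistribution named vector over stages CA, I, II, III, IV;
#'   integer counts summing to `nPairs` are used exactly, anything else is
#'   normalised to sampling probabilities
#' @param effectDeltaCt tumor up-regulation in delta-Ct units (cycles)
#' @param noiseSd SD (cycles) of the biological delta-Ct noise; technical
#'   duplicate noise is `noiseSd/5` per well
#' @param seed integer seed
#' @param stageEffects optional named numeric of extra tumor delta-Ct
#'   shifts per stage (positive = higher expression)
#' @param target label written in the `target` column
#' @param baselineDeltaCt mean normal-tissue delta-Ct (default 8 cycles,
#'   a low-abundance transcript relative to the reference gene)
#' @return A `data.frame` with columns `patient_id`, `tissue`, `stage`,
#'   `target`, `ct_rep1`, `ct_rep2`, `ref_ct_rep1`, `ref_ct_rep2` (two rows
#'   per pair).
#' @examples
#' head(simulateQpcrCohort(10, effectDeltaCt = 1, noiseSd = 0.5, seed = 1))
#' @export
simulateQpcrCohort <- function(nPairs,
                               stageDistribution = c(CA = 5, I = 27, II = 40,
                                                     III = 42, IV = 25),
                               effectDeltaCt = 1, noiseSd = 0.5, seed = 1L,
                               stageEffects = NULL, target = "LNC_TARGET",
                               baselineDeltaCt = 8) {
  if (nPairs < 1L) stop("nPairs must be >= 1")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  if (!all(names(stageDistribution) %in% .STAGES))
    stop("stageDistribution names must be among: ",
         paste(.STAGES, collapse = ", "))
  set.seed(as.integer(seed))

  sd0 <- stageDistribution[stageDistribution > 0]
  if (all(sd0 == round(sd0)) && sum(sd0) == nPairs)
    stage <- sample(rep(names(sd0), times = sd0))
  else
    stage <- sample(names(sd0), nPairs, replace = TRUE,
                    prob = sd0 / sum(sd0))

  pairBase <- rnorm(nPairs, baselineDeltaCt, 1)
  stageShift <- if (is.null(stageEffects)) numeric(length(.STAGES)) else
    ifelse(is.na(match(.STAGES, names(stageEffects))), 0,
           stageEffects[match(.STAGES, names(stageEffects))])
  names(stageShift) <- .STAGES

  dNormal <- pairBase + rnorm(nPairs, 0, noiseSd)
  dTumor <- pairBase - effectDeltaCt - stageShift[stage] +
    rnorm(nPairs, 0, noiseSd)

  mk <- function(tissue, dct, stg) {
    ref <- 20 + rnorm(nPairs, 0, noiseSd / 2)
    tgt <- ref + dct
    wellSd <- noiseSd / 5
    data.frame(patient_id = sprintf("Q%03d", seq_len(nPairs)),
               tissue = tissue, stage = stg, target = target,
               ct_rep1 = tgt + rnorm(nPairs, 0, wellSd),
               ct_rep2 = tgt + rnorm(nPairs, 0, wellSd),
               ref_ct_rep1 = ref + rnorm(nPairs, 0, wellSd),
               ref_ct_rep2 = ref + rnorm(nPairs, 0, wellSd))
  }
  out <- rbind(mk("tumor", dTumor, stage),
               mk("normal", dNormal, NA_character_))
  out[order(out$patient_id, out$tissue, method = "radix"), ]
}
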