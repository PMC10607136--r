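#' @importFrom stats rnorm rbinom runif rpois median setNames
NULL

# Deterministic 32-bit substream seed from a root seed and a stage key, so
# that e.g. adding a group to the design never perturbs another group's draws.
.subSeed <- function(seed, key) {
    h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
    as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Build a simulation configuration
#'
#' Constructor for \linkS4class{SimulationConfig} with defaults chosen to
#' resemble targeted antigen bead-array serology data: lognormal antigen
#' backgrounds with heavy right tails, modest per-sample scale and per-site
#' batch variation, and a strong multiplicative boost for the sparse planted
#' seropositive values (so that robust per-sample median/MAD calling is the
#' appropriate detector).
#'
#' @param nSamplesPerGroup named vector of group sizes, names among AAV, GCA,
#'   PMR, HC.
#' @param nAntigens number of antigen fragments.
#' @param prevalence planted seropositivity probabilities: either a single
#'   number (shared by every group and antigen), a per-antigen vector, or a
#'   full groups-x-antigens matrix with rownames matching the groups.
#' @param baselineLogMean,baselineLogSd,antigenLogSd,sampleScaleLogSd,siteEffectLogSd
#'   noise-model parameters on the natural-log scale (see
#'   \linkS4class{SimulationConfig}).
#' @param positiveEffectLogMean,positiveEffectLogSd log boost of planted
#'   positives; the default \code{log(50)} places positives far above the
#'   per-sample median + 20-50 x MAD cutoffs.
#' @param longitudinalFraction,nRelapse,positivePersistence longitudinal
#'   design (AAV only).
#' @param assayType label selecting the default cutoff multiplier:
#'   "planar" (30), "bead_targeted" (50), "bead_kinesin" (20).
#' @param seed integer root seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSamplesPerGroup = c(AAV = 50, HC = 50),
                             nAntigens = 100,
                             prevalence = 0.03,
                             baselineLogMean = log(500),
                             baselineLogSd = 0.3,
                             antigenLogSd = 0.5,
                             sampleScaleLogSd = 0.2,
                             siteEffectLogSd = 0.05,
                             positiveEffectLogMean = log(50),
                             positiveEffectLogSd = 0.4,
                             longitudinalFraction = 0,
                             nRelapse = 0,
                             positivePersistence = 0.9,
                             assayType = "bead_targeted",
                             seed = 1L) {
    nSamplesPerGroup <- setNames(as.integer(nSamplesPerGroup),
                                 names(nSamplesPerGroup))
    groups <- names(nSamplesPerGroup)
    if (is.matrix(prevalence)) {
        prev <- prevalence
    } else {
        prev <- matrix(rep(prevalence, length.out = nAntigens),
                       nrow = length(groups), ncol = nAntigens, byrow = TRUE)
        rownames(prev) <- groups
    }
    new("SimulationConfig",
        nSamplesPerGroup = nSamplesPerGroup, nAntigens = as.integer(nAntigens),
        baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
        antigenLogSd = antigenLogSd, sampleScaleLogSd = sampleScaleLogSd,
        siteEffectLogSd = siteEffectLogSd,
        positiveEffectLogMean = positiveEffectLogMean,
        positiveEffectLogSd = positiveEffectLogSd,
        prevalence = prev, longitudinalFraction = longitudinalFraction,
        nRelapse = as.integer(nRelapse),
        positivePersistence = positivePersistence,
        assayType = assayType, seed = as.integer(seed))
}

.N_FACTOR_DEFAULTS <- c(planar = 30, bead_targeted = 50, bead_kinesin = 20)

#' Default cutoff multiplier for an assay type
#'
#' The per-sample reactivity cutoff is median + n x MAD; the multiplier n is
#' assay-specific: 30 for the untargeted planar array, 50 for the targeted
#' bead array, 20 for the kinesin bead array.
#'
#' @param assayType one of "planar", "bead_targeted", "bead_kinesin".
#' @return the multiplier n.
#' @export
defaultNFactor <- function(assayType) {
    if (!assayType %in% names(.N_FACTOR_DEFAULTS))
        stop(sprintf("unknown assay type '%s'", assayType), call. = FALSE)
    unname(.N_FACTOR_DEFAULTS[assayType])
}

#' Preset configurations mirroring the two bead-array study phases
#'
#' \code{"phase2"} emulates the first targeted screen: 126 AAV diagnosis
#' samples plus 168 healthy controls on a 151-fragment array, with one
#' antigen planted at clearly higher prevalence in AAV (~5\% vs ~0.6\%), one
#' moderately elevated (~16\% vs ~10\%), a few broadly reactive fragments and
#' a low background prevalence tuned so a typical sample carries about five
#' reactive antigens. \code{"phase3"} emulates the kinesin verification
#' screen: 126 AAV diagnosis samples with matched remission (65) and relapse
#' (5) samples, 121 GCA, 63 PMR and 171 healthy controls on a 118-fragment
#' array, with three AAV-enriched fragments (emulating the KIF5C/KIF13A/KIF4A
#' stalk fragments) and several broadly prevalent ones.
#'
#' @param phase \code{"phase2"} or \code{"phase3"}.
#' @param seed integer root seed stored in the configuration.
#' @return A \linkS4class{SimulationConfig}. Calling this twice with the same
#'   arguments yields identical configurations.
#' @export
studyPhaseConfig <- function(phase = c("phase2", "phase3"), seed = 1L) {
    phase <- match.arg(phase)
    if (phase == "phase2") {
        groups <- c(AAV = 126L, HC = 168L)
        nA <- 151L
        prev <- matrix(0.028, nrow = 2, ncol = nA,
                       dimnames = list(names(groups), NULL))
        prev["AAV", 1L] <- 0.048; prev["HC", 1L] <- 0.006
        prev["AAV", 2L] <- 0.16;  prev["HC", 2L] <- 0.10
        prev[, 3L] <- 0.30; prev[, 4L] <- 0.20; prev[, 5L] <- 0.12
        simulationConfig(groups, nA, prev, assayType = "bead_targeted",
                         seed = seed)
    } else {
        groups <- c(AAV = 126L, GCA = 121L, PMR = 63L, HC = 171L)
        nA <- 118L
        prev <- matrix(0.03, nrow = 4, ncol = nA,
                       dimnames = list(names(groups), NULL))
        prev[, 1L] <- 0.10; prev["AAV", 1L] <- 0.40
        prev[, 2L] <- 0.06; prev["AAV", 2L] <- 0.18
        prev[, 3L] <- 0.05; prev["AAV", 3L] <- 0.16
        prev[, 4L] <- 0.45; prev[, 5L] <- 0.35; prev[, 6L] <- 0.25
        simulationConfig(groups, nA, prev,
                         longitudinalFraction = 65 / 126, nRelapse = 5L,
                         assayType = "bead_kinesin", seed = seed)
    }
}

.antigenIds <- function(config) {
    prefix <- if (config@assayType == "bead_kinesin") "KIN" else "AG"
    sprintf("%s%03d", prefix, seq_len(config@nAntigens))
}

.simAntigenAnnotation <- function(config) {
    ids <- .antigenIds(config)
    kin <- config@assayType == "bead_kinesin"
    .withSeed(.subSeed(config@seed, "antigen_annotation"), {
        len <- sample(40:100, config@nAntigens, replace = TRUE)
        start <- sample(1:900, config@nAntigens, replace = TRUE)
        DataFrame(
            antigen_id = ids,
            gene_symbol = if (kin) sprintf("KIF%d", seq_len(config@nAntigens))
                          else sprintf("GENE%03d", seq_len(config@nAntigens)),
            uniprot_id = sprintf("P%05d", seq_len(config@nAntigens)),
            aa_start = as.integer(start),
            aa_end = as.integer(start + len - 1L),
            family_tag = if (kin)
                sprintf("kinesin-%d", 1L + (seq_len(config@nAntigens) %% 14L))
                else NA_character_,
            row.names = ids)
    })
}

.simGroupSamples <- function(config, g, antigenIds, baselineLog, siteLog) {
    nS <- config@nSamplesPerGroup[[g]]
    nA <- config@nAntigens
    .withSeed(.subSeed(config@seed, paste0("group_", g)), {
        subj <- sprintf("SUBJ_%s_%03d", g, seq_len(nS))
        is_aav <- g == "AAV"
        sites <- if (is_aav) c("MUW", "UCAM", "UMCG") else c("UCAM", "UMCG")
        site <- sample(sites, nS, replace = TRUE)
        anca <- if (is_aav)
            sample(c("MPO", "PR3", "negative"), nS, TRUE, c(0.42, 0.50, 0.08))
            else rep("unknown", nS)
        pheno <- if (is_aav)
            ifelse(runif(nS) < ifelse(anca == "MPO", 0.75,
                                      ifelse(anca == "PR3", 0.15, 0.5)),
                   "MPA", "GPA")
            else rep("not_applicable", nS)
        meta <- DataFrame(
            sample_id = sprintf("S_%s_%03d_dx", g, seq_len(nS)),
            subject_id = subj,
            group = factor(g, .GROUP_LEVELS),
            site = factor(site, .SITE_LEVELS),
            timepoint = factor(if (is_aav) "diagnosis" else "single",
                               .TIMEPOINT_LEVELS),
            anca_serotype = factor(anca, .ANCA_LEVELS),
            phenotype = factor(pheno, .PHENOTYPE_LEVELS),
            sex = factor(sample(c("M", "F"), nS, TRUE), .SEX_LEVELS),
            age = round(rnorm(nS, if (g == "HC") 52 else 66, 12)),
            on_treatment = if (is_aav) runif(nS) < 0.6 else NA,
            bvas = if (is_aav) rpois(nS, 15) else NA_integer_,
            organ_kidney = if (is_aav) runif(nS) < 0.55 else FALSE,
            organ_ENT = if (is_aav) runif(nS) < 0.35 else FALSE,
            organ_respiratory = if (is_aav) runif(nS) < 0.40 else FALSE)

        truth_dx <- matrix(rbinom(nS * nA, 1L,
                                  rep(config@prevalence[g, ], each = nS)),
                           nrow = nS, ncol = nA)

        # longitudinal AAV design: matched remission (and a few relapse)
        # samples share the subject id; remission truth keeps each diagnosis
        # positive with probability positivePersistence, relapse reuses the
        # diagnosis truth.
        extra_meta <- NULL; extra_truth <- NULL
        if (is_aav && config@longitudinalFraction > 0) {
            nLong <- floor(config@longitudinalFraction * nS)
            longIdx <- sort(sample.int(nS, nLong))
            rem_truth <- truth_dx[longIdx, , drop = FALSE] *
                matrix(rbinom(nLong * nA, 1L, config@positivePersistence),
                       nrow = nLong)
            rem_meta <- meta[longIdx, ]
            rem_meta$sample_id <- sub("_dx$", "_rem", rem_meta$sample_id)
            rem_meta$timepoint <- factor("remission", .TIMEPOINT_LEVELS)
            rem_meta$bvas <- rpois(nLong, 1)
            extra_meta <- rem_meta; extra_truth <- rem_truth
            if (config@nRelapse > 0) {
                relIdx <- longIdx[seq_len(min(config@nRelapse, nLong))]
                rel_meta <- meta[relIdx, ]
                rel_meta$sample_id <- sub("_dx$", "_rel", rel_meta$sample_id)
                rel_meta$timepoint <- factor("relapse", .TIMEPOINT_LEVELS)
                rel_meta$bvas <- rpois(length(relIdx), 12)
                extra_meta <- rbind(extra_meta, rel_meta)
                extra_truth <- rbind(extra_truth,
                                     truth_dx[relIdx, , drop = FALSE])
            }
        }
        meta <- if (is.null(extra_meta)) meta else rbind(meta, extra_meta)
        truth <- if (is.null(extra_truth)) truth_dx else
            rbind(truth_dx, extra_truth)

        n <- nrow(meta)
        sampleScale <- rnorm(n, 0, config@sampleScaleLogSd)
        boost <- matrix(rnorm(n * nA, config@positiveEffectLogMean,
                              config@positiveEffectLogSd), nrow = n)
        eps <- matrix(rnorm(n * nA, 0, config@baselineLogSd), nrow = n)
        logm <- matrix(baselineLog, nrow = n, ncol = nA, byrow = TRUE) +
            sampleScale + siteLog[as.character(meta$site)] +
            truth * boost + eps
        list(mfi = t(exp(logm)), truth = t(truth), meta = meta)
    })
}

#' Simulate a bead-array serology cohort with planted seropositivity
#'
#' Draws a full synthetic cohort under the multiplicative noise model of
#' \linkS4class{SimulationConfig}: per-antigen lognormal backgrounds, per-
#' sample scales, per-site batch effects, and a strong multiplicative boost
#' on the sparse planted seropositive values. Clinical metadata (ANCA
#' serotype, phenotype, sex, age, treatment, BVAS, organ flags) and the
#' longitudinal AAV design (matched remission/relapse samples sharing the
#' subject id) are populated so that every downstream comparison has
#' realistic inputs. The planted truth is kept as assay \code{"truth"}.
#' Identical (config, seed) reproduce the output exactly.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SeroExperiment} with assays \code{"MFI"} and
#'   \code{"truth"}, full \code{colData}/\code{rowData}, and the
#'   configuration echoed in \code{metadata()} (\code{sim_config},
#'   \code{assay_type}, \code{default_n_factor}).
#' @examples
#' se <- simulateCohort(simulationConfig(c(AAV = 20, HC = 20), nAntigens = 30))
#' se
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    antigenIds <- .antigenIds(config)
    baselineLog <- .withSeed(.subSeed(config@seed, "antigen_baselines"),
        rnorm(config@nAntigens, config@baselineLogMean, config@antigenLogSd))
    siteLog <- .withSeed(.subSeed(config@seed, "site_effects"),
        setNames(rnorm(length(.SITE_LEVELS), 0, config@siteEffectLogSd),
                 .SITE_LEVELS))
    parts <- lapply(names(config@nSamplesPerGroup), function(g)
        .simGroupSamples(config, g, antigenIds, baselineLog, siteLog))
    mfi <- do.call(cbind, lapply(parts, `[[`, "mfi"))
    truth <- do.call(cbind, lapply(parts, `[[`, "truth"))
    meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
    rownames(mfi) <- rownames(truth) <- antigenIds
    colnames(mfi) <- colnames(truth) <- meta$sample_id
    rownames(meta) <- meta$sample_id
    SeroExperiment(mfi, sampleData = meta,
                   antigenData = .simAntigenAnnotation(config),
                   truth = truth,
                   metadata = list(
                       sim_config = config,
                       assay_type = config@assayType,
                       default_n_factor = defaultNFactor(config@assayType),
                       prevalence_planted = config@prevalence))
}
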