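#' @import methods
NULL

PERSON_LEVELS <- c("proband", "father", "mother", "sibling", "control")
TISSUE_LEVELS <- c("blood", "sperm", "oral_epithelium", "saliva",
                   "hair_follicle", "urine")
PLATFORM_LEVELS <- c("mDDPCR", "PASM", "Sanger")
SANGER_LEVELS <- c("detectable", "undetectable", "not_assayed")
CALL_LEVELS <- c("unset", "not_detected", "mosaic", "heterozygous_band")

#' Variant identity
#'
#' Identity of a single-nucleotide variant or small indel on hg19/GRCh37,
#' 1-based coordinates as printed in clinical variant tables. A deletion is
#' encoded with `alt = "-"`; an insertion with `ref = "-"`.
#'
#' @slot chromosome character(1), e.g. `"2"`.
#' @slot position integer(1), 1-based hg19 position of the first affected base.
#' @slot ref,alt character(1) reference and alternate alleles (`"-"` = absent).
#' @slot exon character(1) exon label, e.g. `"Exon26"`.
#' @export
setClass("VariantInfo",
  representation(chromosome = "character", position = "integer",
                 ref = "character", alt = "character", exon = "character"),
  prototype(exon = NA_character_))

setValidity("VariantInfo", function(object) {
  msg <- character()
  if (length(object@position) != 1L || is.na(object@position) ||
      object@position <= 0L)
    msg <- c(msg, "'position' must be a single positive integer")
  if (identical(object@ref, object@alt))
    msg <- c(msg, "'ref' and 'alt' must differ")
  if (!nzchar(object@ref) || !nzchar(object@alt))
    msg <- c(msg, "'ref' and 'alt' must be non-empty ('-' marks an absent allele)")
  if (length(msg)) msg else TRUE
})

#' Gated droplet counts from one digital-PCR run
#'
#' Event counts after gating the two-colour droplet fluorescence readout of a
#' micro-droplet digital PCR (mDDPCR) run into the four droplet classes:
#' mutant-probe-only positive, wild-type-probe-only positive, double-positive
#' and empty.
#'
#' @slot nMutant,nWildtype,nDouble,nEmpty non-negative counts.
#' @export
setClass("DropletCounts",
  representation(nMutant = "numeric", nWildtype = "numeric",
                 nDouble = "numeric", nEmpty = "numeric"))

setValidity("DropletCounts", function(object) {
  v <- c(object@nMutant, object@nWildtype, object@nDouble, object@nEmpty)
  if (length(v) != 4L || anyNA(v)) return("all four counts must be single non-missing numbers")
  if (any(v < 0)) return("droplet counts must be non-negative")
  if (any(v != round(v))) return("droplet counts must be whole numbers")
  TRUE
})

#' Mutant allelic fraction estimate with confidence interval
#'
#' Maximum-likelihood MAF point estimate from droplet counts, its exact 95%
#' binomial (Clopper-Pearson) confidence interval, the homology-corrected
#' values where a correction applies, and the mosaic call.
#'
#' The raw scale is what the droplets measure; when the TaqMan target region
#' co-amplifies `homologyCopies - 1` near-identical genomic regions, the
#' wild-type signal is inflated and the corrected MAF is
#' `min(1, raw * homologyCopies)` (applied to the point estimate and both
#' interval bounds alike).
#'
#' @slot maf,ciLow,ciHigh raw-scale point estimate and 95% CI bounds.
#' @slot mafCorrected,ciLowCorrected,ciHighCorrected homology-corrected
#'   values; `NA` until [correctHomology()] has been applied.
#' @slot homologyCopies integer(1) >= 1; number of genomic matches of the
#'   target region including the target itself.
#' @slot kEff,nEff effective binomial successes/trials backing the interval.
#' @slot call one of `"unset"`, `"not_detected"`, `"mosaic"`,
#'   `"heterozygous_band"` (set by [callSample()]).
#' @slot putativeMosaicProband logical(1); `TRUE` for a proband whose
#'   corrected MAF falls below the heterozygous band.
#' @export
setClass("MafEstimate",
  representation(maf = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 mafCorrected = "numeric", ciLowCorrected = "numeric",
                 ciHighCorrected = "numeric", homologyCopies = "integer",
                 kEff = "numeric", nEff = "numeric", call = "character",
                 putativeMosaicProband = "logical"),
  prototype(mafCorrected = NA_real_, ciLowCorrected = NA_real_,
            ciHighCorrected = NA_real_, homologyCopies = 1L,
            call = "unset", putativeMosaicProband = FALSE))

setValidity("MafEstimate", function(object) {
  msg <- character()
  b <- c(object@ciLow, object@maf, object@ciHigh)
  if (anyNA(b) || any(b < 0) || any(b > 1) || is.unsorted(b))
    msg <- c(msg, "need 0 <= ciLow <= maf <= ciHigh <= 1")
  if (object@homologyCopies < 1L)
    msg <- c(msg, "'homologyCopies' must be >= 1")
  if (!is.na(object@mafCorrected) && object@homologyCopies > 1L &&
      object@mafCorrected < object@maf)
    msg <- c(msg, "corrected MAF cannot be below the raw MAF")
  if (!object@call %in% CALL_LEVELS)
    msg <- c(msg, sprintf("'call' must be one of %s",
                          paste(CALL_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Assay configuration for mosaic calling
#'
#' @slot variant a [VariantInfo-class] (optional; needed for VCF export).
#' @slot homologyCopies integer(1) >= 1: number of genomic regions matched by
#'   the ~130 bp TaqMan target (BLAST/BLAT), including the target. Supplied
#'   as configuration, never inferred from the droplet data.
#' @slot detectThreshold fraction; a sample is called mosaic when the 95% CI
#'   lower bound of its corrected MAF is `>=` this value. Default `1e-4`.
#' @slot hetBand length-2 numeric; corrected-MAF window consistent with a
#'   constitutional heterozygote. Default `c(0.40, 0.60)`.
#' @export
setClass("AssayConfig",
  representation(variant = "ANY", homologyCopies = "integer",
                 detectThreshold = "numeric", hetBand = "numeric"),
  prototype(variant = NULL, homologyCopies = 1L, detectThreshold = 1e-4,
            hetBand = c(0.40, 0.60)))

setValidity("AssayConfig", function(object) {
  msg <- character()
  if (!is.null(object@variant) && !is(object@variant, "VariantInfo"))
    msg <- c(msg, "'variant' must be NULL or a VariantInfo")
  if (object@homologyCopies < 1L)
    msg <- c(msg, "'homologyCopies' must be >= 1")
  if (length(object@hetBand) != 2L || is.unsorted(object@hetBand) ||
      any(object@hetBand < 0 | object@hetBand > 1))
    msg <- c(msg, "'hetBand' must be an increasing interval within [0, 1]")
  if (object@detectThreshold <= 0 || object@detectThreshold >= object@hetBand[1L])
    msg <- c(msg, "'detectThreshold' must lie in (0, hetBand lower bound)")
  if (length(msg)) msg else TRUE
})

#' Beta-binomial posterior MAF estimate (PASM)
#'
#' Posterior summary of a mutant allelic fraction from amplicon
#' deep-sequencing pileup counts under a `Beta(priorAlpha, priorBeta)` prior:
#' maximum a posteriori point estimate and central 95% credible interval.
#'
#' @slot map,criLow,criHigh MAP estimate and credible interval bounds.
#' @slot priorAlpha,priorBeta beta prior parameters (default uniform, 1/1).
#' @slot altCount,depth the observed counts.
#' @export
setClass("PosteriorMaf",
  representation(map = "numeric", criLow = "numeric", criHigh = "numeric",
                 priorAlpha = "numeric", priorBeta = "numeric",
                 altCount = "numeric", depth = "numeric"))

setValidity("PosteriorMaf", function(object) {
  b <- c(object@criLow, object@map, object@criHigh)
  if (anyNA(b) || any(b < 0) || any(b > 1) || is.unsorted(b))
    return("need 0 <= criLow <= map <= criHigh <= 1")
  if (object@priorAlpha <= 0 || object@priorBeta <= 0)
    return("prior parameters must be positive")
  TRUE
})

#' Cohort of families with per-sample MAF records
#'
#' Container for a mosaicism-screening cohort: one `families` row per family
#' (variant identity, parent of origin, mosaic-call flags) and one `samples`
#' row per (family, person, tissue, platform) MAF measurement.
#'
#' Column contracts: `families` has `family_id`, `parental_origin`
#' (`"paternal"`, `"maternal"` or `"none"`), `chromosome`, `position`, `ref`,
#' `alt`, `exon`, `sanger_screening`, `blood_called`, `sperm_called`;
#' `samples` has `family_id`, `person`, `tissue`, `platform`, `maf`,
#' `maf_raw`, `sanger_status`, `na_token`. MAFs are stored as fractions in
#' [0, 1]; percent conversion happens only at I/O boundaries.
#'
#' @slot families data.frame of per-family metadata.
#' @slot samples data.frame of per-sample measurements.
#' @seealso [table1Fixture()], [readCohort()], [summarizeCohort()]
#' @export
setClass("CohortTable",
  representation(families = "data.frame", samples = "data.frame"))

setValidity("CohortTable", function(object) {
  fam <- object@families
  smp <- object@samples
  msg <- character()
  need_fam <- c("family_id", "parental_origin")
  need_smp <- c("family_id", "person", "tissue", "platform", "maf")
  if (!all(need_fam %in% names(fam)))
    return(sprintf("'families' must have columns %s", paste(need_fam, collapse = ", ")))
  if (!all(need_smp %in% names(smp)))
    return(sprintf("'samples' must have columns %s", paste(need_smp, collapse = ", ")))
  if (anyDuplicated(fam$family_id))
    msg <- c(msg, "duplicated family_id in 'families'")
  if (nrow(smp)) {
    key <- paste(smp$family_id, smp$person, smp$tissue, smp$platform, sep = "\r")
    dup <- unique(key[duplicated(key)])
    if (length(dup))
      msg <- c(msg, sprintf("duplicated sample keys: %s",
                            paste(gsub("\r", "/", dup), collapse = "; ")))
    orphan <- setdiff(smp$family_id, fam$family_id)
    if (length(orphan))
      msg <- c(msg, sprintf("samples reference unknown families: %s",
                            paste(orphan, collapse = ", ")))
    if (!all(smp$person %in% PERSON_LEVELS))
      msg <- c(msg, "invalid 'person' value in samples")
    if (!all(smp$tissue %in% TISSUE_LEVELS))
      msg <- c(msg, "invalid 'tissue' value in samples")
    if (!all(smp$platform %in% PLATFORM_LEVELS))
      msg <- c(msg, "invalid 'platform' value in samples")
    bad <- !is.na(smp$maf) & (smp$maf < 0 | smp$maf > 1)
    if (any(bad))
      msg <- c(msg, "'maf' values must lie in [0, 1]")
    if ("maf_raw" %in% names(smp)) {
      both <- !is.na(smp$maf) & !is.na(smp$maf_raw)
      if (any(both & smp$maf < smp$maf_raw - 1e-12))
        msg <- c(msg, "'maf' must be >= 'maf_raw' (homology factor >= 1)")
    }
  }
  if (!all(fam$parental_origin %in% c("paternal", "maternal", "none")))
    msg <- c(msg, "'parental_origin' must be paternal, maternal or none")
  if (length(msg)) msg else TRUE
})

#' Synthetic-cohort generator configuration
#'
#' All parameters of the synthetic cohort, droplet-run and detection-limit
#' generators. Defaults emulate the study conditions of the packaged Dravet
#' syndrome cohort; see the package vignette for the rationale behind each
#' value.
#'
#' @slot nFamilies number of families screened.
#' @slot mosaicFamilyFraction fraction of screened families with a mosaic
#'   parent.
#' @slot paternalFraction fraction of mosaicisms that are paternal.
#' @slot divisionWeights named numeric, probability that the postzygotic
#'   mutation arose at cleavage division 1, 2, ... (names are division
#'   indices; must sum to 1). Division d implies an expected bulk MAF of
#'   `2^-(d+1)`.
#' @slot spermElevation multiplicative factor >= 1 applied to the germline
#'   (sperm) MAF of mosaic fathers.
#' @slot tissueNoiseSd standard deviation of tissue-level noise, applied on
#'   the square-root MAF scale.
#' @slot nTemplates expected number of amplifiable genome copies loaded per
#'   droplet run.
#' @slot nDroplets droplets per run.
#' @slot pasmDepth amplicon sequencing depth simulated for PASM.
#' @slot platformLimits named fractions: nominal detection limits,
#'   `c(Sanger = 0.05, PASM = 0.005, mDDPCR = 5e-5)`.
#' @slot epilepsySlope,epilepsyIntercept logistic model of the mosaic
#'   parent's epileptic phenotype on their blood MAF.
#' @slot seed integer or NA; when set, [simulateCohort()] seeds the RNG.
#' @export
setClass("GeneratorConfig",
  representation(nFamilies = "integer", mosaicFamilyFraction = "numeric",
                 paternalFraction = "numeric", divisionWeights = "numeric",
                 spermElevation = "numeric", tissueNoiseSd = "numeric",
                 nTemplates = "numeric", nDroplets = "numeric",
                 pasmDepth = "integer", platformLimits = "numeric",
                 epilepsySlope = "numeric", epilepsyIntercept = "numeric",
                 seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  fr <- c(object@mosaicFamilyFraction, object@paternalFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  w <- object@divisionWeights
  if (is.null(names(w)) || anyNA(suppressWarnings(as.integer(names(w)))))
    msg <- c(msg, "'divisionWeights' must be named by division index")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "'divisionWeights' must be non-negative and sum to 1")
  if (object@spermElevation < 1)
    msg <- c(msg, "'spermElevation' must be >= 1")
  if (object@tissueNoiseSd < 0) msg <- c(msg, "'tissueNoiseSd' must be >= 0")
  if (any(c(object@nFamilies, object@nTemplates, object@nDroplets,
            object@pasmDepth) <= 0))
    msg <- c(msg, "counts must be positive")
  if (!all(c("Sanger", "PASM", "mDDPCR") %in% names(object@platformLimits)))
    msg <- c(msg, "'platformLimits' must name Sanger, PASM and mDDPCR")
  if (length(msg)) msg else TRUE
})

#' Cohort-level summary counts
#'
#' Descriptive counting rules over a validated [CohortTable-class]; see
#' [summarizeCohort()] for the precise definitions of each field.
#'
#' @slot nBloodMosaic,nSpermMosaic,nSpermOnly,nPaternal,nMaternal,nSangerUndetectableBloodMosaic,nTissueSamples,nTissuePositive counts.
#' @slot fathersSpermHighest,mothersBloodHighest integer pairs `c(k, n)`.
#' @slot spermMafRange,bloodMafRange fraction intervals.
#' @export
setClass("CohortSummary",
  representation(nBloodMosaic = "integer", nSpermMosaic = "integer",
                 nSpermOnly = "integer", nPaternal = "integer",
                 nMaternal = "integer",
                 nSangerUndetectableBloodMosaic = "integer",
                 nTissueSamples = "integer", nTissuePositive = "integer",
                 fathersSpermHighest = "integer",
                 mothersBloodHighest = "integer",
                 spermMafRange = "numeric", bloodMafRange = "numeric"))
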