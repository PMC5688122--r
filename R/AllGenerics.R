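#' @rdname CohortTable-class
#' @param x a `CohortTable`.
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname CohortTable-class
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname estimateMaf
#' @export
setGeneric("estimateMaf",
           function(counts, lambdaCorrect = FALSE, conf = 0.95)
             standardGeneric("estimateMaf"))

#' @rdname correctHomology
#' @export
setGeneric("correctHomology",
           function(x, homologyCopies) standardGeneric("correctHomology"))

#' @rdname callSample
#' @export
setGeneric("callSample",
           function(estimate, assay, personRole = "parent")
             standardGeneric("callSample"))

#' @rdname summarizeCohort
#' @export
setGeneric("summarizeCohort", function(cohort) standardGeneric("summarizeCohort"))

#' @export
#' @rdname CohortTable-class
setMethod("families", "CohortTable", function(x) x@families)

#' @export
#' @rdname CohortTable-class
setMethod("samples", "CohortTable", function(x) x@samples)

setMethod("show", "CohortTable", function(object) {
  fam <- object@families
  cat(sprintf("CohortTable with %d famil%s and %d sample records\n",
              nrow(fam), if (nrow(fam) == 1) "y" else "ies",
              nrow(object@samples)))
  if (nrow(fam)) {
    tab <- table(factor(fam$parental_origin,
                        levels = c("paternal", "maternal", "none")))
    cat(sprintf("  parental origin: %d paternal, %d maternal, %d none\n",
                tab[["paternal"]], tab[["maternal"]], tab[["none"]]))
  }
  invisible(NULL)
})

setMethod("show", "DropletCounts", function(object) {
  cat(sprintf(paste0("DropletCounts: %g mutant, %g wild-type, %g double, ",
                     "%g empty (total %g)\n"),
              object@nMutant, object@nWildtype, object@nDouble,
              object@nEmpty, dropletTotal(object)))
  invisible(NULL)
})

setMethod("show", "MafEstimate", function(object) {
  cat(sprintf("MafEstimate: MAF %.4g%% [%.4g%%, %.4g%%]\n",
              100 * object@maf, 100 * object@ciLow, 100 * object@ciHigh))
  if (!is.na(object@mafCorrected))
    cat(sprintf("  homology-corrected (x%d): %.4g%% [%.4g%%, %.4g%%]\n",
                object@homologyCopies, 100 * object@mafCorrected,
                100 * object@ciLowCorrected, 100 * object@ciHighCorrected))
  cat(sprintf("  call: %s%s\n", object@call,
              if (isTRUE(object@putativeMosaicProband))
                " (putative mosaic proband)" else ""))
  invisible(NULL)
})

setMethod("show", "PosteriorMaf", function(object) {
  cat(sprintf(paste0("PosteriorMaf: MAP %.4g%% [%.4g%%, %.4g%%] ",
                     "(Beta(%g, %g) prior; %g/%g reads)\n"),
              100 * object@map, 100 * object@criLow, 100 * object@criHigh,
              object@priorAlpha, object@priorBeta, object@altCount,
              object@depth))
  invisible(NULL)
})

setMethod("show", "VariantInfo", function(object) {
  cat(sprintf("VariantInfo: %s:%d %s>%s (%s, hg19)\n", object@chromosome,
              object@position, object@ref, object@alt,
              ifelse(is.na(object@exon), "exon NA", object@exon)))
  invisible(NULL)
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary\n")
  cat(sprintf("  blood mosaics: %d (Sanger-undetectable: %d)\n",
              object@nBloodMosaic, object@nSangerUndetectableBloodMosaic))
  cat(sprintf("  sperm mosaics: %d (sperm-only: %d)\n",
              object@nSpermMosaic, object@nSpermOnly))
  cat(sprintf("  origin: %d paternal / %d maternal\n",
              object@nPaternal, object@nMaternal))
  cat(sprintf("  non-sperm peripheral tissue samples: %d (%d with signal)\n",
              object@nTissueSamples, object@nTissuePositive))
  cat(sprintf("  fathers with sperm MAF highest: %d of %d\n",
              object@fathersSpermHighest[1L], object@fathersSpermHighest[2L]))
  cat(sprintf("  mothers with blood MAF highest: %d of %d\n",
              object@mothersBloodHighest[1L], object@mothersBloodHighest[2L]))
  fmt <- function(r) if (all(is.na(r))) "NA" else
    sprintf("%.2f%%-%.2f%%", 100 * r[1L], 100 * r[2L])
  cat(sprintf("  sperm MAF range: %s; blood MAF range: %s\n",
              fmt(object@spermMafRange), fmt(object@bloodMafRange)))
  invisible(NULL)
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(paste0("GeneratorConfig: %d families (mosaic fraction %.3g, ",
                     "paternal fraction %.3g)\n"),
              object@nFamilies, object@mosaicFamilyFraction,
              object@paternalFraction))
  cat(sprintf("  sperm elevation x%.3g; tissue noise sd %.3g (sqrt scale)\n",
              object@spermElevation, object@tissueNoiseSd))
  cat(sprintf("  %g templates over %g droplets; PASM depth %d\n",
              object@nTemplates, object@nDroplets, object@pasmDepth))
  invisible(NULL)
})
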