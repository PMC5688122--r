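## hg19/GRCh37 primary contig lengths for the VCF header
HG19_CONTIGS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566)

## Left-anchor an allele pair for VCF. Table coordinates are 1-based hg19
## with "-" marking an absent allele; the true flanking base is not part of
## the printed data, so the padding base is written as "N".
anchorAlleles <- function(position, ref, alt) {
  if (identical(alt, "-")) {          # deletion: pad with the previous base
    list(pos = position - 1L, ref = paste0("N", ref), alt = "N")
  } else if (identical(ref, "-")) {   # insertion
    list(pos = position - 1L, ref = "N", alt = paste0("N", alt))
  } else {
    list(pos = position, ref = ref, alt = alt)
  }
}

#' Export mosaic calls as VCF
#'
#' Writes one VCFv4.2 record per call at the family's variant position
#' (1-based hg19). Each called (family, person, tissue) combination becomes
#' a sample column; its genotype field carries the MAF and the 95%
#' confidence bounds (`GT:MAF:CILO:CIHI`). Indels are left-anchored with an
#' `N` padding base because the printed coordinates do not include the
#' flanking reference base.
#'
#' @param cohort a [CohortTable-class] whose `families` carry variant
#'   columns (`chromosome`, `position`, `ref`, `alt`).
#' @param calls data.frame with columns `family_id`, `person`, `tissue`,
#'   `maf`, `ci_low`, `ci_high` (fractions).
#' @param path optional output file; when `NULL` the VCF text is returned
#'   as a character vector of lines.
#' @return The VCF lines invisibly (also written to `path` if given).
#' @examples
#' cohort <- table1Fixture()
#' calls <- data.frame(family_id = "DS314", person = "father",
#'                     tissue = "blood", maf = 0.1436,
#'                     ci_low = 0.142, ci_high = 0.145)
#' head(exportVCF(cohort, calls))
#' @export
exportVCF <- function(cohort, calls, path = NULL) {
  stopifnot(is(cohort, "CohortTable"))
  fam <- families(cohort)
  need <- c("chromosome", "position", "ref", "alt")
  if (!all(need %in% names(fam)))
    stop("cohort families lack variant information (chromosome/position/ref/alt)")
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=hg19",
    sprintf("##contig=<ID=%s,length=%.0f,assembly=hg19>",
            names(HG19_CONTIGS), HG19_CONTIGS),
    "##INFO=<ID=FAM,Number=1,Type=String,Description=\"Family identifier\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=MAF,Number=1,Type=Float,Description=\"Mutant allelic fraction\">",
    "##FORMAT=<ID=CILO,Number=1,Type=Float,Description=\"MAF 95% CI lower bound\">",
    "##FORMAT=<ID=CIHI,Number=1,Type=Float,Description=\"MAF 95% CI upper bound\">")
  if (nrow(calls) == 0L) {
    lines <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO"), collapse = "\t"))
  } else {
    need_calls <- c("family_id", "person", "tissue", "maf", "ci_low", "ci_high")
    if (!all(need_calls %in% names(calls)))
      stop(sprintf("'calls' must have columns %s",
                   paste(need_calls, collapse = ", ")))
    miss <- setdiff(calls$family_id, fam$family_id)
    if (length(miss))
      stop(sprintf("calls reference families without variant info: %s",
                   paste(miss, collapse = ", ")))
    sampleIds <- paste(calls$family_id, calls$person, calls$tissue, sep = "_")
    if (anyDuplicated(sampleIds)) stop("duplicated call records")
    lines <- c(header,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds), collapse = "\t"))
    for (i in seq_len(nrow(calls))) {
      f <- fam[fam$family_id == calls$family_id[i], , drop = FALSE]
      a <- anchorAlleles(f$position, f$ref, f$alt)
      gt <- rep(".", nrow(calls))
      gt[i] <- sprintf("0/1:%.6g:%.6g:%.6g", calls$maf[i], calls$ci_low[i],
                       calls$ci_high[i])
      lines <- c(lines, paste(c(
        f$chromosome, a$pos, ".", a$ref, a$alt, ".", "PASS",
        sprintf("FAM=%s", f$family_id), "GT:MAF:CILO:CIHI", gt),
        collapse = "\t"))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
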