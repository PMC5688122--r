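## Token parsing for printed MAF cells: "4.36%(1.45%)", "0.0436", "NA", "ND".
## Percent cells carry the corrected value first and, in parentheses, the raw
## (pre-homology-correction) value when the assay needed correcting.
parseMafToken <- function(token, unit = c("percent", "fraction")) {
  unit <- match.arg(unit)
  token <- trimws(token)
  out <- list(maf = NA_real_, raw = NA_real_, na_token = NA_character_)
  if (is.na(token) || token %in% c("", "NA", "ND", ".")) {
    out$na_token <- if (is.na(token) || token == "") "NA" else token
    return(out)
  }
  m <- regmatches(token, regexec(
    "^([0-9.eE+-]+)%?(?:\\(([0-9.eE+-]+)%?\\))?$", token))[[1L]]
  if (!length(m))
    stop(sprintf("malformed MAF value: '%s'", token))
  scale <- if (unit == "percent" || grepl("%", token)) 100 else 1
  out$maf <- as.numeric(m[2L]) / scale
  if (nzchar(m[3L])) out$raw <- as.numeric(m[3L]) / scale
  if (is.na(out$maf))
    stop(sprintf("malformed MAF value: '%s'", token))
  out
}

#' Construct a cohort table
#'
#' @param families data.frame with one row per family; see
#'   [CohortTable-class] for the column contract.
#' @param samples data.frame with one row per (family, person, tissue,
#'   platform) measurement.
#' @return A validated [CohortTable-class].
#' @export
CohortTable <- function(families, samples) {
  for (col in c("maf", "maf_raw"))
    if (!col %in% names(samples)) samples[[col]] <- NA_real_
  if (!"sanger_status" %in% names(samples))
    samples$sanger_status <- "not_assayed"
  if (!"na_token" %in% names(samples)) samples$na_token <- NA_character_
  rownames(families) <- rownames(samples) <- NULL
  new("CohortTable", families = families, samples = samples)
}

#' Read a cohort from a tabular file
#'
#' Reads a long-format TSV/CSV with one row per measured sample. Required
#' columns: `family_id`, `person`, `tissue`, `platform` and either `maf`
#' (fractions in [0, 1]) or `maf_percent`; likewise `maf_raw` /
#' `maf_raw_percent` for pre-correction values. Optional per-family columns
#' (`parental_origin`, `chromosome`, `position`, `ref`, `alt`, `exon`,
#' `sanger_screening`, `blood_called`, `sperm_called`) are collapsed into
#' the family table. `NA` and `ND` cells become missing values with the
#' original token retained in `na_token`.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param unit `"auto"` (default; decided by column naming), `"fraction"`
#'   or `"percent"`.
#' @return A validated [CohortTable-class].
#' @seealso [writeCohort()] for the inverse.
#' @export
readCohort <- function(path, unit = c("auto", "fraction", "percent")) {
  unit <- match.arg(unit)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           na.strings = NULL, quote = "\"",
                           stringsAsFactors = FALSE)
  need <- c("family_id", "person", "tissue", "platform")
  if (!all(need %in% names(raw)))
    stop(sprintf("cohort file must have columns %s",
                 paste(need, collapse = ", ")))
  pickMafCol <- function(base) {
    pct <- paste0(base, "_percent")
    if (pct %in% names(raw)) list(col = pct, unit = "percent")
    else if (base %in% names(raw)) list(col = base, unit = "fraction")
    else NULL
  }
  mafCol <- pickMafCol("maf")
  if (is.null(mafCol)) stop("cohort file must have a 'maf' or 'maf_percent' column")
  rawCol <- pickMafCol("maf_raw")
  parseCol <- function(spec) {
    if (is.null(spec)) return(rep(NA_real_, nrow(raw)))
    u <- if (unit == "auto") spec$unit else unit
    vapply(seq_len(nrow(raw)), function(i) {
      tryCatch(parseMafToken(raw[[spec$col]][i], unit = u)$maf,
               error = function(e)
                 stop(sprintf("row %d, column '%s': %s", i, spec$col,
                              conditionMessage(e)), call. = FALSE))
    }, numeric(1L))
  }
  tokens <- trimws(raw[[mafCol$col]])
  samples <- data.frame(
    family_id = raw$family_id, person = raw$person, tissue = raw$tissue,
    platform = raw$platform, maf = parseCol(mafCol), maf_raw = parseCol(rawCol),
    sanger_status = if ("sanger_status" %in% names(raw)) raw$sanger_status
                    else rep("not_assayed", nrow(raw)),
    na_token = ifelse(tokens %in% c("NA", "ND", ""), tokens, NA_character_),
    stringsAsFactors = FALSE)

  famCols <- intersect(c("family_id", "parental_origin", "chromosome",
                         "position", "ref", "alt", "exon", "sanger_screening",
                         "blood_called", "sperm_called"), names(raw))
  families <- unique(raw[famCols])
  if (anyDuplicated(families$family_id))
    stop("inconsistent per-family metadata across sample rows")
  if (!"parental_origin" %in% names(families))
    families$parental_origin <- rep("none", nrow(families))
  families$parental_origin <- tolower(families$parental_origin)
  if ("position" %in% names(families))
    families$position <- as.integer(families$position)
  for (col in c("blood_called", "sperm_called"))
    if (col %in% names(families)) families[[col]] <- as.logical(families[[col]])
  CohortTable(families, samples)
}

#' Write a cohort to a tabular file
#'
#' Emits the long format read by [readCohort()]: one row per sample with
#' the per-family metadata repeated, so a single file round-trips the whole
#' object.
#'
#' @param cohort a [CohortTable-class].
#' @param path output path; `.csv` gives comma-separated output.
#' @param unit `"fraction"` (default) or `"percent"`; percent output renames
#'   the MAF columns to `maf_percent` / `maf_raw_percent`.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  stopifnot(is(cohort, "CohortTable"))
  smp <- samples(cohort)
  fam <- families(cohort)
  out <- merge(smp, fam, by = "family_id", sort = FALSE)
  out <- out[order(match(paste(smp$family_id, smp$person, smp$tissue,
                               smp$platform),
                         paste(out$family_id, out$person, out$tissue,
                               out$platform))), , drop = FALSE]
  if (unit == "percent") {
    out$maf <- out$maf * 100
    out$maf_raw <- out$maf_raw * 100
    names(out)[names(out) == "maf"] <- "maf_percent"
    names(out)[names(out) == "maf_raw"] <- "maf_raw_percent"
  }
  # keep the original NA/ND token in the MAF column so ND survives round trips
  mafName <- if (unit == "percent") "maf_percent" else "maf"
  tok <- ifelse(is.na(out$na_token), "NA", out$na_token)
  out[[mafName]] <- ifelse(is.na(out[[mafName]]), tok,
                           as.character(out[[mafName]]))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' The packaged cohort of validated parental mosaic mutations
#'
#' Transcription of the published table of 29 Dravet-syndrome families with
#' a validated mosaic parent: variant identity (hg19), Sanger screening
#' status, mDDPCR MAFs (homology-corrected, with raw pre-correction values
#' where the assay required correcting), PASM MAFs for blood samples, the
#' father's sperm MAF where semen was donated, and the mosaic parent's
#' MAFs in oral epithelium, saliva, hair follicle and urine.
#'
#' The per-family `blood_called` / `sperm_called` flags record the study's
#' classification: 26 of the 29 mosaic parents were callable in blood; in
#' families DS203, DS296 and DS308 the mosaicism was detected only in the
#' father's sperm. Father's-semen measurements in maternal-origin families
#' (e.g. DS306, 0.04%) are stored verbatim but never counted as sperm
#' mosaics.
#'
#' @return A validated [CohortTable-class] with 29 families.
#' @examples
#' cohort <- table1Fixture()
#' summarizeCohort(cohort)
#' @export
table1Fixture <- function() {
  path <- system.file("extdata", "table1.tsv", package = "mosaicDDPCR",
                      mustWork = TRUE)
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", na.strings = NULL,
                            stringsAsFactors = FALSE)
  families <- data.frame(
    family_id = wide$family_id,
    parental_origin = tolower(wide$parental_origin),
    chromosome = wide$chromosome,
    position = as.integer(wide$position),
    ref = wide$ref, alt = wide$alt, exon = wide$exon,
    sanger_screening = tolower(wide$sanger_screening),
    blood_called = as.logical(wide$blood_called),
    sperm_called = suppressWarnings(as.logical(wide$sperm_called)),
    stringsAsFactors = FALSE)

  rows <- vector("list", nrow(wide) * 12L)
  n <- 0L
  addRecord <- function(fid, person, tissue, platform, token, sanger) {
    p <- parseMafToken(token, unit = "percent")
    n <<- n + 1L
    rows[[n]] <<- data.frame(
      family_id = fid, person = person, tissue = tissue, platform = platform,
      maf = p$maf, maf_raw = p$raw, sanger_status = sanger,
      na_token = p$na_token, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(wide))) {
    fid <- wide$family_id[i]
    origin <- tolower(wide$parental_origin[i])
    mosaicParent <- if (origin == "paternal") "father" else "mother"
    sanger <- tolower(wide$sanger_screening[i])
    addRecord(fid, "proband", "blood", "mDDPCR", wide$proband_mddpcr[i], "not_assayed")
    addRecord(fid, "proband", "blood", "PASM", wide$proband_pasm[i], "not_assayed")
    addRecord(fid, "control", "blood", "mDDPCR", wide$control_mddpcr[i], "not_assayed")
    addRecord(fid, "control", "blood", "PASM", wide$control_pasm[i], "not_assayed")
    addRecord(fid, "father", "blood", "mDDPCR", wide$father_mddpcr[i],
              if (mosaicParent == "father") sanger else "not_assayed")
    addRecord(fid, "father", "blood", "PASM", wide$father_pasm[i], "not_assayed")
    addRecord(fid, "mother", "blood", "mDDPCR", wide$mother_mddpcr[i],
              if (mosaicParent == "mother") sanger else "not_assayed")
    addRecord(fid, "mother", "blood", "PASM", wide$mother_pasm[i], "not_assayed")
    addRecord(fid, "father", "sperm", "mDDPCR", wide$father_sperm[i], "not_assayed")
    for (tissue in c("oral_epithelium", "saliva", "hair_follicle", "urine"))
      addRecord(fid, mosaicParent, tissue, "mDDPCR", wide[[tissue]][i],
                "not_assayed")
  }
  CohortTable(families, do.call(rbind, rows[seq_len(n)]))
}
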