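test_that("packaged cohort reproduces the printed table cell by cell", {
  cohort <- fixtureCohort()
  fam <- families(cohort)
  smp <- samples(cohort)

  expect_equal(nrow(fam), 29L)
  expect_equal(sum(fam$parental_origin == "paternal"), 18L)
  expect_equal(sum(fam$parental_origin == "maternal"), 11L)

  getMaf <- function(fid, person, tissue, platform = "mDDPCR")
    smp$maf[smp$family_id == fid & smp$person == person &
            smp$tissue == tissue & smp$platform == platform]
  expect_equal(getMaf("DS314", "father", "blood"), 0.1436)
  expect_equal(getMaf("DS314", "father", "blood", "PASM"), 0.075)
  expect_equal(getMaf("DS276", "mother", "hair_follicle"), 0)
  expect_equal(getMaf("DS308", "father", "sperm"), 0.0003)
  expect_equal(getMaf("DS308", "father", "blood"), 0)
  # raw (pre-correction) values kept alongside corrected ones
  raw <- smp$maf_raw[smp$family_id == "DS017" & smp$person == "father" &
                     smp$tissue == "blood" & smp$platform == "mDDPCR"]
  expect_equal(raw, 0.0145)
  # an ND cell keeps its token
  nd <- smp[smp$family_id == "DS003" & smp$person == "mother" &
            smp$platform == "PASM", ]
  expect_true(is.na(nd$maf))
  expect_equal(nd$na_token, "ND")

  expect_true(all(smp$maf >= 0 & smp$maf <= 0.61, na.rm = TRUE))

  # sperm-only families are flagged, not inferred from point MAFs
  spermOnly <- fam$family_id[!fam$blood_called %in% TRUE &
                             fam$sperm_called %in% TRUE]
  expect_setequal(spermOnly, c("DS203", "DS296", "DS308"))

  vi <- fam[fam$family_id == "DS314", ]
  expect_equal(vi$chromosome, "2")
  expect_equal(vi$position, 166895938L)
  expect_equal(vi$ref, "C")
  expect_equal(vi$alt, "T")
})

test_that("percent and fraction columns parse to identical MAFs", {
  lines_pct <- c("family_id\tperson\ttissue\tplatform\tmaf_percent",
                 "F1\tfather\tblood\tmDDPCR\t45.00%")
  lines_fr <- c("family_id\tperson\ttissue\tplatform\tmaf",
                "F1\tfather\tblood\tmDDPCR\t0.4500")
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines_pct, f1); writeLines(lines_fr, f2)
  expect_equal(samples(readCohort(f1))$maf, 0.45)
  expect_equal(samples(readCohort(f2))$maf, 0.45)
})

test_that("empty cohort file yields an empty validated cohort", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("family_id\tperson\ttissue\tplatform\tmaf", f)
  cohort <- readCohort(f)
  expect_s4_class(cohort, "CohortTable")
  expect_equal(nrow(families(cohort)), 0L)
  expect_equal(nrow(samples(cohort)), 0L)
})

test_that("duplicate keys and malformed numbers are rejected with context", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tperson\ttissue\tplatform\tmaf",
               "F1\tfather\tblood\tmDDPCR\t0.1",
               "F1\tfather\tblood\tmDDPCR\t0.2"), f)
  expect_error(readCohort(f), "duplicated sample keys.*F1")

  writeLines(c("family_id\tperson\ttissue\tplatform\tmaf",
               "F1\tfather\tblood\tmDDPCR\t0.1",
               "F2\tfather\tblood\tmDDPCR\tbogus"), f)
  expect_error(readCohort(f), "row 2")
})

test_that("cohort tables round-trip through write/read, fractions or percent", {
  cohort <- fixtureCohort()
  for (unit in c("fraction", "percent")) {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCohort(cohort, f, unit = unit)
    back <- readCohort(f)
    expect_equal(samples(back)$maf, samples(cohort)$maf)
    expect_equal(samples(back)$maf_raw, samples(cohort)$maf_raw)
    expect_equal(samples(back)$na_token, samples(cohort)$na_token)
    fam0 <- families(cohort)
    fam1 <- families(back)[names(families(cohort))]
    expect_equal(fam1, fam0)
  }
})

test_that("cohort invariants are enforced by validity", {
  fam <- data.frame(family_id = "F1", parental_origin = "paternal")
  smp <- data.frame(family_id = "F1", person = "father", tissue = "blood",
                    platform = "mDDPCR", maf = 1.2)
  expect_error(CohortTable(fam, smp), "\\[0, 1\\]")
  smp$maf <- 0.1
  smp$family_id <- "F2"
  expect_error(CohortTable(fam, smp), "unknown families")
  # corrected MAF may not fall below the raw value
  smp$family_id <- "F1"
  smp$maf_raw <- 0.5
  expect_error(CohortTable(fam, smp), "maf_raw")
})

test_that("VCF export writes anchored hg19 records with MAF format fields", {
  cohort <- fixtureCohort()
  calls <- data.frame(
    family_id = c("DS314", "DS001"), person = "father",
    tissue = c("blood", "sperm"), maf = c(0.1436, 0.3904),
    ci_low = c(0.14, 0.38), ci_high = c(0.15, 0.40),
    stringsAsFactors = FALSE)
  lines <- exportVCF(cohort, calls)
  expect_true(any(grepl("^##fileformat=VCFv4.2$", lines)))
  snv <- grep("166895938", lines, value = TRUE)
  expect_length(snv, 1L)
  expect_match(snv, "^2\t166895938\t\\.\tC\tT\t")
  expect_match(snv, "GT:MAF:CILO:CIHI")
  expect_match(snv, "0/1:0\\.1436:0\\.14:0\\.15")
  # deletion left-anchored one base upstream with N padding
  del <- grep("FAM=DS001", lines, value = TRUE)
  expect_match(del, "^2\t166904193\t\\.\tNT\tN\t")

  empty <- exportVCF(cohort, calls[0, ])
  expect_match(empty[length(empty)], "^#CHROM")
  expect_false(any(grepl("^2\t", empty)))
})

test_that("exported VCF is machine-readable by a VCF parser", {
  skip_if_not_installed("VariantAnnotation")
  cohort <- fixtureCohort()
  calls <- data.frame(family_id = c("DS314", "DS308"), person = "father",
                      tissue = c("blood", "sperm"), maf = c(0.1436, 3e-04),
                      ci_low = c(0.14, 1e-04), ci_high = c(0.15, 9e-04),
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  exportVCF(cohort, calls, path = f)
  vcf <- VariantAnnotation::readVcf(f, genome = "hg19")
  expect_equal(nrow(vcf), 2L)
  expect_equal(ncol(vcf), 2L)
  maf <- VariantAnnotation::geno(vcf)$MAF
  expect_equal(maf[1L, "DS314_father_blood"], 0.1436, tolerance = 1e-6)
  # the indel record is anchored upstream of the printed position
  expect_equal(BiocGenerics::start(SummarizedExperiment::rowRanges(vcf))[2L],
               166852540L)
})

test_that("calls without variant information are refused", {
  fam <- data.frame(family_id = "F1", parental_origin = "paternal")
  smp <- data.frame(family_id = "F1", person = "father", tissue = "blood",
                    platform = "mDDPCR", maf = 0.1)
  cohort <- CohortTable(fam, smp)
  calls <- data.frame(family_id = "F1", person = "father", tissue = "blood",
                      maf = 0.1, ci_low = 0.09, ci_high = 0.11)
  expect_error(exportVCF(cohort, calls), "variant information")
})
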