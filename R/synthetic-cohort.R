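#' Construct a synthetic-cohort generator configuration
#'
#' Defaults emulate the packaged cohort's study conditions: 112 screened
#' families of which 29/112 carry a parental mosaicism, 18/29 paternal; an
#' early-embryonic mutation-timing distribution concentrated on the first
#' cleavage divisions (bulk MAF peaks at 25% and 12.5%); a 1.5-fold
#' multiplicative sperm elevation of the germline MAF in mosaic fathers;
#' tissue-level noise of 0.05 on the square-root MAF scale; droplet runs
#' loading an expected 1e6 template copies into 1e7 droplets; PASM depth
#' 10,000 reads; and nominal platform detection limits of 5% (Sanger),
#' 0.5% (PASM) and 0.005% (mDDPCR). The vignette motivates each value.
#'
#' @param nFamilies,mosaicFamilyFraction,paternalFraction,divisionWeights,spermElevation,tissueNoiseSd,nTemplates,nDroplets,pasmDepth,platformLimits,epilepsySlope,epilepsyIntercept,seed
#'   see [GeneratorConfig-class].
#' @return A validated [GeneratorConfig-class].
#' @examples
#' generatorConfig(nFamilies = 20, seed = 1)
#' @export
generatorConfig <- function(nFamilies = 112L,
                            mosaicFamilyFraction = 29 / 112,
                            paternalFraction = 18 / 29,
                            divisionWeights = c("1" = 0.35, "2" = 0.30,
                                                "3" = 0.20, "4" = 0.10,
                                                "5" = 0.05),
                            spermElevation = 1.5,
                            tissueNoiseSd = 0.05,
                            nTemplates = 1e6,
                            nDroplets = 1e7,
                            pasmDepth = 10000L,
                            platformLimits = c(Sanger = 0.05, PASM = 0.005,
                                               mDDPCR = 5e-5),
                            epilepsySlope = 16,
                            epilepsyIntercept = -2.75,
                            seed = NA_integer_) {
  new("GeneratorConfig", nFamilies = as.integer(nFamilies),
      mosaicFamilyFraction = mosaicFamilyFraction,
      paternalFraction = paternalFraction, divisionWeights = divisionWeights,
      spermElevation = spermElevation, tissueNoiseSd = tissueNoiseSd,
      nTemplates = nTemplates, nDroplets = nDroplets,
      pasmDepth = as.integer(pasmDepth), platformLimits = platformLimits,
      epilepsySlope = epilepsySlope, epilepsyIntercept = epilepsyIntercept,
      seed = as.integer(seed))
}

#' Expected bulk MAF of an early-embryonic postzygotic mutation
#'
#' A mutation arising in one daughter cell of cleavage division `d` is
#' carried heterozygously by a `2^-d` fraction of cells under symmetric
#' lineage contribution, so the expected bulk mutant allelic fraction is
#' `2^-(d + 1)`: 25% for the first division, 12.5% for the second, halving
#' with each later division.
#'
#' @param divisionIndex integer >= 1 (vectorised).
#' @return Expected bulk MAF as a fraction.
#' @examples
#' embryonicMaf(1:3)  # 0.25 0.125 0.0625
#' @export
embryonicMaf <- function(divisionIndex) {
  if (any(is.na(divisionIndex)) || any(divisionIndex < 1) ||
      any(divisionIndex != round(divisionIndex)))
    stop("'divisionIndex' must be a whole number >= 1")
  2^-(divisionIndex + 1)
}

## noise on the sqrt scale, truncated back into [0, 1]
sqrtNoise <- function(maf, sd) {
  if (sd == 0) return(maf)
  pmin(1, pmax(0, sqrt(maf) + stats::rnorm(length(maf), 0, sd)))^2
}

#' Simulate one family
#'
#' Draws one family under the generator model: with probability
#' `mosaicFamilyFraction` one parent is mosaic (paternal with probability
#' `paternalFraction`); the mosaic parent's base MAF comes from the
#' embryonic-division model, each tissue adds independent noise on the
#' square-root scale (truncated to [0, 1]), the father's germline (sperm)
#' MAF is the base multiplied by `spermElevation` before tissue noise, the
#' proband is heterozygous (MAF 0.5), and the mosaic parent's epileptic
#' phenotype is Bernoulli with logistic probability
#' `plogis(epilepsyIntercept + epilepsySlope * bloodMaf)`.
#'
#' Randomness is taken from the session RNG; seed via `set.seed()` or
#' [simulateCohort()].
#'
#' @param config a [GeneratorConfig-class].
#' @param familyId identifier for the emitted records.
#' @return A list with `family` (one-row data.frame of truth metadata:
#'   origin, division index, base and germline MAFs, epilepsy label) and
#'   `samples` (per-tissue MAF records in the cohort dialect).
#' @export
simulateFamily <- function(config, familyId = "SIM001") {
  stopifnot(is(config, "GeneratorConfig"))
  mosaic <- stats::runif(1L) < config@mosaicFamilyFraction
  origin <- if (!mosaic) "none" else
    if (stats::runif(1L) < config@paternalFraction) "paternal" else "maternal"
  division <- NA_integer_
  base <- 0
  germline <- 0
  if (mosaic) {
    division <- as.integer(sample(names(config@divisionWeights), 1L,
                                  prob = config@divisionWeights))
    base <- embryonicMaf(division)
    germline <- if (origin == "paternal")
      min(1, base * config@spermElevation) else base
  }
  parent <- mosaicParentOf(origin)
  sd <- config@tissueNoiseSd
  tissueOf <- function(truth) sqrtNoise(truth, sd)
  rec <- function(person, tissue, maf)
    data.frame(family_id = familyId, person = person, tissue = tissue,
               platform = "mDDPCR", maf = maf, maf_raw = NA_real_,
               sanger_status = "not_assayed", na_token = NA_character_,
               stringsAsFactors = FALSE)
  rows <- list(rec("proband", "blood", 0.5))
  peripheral <- c("oral_epithelium", "saliva", "hair_follicle", "urine")
  for (person in c("father", "mother")) {
    isMosaic <- mosaic && identical(person, parent)
    bl <- if (isMosaic) tissueOf(base) else 0
    rows <- c(rows, list(rec(person, "blood", bl)))
    if (person == "father")
      rows <- c(rows, list(rec("father", "sperm",
                               if (isMosaic) tissueOf(germline) else 0)))
    if (isMosaic)
      for (tissue in peripheral)
        rows <- c(rows, list(rec(person, tissue, tissueOf(base))))
    if (isMosaic) bloodMaf <- bl
  }
  epileptic <- if (mosaic)
    stats::rbinom(1L, 1L, stats::plogis(config@epilepsyIntercept +
                                        config@epilepsySlope * bloodMaf)) == 1L
  else FALSE
  family <- data.frame(
    family_id = familyId, parental_origin = origin,
    blood_called = NA, sperm_called = NA,
    true_division = division, true_base_maf = base,
    true_germline_maf = germline, mosaic_parent_epileptic = epileptic,
    stringsAsFactors = FALSE)
  list(family = family, samples = do.call(rbind, rows))
}

#' Simulate a cohort
#'
#' Draws `config@nFamilies` independent families with [simulateFamily()]
#' and assembles them into a [CohortTable-class] (truth metadata kept as
#' extra `families` columns), so the downstream pipeline - transmission
#' statistics, cohort summaries, clustering - consumes synthetic cohorts
#' unchanged. When `config@seed` is set the RNG is seeded first, making the
#' cohort fully reproducible.
#'
#' @param config a [GeneratorConfig-class].
#' @return A [CohortTable-class].
#' @examples
#' cohort <- simulateCohort(generatorConfig(nFamilies = 30, seed = 7))
#' summarizeCohort(cohort)
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  if (!is.na(config@seed)) set.seed(config@seed)
  ids <- sprintf("SIM%03d", seq_len(config@nFamilies))
  fams <- lapply(ids, function(id) simulateFamily(config, id))
  CohortTable(do.call(rbind, lapply(fams, `[[`, "family")),
              do.call(rbind, lapply(fams, `[[`, "samples")))
}

#' Simulate one droplet run
#'
#' Generative model of a digital-PCR run: the number of template molecules
#' is Poisson with mean `nTemplates`, each is independently mutant with
#' probability `trueMaf`, and molecules land in the `nDroplets` droplets
#' uniformly at random. Under Poisson loading the per-droplet mutant and
#' wild-type occupancies are independent Poisson with means
#' `nTemplates * trueMaf / nDroplets` and
#' `nTemplates * (1 - trueMaf) / nDroplets`, so the four gated droplet
#' class counts are drawn in one multinomial step with the corresponding
#' occupancy probabilities - exactly the marginal law of the
#' molecule-by-molecule model.
#'
#' @param trueMaf fraction in [0, 1].
#' @param config a [GeneratorConfig-class] (uses `nTemplates`,
#'   `nDroplets`).
#' @return A [DropletCounts-class].
#' @examples
#' set.seed(1)
#' simulateDropletRun(0.01, generatorConfig())
#' @export
simulateDropletRun <- function(trueMaf, config) {
  stopifnot(is(config, "GeneratorConfig"))
  if (is.na(trueMaf) || trueMaf < 0 || trueMaf > 1)
    stop("'trueMaf' must lie in [0, 1]")
  lmu <- config@nTemplates * trueMaf / config@nDroplets
  lwt <- config@nTemplates * (1 - trueMaf) / config@nDroplets
  pmu <- -expm1(-lmu) * exp(-lwt)
  pwt <- exp(-lmu) * -expm1(-lwt)
  pdb <- -expm1(-lmu) * -expm1(-lwt)
  pem <- exp(-lmu - lwt)
  n <- stats::rmultinom(1L, config@nDroplets, c(pmu, pwt, pdb, pem))
  DropletCounts(nMutant = n[1L], nWildtype = n[2L], nDouble = n[3L],
                nEmpty = n[4L])
}

#' Theoretical MAFs of a sequential dilution series
#'
#' @param stockMaf MAF of the undiluted standard, default 0.5 (a
#'   constitutional heterozygote).
#' @param dilutionFactor fold-dilution per step, default 10.
#' @param nSteps number of steps, default 6.
#' @return Numeric vector of length `nSteps`: step `i` has theoretical MAF
#'   `stockMaf / dilutionFactor^i`.
#' @examples
#' simulateDilutionSeries()  # 5% down to 0.00005%
#' @export
simulateDilutionSeries <- function(stockMaf = 0.5, dilutionFactor = 10,
                                   nSteps = 6L) {
  if (stockMaf <= 0 || stockMaf > 1) stop("'stockMaf' must lie in (0, 1]")
  if (dilutionFactor <= 0) stop("'dilutionFactor' must be positive")
  if (nSteps < 0) stop("'nSteps' must be >= 0")
  stockMaf / dilutionFactor^seq_len(nSteps)
}

#' Detection power of a platform at a given MAF
#'
#' Monte-Carlo estimate of the probability that a platform detects a
#' mosaic MAF, under each platform's measurement model:
#' \itemize{
#'   \item Sanger: deterministic threshold - detected iff
#'     `trueMaf > platformLimits["Sanger"]` (chromatogram peak height,
#'     no count statistics).
#'   \item PASM: `altCount ~ Binomial(pasmDepth, trueMaf)`; detected iff
#'     at least one mutant read is seen and the 95% posterior credible
#'     upper bound reaches the platform's nominal limit.
#'   \item mDDPCR: a full droplet run is simulated and the MAF estimated;
#'     detected iff at least one mutant-positive droplet is seen and the
#'     95% CI upper bound reaches the platform's nominal limit.
#' }
#' For the counting platforms "detected" therefore means the run shows
#' mutant signal statistically compatible with a MAF at or above the
#' platform's limit; this benchmark criterion is intentionally distinct
#' from the cohort mosaic-calling rule of [callSample()], which demands the
#' CI *lower* bound clear the background threshold.
#'
#' @param platform `"Sanger"`, `"PASM"` or `"mDDPCR"`.
#' @param trueMaf fraction in [0, 1].
#' @param config a [GeneratorConfig-class].
#' @param nReps Monte-Carlo replicates, default 200.
#' @return A list with `power`, its 95% Monte-Carlo confidence bounds
#'   `ciLow`/`ciHigh` (Clopper-Pearson), `platform`, `trueMaf`, `nReps`.
#' @examples
#' set.seed(1)
#' detectionPower("PASM", 0.005, generatorConfig(), nReps = 50)$power
#' @export
detectionPower <- function(platform, trueMaf, config, nReps = 200L) {
  stopifnot(is(config, "GeneratorConfig"))
  if (!platform %in% names(config@platformLimits))
    stop(sprintf("unknown platform '%s'", platform))
  if (nReps < 1L) stop("'nReps' must be >= 1")
  limit <- config@platformLimits[[platform]]
  detected <- switch(platform,
    Sanger = rep(trueMaf > limit, nReps),
    PASM = {
      k <- stats::rbinom(nReps, config@pasmDepth, trueMaf)
      upper <- stats::qbeta(0.975, k + 1, config@pasmDepth - k + 1)
      k >= 1L & upper >= limit
    },
    mDDPCR = vapply(seq_len(nReps), function(i) {
      counts <- simulateDropletRun(trueMaf, config)
      k <- counts@nMutant + counts@nDouble
      if (k < 1) return(FALSE)
      est <- estimateMaf(counts)
      est@ciHigh >= limit
    }, logical(1L)))
  ci <- clopperPearson(sum(detected), nReps)
  list(platform = platform, trueMaf = trueMaf, power = mean(detected),
       ciLow = ci[1L, "lower"], ciHigh = ci[1L, "upper"], nReps = nReps)
}
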