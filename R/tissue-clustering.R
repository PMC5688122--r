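#' Tissue-by-family MAF matrix
#'
#' Builds the matrix clustered in the multi-tissue analysis: one row per
#' sample type (the mosaic parent's blood, the father's sperm, and the
#' mosaic parent's oral epithelium, saliva, hair follicle and urine), one
#' column per family. By default the columns are the families in which the
#' mosaic parent donated at least one non-blood, non-sperm peripheral
#' tissue.
#'
#' @param cohort a [CohortTable-class].
#' @param familyIds optional character vector selecting the columns.
#' @return A numeric matrix of MAF fractions with `NA` for unmeasured
#'   cells.
#' @examples
#' m <- mafMatrix(table1Fixture())
#' dim(m)
#' @export
mafMatrix <- function(cohort, familyIds = NULL) {
  stopifnot(is(cohort, "CohortTable"))
  fam <- families(cohort)
  smp <- samples(cohort)
  mdd <- smp[smp$platform == "mDDPCR" & !is.na(smp$maf), , drop = FALSE]
  fam$mosaic_parent <- mosaicParentOf(fam$parental_origin)
  fam <- fam[!is.na(fam$mosaic_parent), , drop = FALSE]
  peripheral <- c("oral_epithelium", "saliva", "hair_follicle", "urine")
  if (is.null(familyIds)) {
    has <- vapply(seq_len(nrow(fam)), function(i)
      any(mdd$family_id == fam$family_id[i] &
          mdd$person == fam$mosaic_parent[i] &
          mdd$tissue %in% peripheral), logical(1L))
    familyIds <- fam$family_id[has]
  }
  tissues <- c("blood", "sperm", peripheral)
  m <- matrix(NA_real_, nrow = length(tissues), ncol = length(familyIds),
              dimnames = list(tissues, familyIds))
  for (fid in familyIds) {
    parent <- fam$mosaic_parent[fam$family_id == fid]
    if (!length(parent)) stop(sprintf("unknown or non-mosaic family '%s'", fid))
    for (tissue in tissues) {
      person <- if (tissue == "sperm") "father" else parent
      # a father's sperm value is germline data only in paternal families
      if (tissue == "sperm" && parent != "father") next
      v <- mdd$maf[mdd$family_id == fid & mdd$person == person &
                   mdd$tissue == tissue]
      if (length(v)) m[tissue, fid] <- v[1L]
    }
  }
  m
}

#' Element-wise square-root transform
#'
#' @param m numeric matrix of fractions in [0, 1]; `NA` preserved.
#' @return The transformed matrix.
#' @export
sqrtTransform <- function(m) {
  if (any(m < 0, na.rm = TRUE)) stop("MAF values must be non-negative")
  sqrt(m)
}

#' Euclidean distances between tissue MAF profiles
#'
#' Pairwise Euclidean distances between the rows of a (typically
#' square-root-transformed) MAF matrix, with one of two missing-data
#' policies: `"complete_pairs_scaled"` (default) computes each pair's
#' distance over its shared observed columns and rescales by
#' `sqrt(ncol / shared)` so distances over few shared columns remain
#' comparable; `"complete_columns"` first drops every column containing a
#' missing value.
#'
#' @param m numeric matrix (rows are clustered).
#' @param naPolicy `"complete_pairs_scaled"` or `"complete_columns"`.
#' @return A `stats::dist` object over the rows.
#' @examples
#' d <- mafDistances(sqrtTransform(mafMatrix(table1Fixture())))
#' @export
mafDistances <- function(m, naPolicy = c("complete_pairs_scaled",
                                         "complete_columns")) {
  naPolicy <- match.arg(naPolicy)
  if (nrow(m) < 2L) stop("need at least 2 rows to compute distances")
  if (naPolicy == "complete_columns") {
    keep <- colSums(is.na(m)) == 0L
    if (!any(keep)) stop("no complete columns")
    return(stats::dist(m[, keep, drop = FALSE], method = "euclidean"))
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(shared))
        stop(sprintf("rows '%s' and '%s' share no observed columns",
                     rownames(m)[i], rownames(m)[j]))
      d <- sqrt(sum((m[i, shared] - m[j, shared])^2) *
                ncol(m) / sum(shared))
      D[i, j] <- D[j, i] <- d
    }
  }
  stats::as.dist(D)
}

#' Agglomerative clustering of tissue profiles
#'
#' Hierarchical clustering of a distance matrix with deterministic
#' behaviour: items are ordered by label before merging so equal-distance
#' ties break lexicographically.
#'
#' @param distances a `stats::dist` object.
#' @param linkage `"average"` (UPGMA, default), `"complete"` or
#'   `"single"`.
#' @return A `stats::hclust` tree.
#' @examples
#' d <- mafDistances(sqrtTransform(mafMatrix(table1Fixture())))
#' hc <- clusterTissues(d)
#' @export
clusterTissues <- function(distances,
                           linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  labels <- attr(distances, "Labels")
  if (attr(distances, "Size") < 2L) stop("need at least 2 items")
  if (!is.null(labels)) {
    ord <- order(labels)
    distances <- stats::as.dist(as.matrix(distances)[ord, ord])
  }
  stats::hclust(distances, method = linkage)
}

#' Export a dendrogram as Newick text
#'
#' Converts the merge tree to a phylogeny (branch lengths are differences
#' of merge heights) and serialises it as Newick.
#'
#' @param hc a `stats::hclust` tree.
#' @param path optional output file.
#' @return The Newick string, invisibly when written to `path`.
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  txt <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
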