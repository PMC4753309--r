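# Community succession analytics: copy-number corrected relative abundance,
# Bray-Curtis dissimilarity and clustering, taxon decline rates, primer-bias
# diagnostics and the four-stage developmental classifier.

#' Copy-number-corrected relative abundance
#'
#' Divides each taxon's counts by its 16S rRNA gene copy number (e.g. 2 for
#' the rod-shaped lithoautotroph, whose genome carries two operons) and
#' renormalises each sample to proportions. With uniform copy numbers the
#' correction reduces to plain normalisation.
#'
#' @param x a [MatCommunity-class] in counts mode.
#' @return A [MatCommunity-class] in proportions mode (copy numbers reset to
#'   1: the correction is not applied twice).
#' @examples
#' m <- matrix(c(100, 50), 2, dimnames = list(c("A", "B"), "s1"))
#' mc <- MatCommunity(m, copy_number = c(2, 1))
#' abundances(relativeAbundance(mc))  # 0.5 / 0.5
#' @export
relativeAbundance <- function(x) {
  stopifnot(is(x, "MatCommunity"))
  if (abundanceMode(x) != "counts")
    stop("relativeAbundance expects a table in counts mode")
  a <- abundances(x) / copyNumbers(x)      # row-wise recycling: taxa in rows
  tot <- colSums(a)
  if (any(tot == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(a)[tot == 0], collapse = ", "))
  a <- sweep(a, 2, tot, "/")
  cd <- SummarizedExperiment::colData(x)
  MatCommunity(a, copy_number = 1, site = cd$site, day = cd$day,
               depth_zone = cd$depth_zone, mode = "proportions")
}

#' Bray-Curtis dissimilarity between two community vectors
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}: 0 for identical
#' vectors, 1 for disjoint supports.
#'
#' @param x,y equal-length non-negative vectors, not both all-zero.
#' @return Dissimilarity in [0, 1].
#' @examples
#' brayCurtis(c(10, 0), c(5, 5))  # 0.5
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("community vectors must be >= 0")
  if (sum(x) + sum(y) == 0) stop("both vectors are all-zero")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Bray-Curtis dissimilarity matrix of a community table
#'
#' Pairwise Bray-Curtis dissimilarities between samples, computed on
#' (copy-corrected) proportions so that sequencing depth does not enter.
#'
#' @param x a [MatCommunity-class]; a counts-mode table is first passed
#'   through [relativeAbundance()].
#' @return A `dist` object over the samples.
#' @examples
#' bc <- brayCurtisMatrix(genCommunityTable(siteConfig("osp")))
#' @export
brayCurtisMatrix <- function(x) {
  stopifnot(is(x, "MatCommunity"))
  if (abundanceMode(x) == "counts") x <- relativeAbundance(x)
  vegan::vegdist(t(abundances(x)), method = "bray")
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of a dissimilarity matrix (default complete
#' linkage, matching the convention of heatmap dendrogram annotations;
#' `"average"` is also meaningful for Bray-Curtis). Ties are broken
#' deterministically by the label order of the input.
#'
#' @param d a `dist` (e.g. from [brayCurtisMatrix()]) or a symmetric matrix
#'   with zero diagonal.
#' @param linkage `"complete"` or `"average"`.
#' @return An `hclust` tree; serialise with [writeNewick()].
#' @examples
#' clusterDendrogram(brayCurtisMatrix(genCommunityTable(siteConfig("osp"))))
#' @export
clusterDendrogram <- function(d, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0))
      stop("dissimilarity matrix must be symmetric with zero diagonal")
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2) stop("need >= 2 samples to cluster")
  stats::hclust(d, method = linkage)
}

#' Linear decline rate of a taxon's relative abundance
#'
#' Ordinary least-squares slope of percentage abundance against day,
#' reported as a positive decline (%/day) when abundance falls.
#'
#' @param day numeric days.
#' @param percent relative abundance in percent at those days.
#' @return Decline in percentage points per day (positive = declining).
#' @examples
#' declineRate(c(15, 70), c(65, 10))  # 1 %/day
#' @export
declineRate <- function(day, percent) {
  if (length(day) != length(percent) || length(day) < 2)
    stop("need >= 2 (day, percent) pairs")
  -stats::coef(stats::lm(percent ~ day))[[2]]
}

#' Linearly extrapolate a declining abundance
#'
#' Projects `from_value` (percent at `from_day`) forward at a constant
#' decline, flooring the result at 0%.
#'
#' @param rate decline in %/day (positive = declining).
#' @param from_day,from_value anchor point (day, percent).
#' @param to_day target day.
#' @return Projected percent, >= 0.
#' @examples
#' extrapolateDecline(1, from_day = 70, from_value = 31, to_day = 100)  # 1
#' @export
extrapolateDecline <- function(rate, from_day, from_value, to_day) {
  max(from_value - rate * (to_day - from_day), 0)
}

#' Amplicon vs reference primer-bias diagnostics
#'
#' Compares per-taxon relative abundances from a 16S amplicon (iTag) table
#' with a reference table (e.g. random shotgun metagenome reads from the
#' same samples). The ratio amplicon/reference flags taxa the primer set
#' over- or under-represents; a single mismatch in a universal primer can
#' shift a dominant taxon by an order of magnitude. Taxa present in one
#' table only are reported `absent`, never 0 or infinity.
#'
#' @param itag,reference [MatCommunity-class] tables (counts tables are
#'   copy-corrected and normalised first) with matching sample columns, or
#'   named proportion vectors for a single sample.
#' @return data.frame with columns `taxon`, `sample`, `itag`, `reference`
#'   (proportions), `ratio` and `flag` (`"over"`, `"under"`, `"equal"`,
#'   `"absent"`).
#' @examples
#' primerBias(c(Hydrogenobaculum = 0.242, Myellow = 0.0051),
#'            c(Hydrogenobaculum = 0.03, Myellow = 0.16))
#' @export
primerBias <- function(itag, reference) {
  as_prop_mat <- function(x, what) {
    if (is(x, "MatCommunity")) {
      if (abundanceMode(x) == "counts") x <- relativeAbundance(x)
      abundances(x)
    } else if (is.numeric(x) && !is.null(names(x))) {
      matrix(x, ncol = 1, dimnames = list(names(x), "sample1"))
    } else stop(what, " must be a MatCommunity or a named numeric vector")
  }
  a <- as_prop_mat(itag, "itag")
  b <- as_prop_mat(reference, "reference")
  samples <- intersect(colnames(a), colnames(b))
  if (!length(samples)) stop("no shared samples between the two tables")
  taxa <- union(rownames(a), rownames(b))
  out <- do.call(rbind, lapply(samples, function(s) {
    ai <- a[match(taxa, rownames(a)), s]
    bi <- b[match(taxa, rownames(b)), s]
    ratio <- ifelse(is.na(ai) | is.na(bi), NA_real_, ai / bi)
    flag <- ifelse(is.na(ai) | is.na(bi), "absent",
            ifelse(ratio > 1, "over", ifelse(ratio < 1, "under", "equal")))
    data.frame(taxon = taxa, sample = s, itag = unname(ai),
               reference = unname(bi), ratio = unname(ratio), flag = flag,
               row.names = NULL)
  }))
  out
}

#' Classify the developmental stage of a mat
#'
#' Rule cascade over a [MatState-class], anchored to the qualitative ranges
#' of the four-stage conceptual model of mat development: Stage I, primary
#' lithoautotroph colonization on a bare substrate; Stage II, visible
#' Fe(III)-oxide accretion and incipient microterracettes; Stage III,
#' heterotroph colonization with apparent O2 gradients at mm depths;
#' Stage IV, thick "mature" mats dominated by organoheterotrophs. Thresholds
#' are configurable; the defaults place Stage IV at >= 5 mm, Stage III at
#' >= 2 mm depth or a heterotroph fraction >= 0.25, Stage II at visible
#' oxide.
#'
#' @param state a [MatState-class].
#' @param stage4_depth_mm,stage3_depth_mm depth thresholds (mm).
#' @param stage3_heterotroph_fraction community threshold in [0, 1].
#' @return Ordered factor level among `"I" < "II" < "III" < "IV"`.
#' @examples
#' classifyStage(matState(day = 5, lithoautotroph_fraction = 0.95))
#' classifyStage(matState(day = 20, mat_depth_mm = 0.7, visible_fe = TRUE))
#' @export
classifyStage <- function(state, stage4_depth_mm = 5, stage3_depth_mm = 2,
                          stage3_heterotroph_fraction = 0.25) {
  stopifnot(is(state, "MatState"))
  validObject(state)
  het <- 1 - state@lithoautotroph_fraction
  stage <-
    if (state@mat_depth_mm >= stage4_depth_mm) "IV"
    else if (state@mat_depth_mm >= stage3_depth_mm ||
             het >= stage3_heterotroph_fraction) "III"
    else if (state@visible_fe) "II"
    else "I"
  factor(stage, levels = c("I", "II", "III", "IV"), ordered = TRUE)
}
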