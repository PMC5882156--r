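#' Per-genome TF proportions, stratified by lifestyle
#'
#' The TF proportion of a genome is its total TF count divided by its size
#' in ORFs. Proportions are grouped by lifestyle and summarized with
#' box-plot statistics (median, min, max, 1.5 IQR outliers).
#'
#' @param abundance An `abundance_matrix` from [count_families()].
#' @param genomes Genome metadata with `lifestyle` labels from the closed
#'   vocabulary.
#' @return A list with `per_genome` (`data.frame`: genome_id, lifestyle,
#'   n_orfs, n_tfs, proportion) and `summary` (`data.frame` per lifestyle:
#'   n_genomes, median, min, max, n_outliers).
#' @export
tf_proportions <- function(abundance, genomes) {
  gid <- colnames(abundance)
  meta <- genomes[match(gid, genomes$genome_id), ]
  if (any(is.na(meta$genome_id)))
    stop("metadata missing for genome(s): ",
         paste(gid[is.na(meta$genome_id)], collapse = ", "))
  bad <- !meta$lifestyle %in% lifestyle_levels()
  if (any(bad))
    stop("unknown lifestyle label for genome ", meta$genome_id[which(bad)[1]])
  per <- data.frame(genome_id = gid, lifestyle = meta$lifestyle,
                    n_orfs = meta$n_orfs, n_tfs = colSums(abundance),
                    stringsAsFactors = FALSE)
  per$proportion <- per$n_tfs / per$n_orfs
  summ <- lapply(lifestyle_levels(), function(L) {
    x <- per$proportion[per$lifestyle == L]
    if (length(x) == 0) return(NULL)
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    data.frame(lifestyle = L, n_genomes = length(x),
               median = stats::median(x), min = min(x), max = max(x),
               n_outliers = sum(x < fence[1] | x > fence[2]),
               stringsAsFactors = FALSE)
  })
  list(per_genome = per, summary = do.call(rbind, summ))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of two or more groups with the standard tie
#' correction; the p-value comes from the chi-square approximation with
#' k - 1 degrees of freedom. When every pooled observation is identical the
#' statistic is defined as 0 with p = 1.
#'
#' @param groups List of numeric vectors, each non-empty.
#' @return A list: `h` (tie-corrected statistic), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 1))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  ni <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / ni) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (corr <= 0) 0 else h / corr
  df <- length(groups) - 1
  list(h = h, p_value = stats::pchisq(h, df, lower.tail = FALSE), df = df)
}

#' Per-family, per-lifestyle occurrence rates
#'
#' `rate[f, L]` is the total count of family f across the genomes of
#' lifestyle L divided by those genomes' total ORFs — the rate of occurrence
#' of the family per ORF and per lifestyle. Lifestyles with no genomes are
#' dropped with a warning.
#'
#' @param abundance An `abundance_matrix`.
#' @param genomes Genome metadata.
#' @return Numeric matrix, families x lifestyles.
#' @export
family_lifestyle_rates <- function(abundance, genomes) {
  meta <- genomes[match(colnames(abundance), genomes$genome_id), ]
  labs <- lifestyle_levels()
  present <- labs[labs %in% meta$lifestyle]
  if (length(present) < length(labs))
    warning("lifestyle(s) with zero genomes dropped: ",
            paste(setdiff(labs, present), collapse = ", "))
  m <- vapply(present, function(L) {
    sel <- meta$lifestyle == L
    rowSums(abundance[, sel, drop = FALSE]) / sum(meta$n_orfs[sel])
  }, numeric(nrow(abundance)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(abundance),
                                   dimnames = list(rownames(abundance),
                                                   present))
  m
}

#' Cluster TF families by their lifestyle rate profiles
#'
#' Agglomerative clustering of family rows with Manhattan (L1) distance and
#' average linkage (UPGMA). Rows are scaled to their maximum by default so
#' clustering reflects relative, not absolute, abundance; an
#' uncentered-correlation distance (1 - r about zero) is available as an
#' alternative metric. The dendrogram is returned as an `hclust` object
#' plus a Newick string, with a flat cut into `k` groups.
#'
#' @param rates Families x lifestyles matrix from
#'   [family_lifestyle_rates()].
#' @param metric `"manhattan"` (default) or `"uncentered"`.
#' @param row_scale Divide each row by its maximum before clustering
#'   (zero rows are left as zeros).
#' @param k Number of flat groups to cut (default 4).
#' @return A list: `hclust`, `newick`, `groups` (named membership vector),
#'   `heights`, `metric`, `row_scale`.
#' @export
cluster_families <- function(rates, metric = c("manhattan", "uncentered"),
                             row_scale = TRUE, k = 4) {
  metric <- match.arg(metric)
  stopifnot(nrow(rates) >= 2)
  m <- rates
  if (row_scale) {
    mx <- apply(m, 1, max)
    mx[mx == 0] <- 1
    m <- m / mx
  }
  d <- if (metric == "manhattan") {
    stats::dist(m, method = "manhattan")
  } else {
    # uncentered correlation: cosine of the angle about the origin
    denom <- sqrt(rowSums(m^2))
    denom[denom == 0] <- 1
    s <- (m / denom) %*% t(m / denom)
    stats::as.dist(1 - s)
  }
  hc <- stats::hclust(d, method = "average")
  k <- min(k, nrow(m))
  groups <- stats::cutree(hc, k = k)
  list(hclust = hc, newick = hclust_to_newick(hc), groups = groups,
       heights = hc$height, metric = metric, row_scale = row_scale)
}

#' @keywords internal
hclust_to_newick <- function(hc) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}
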