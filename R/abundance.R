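#' Per-family, per-genome TF abundance matrix
#'
#' Counts, for every family and genome, the number of proteins with at
#' least one DBD assignment of that family. A protein with repeated DBD
#' segments of the same family counts once; a protein carrying DBDs of two
#' different families counts once in each family's row.
#'
#' @param arch Architectures from [assemble_architectures()].
#' @param catalog Family catalog; its families define the row order.
#' @param genomes Genome metadata; its `genome_id`s define the column order
#'   (genomes without any TF get a zero column).
#' @return Integer matrix, families x genomes, of class `c("abundance_matrix",
#'   "matrix")`.
#' @export
count_families <- function(arch, catalog = default_family_catalog(),
                           genomes = NULL) {
  fams <- unique(catalog$family)
  gids <- if (!is.null(genomes)) genomes$genome_id else
    sort(unique(arch$genome_id))
  m <- matrix(0L, nrow = length(fams), ncol = length(gids),
              dimnames = list(fams, gids))
  tf <- arch[!is.na(arch$dbd_family), , drop = FALSE]
  if (nrow(tf) > 0) {
    fam_list <- strsplit(tf$dbd_family, ";", fixed = TRUE)
    gid_rep <- rep(tf$genome_id, lengths(fam_list))
    fam_rep <- unlist(fam_list)
    keep <- fam_rep %in% fams & gid_rep %in% gids
    tab <- table(factor(fam_rep[keep], levels = fams),
                 factor(gid_rep[keep], levels = gids))
    m[] <- as.integer(tab)
  }
  class(m) <- c("abundance_matrix", class(m))
  m
}

#' Normalize one family's abundance counts across genomes
#'
#' Standardizes the per-genome counts `A_i` to the abundance profile
#' `A_n = (A_i - A_avg) / A_sdv`, where `A_avg` and `A_sdv` are the mean
#' and sample (n-1) standard deviation across genomes. A zero-variance
#' family yields an all-zero profile with `degenerate = TRUE` rather than
#' NaNs, so downstream clustering never sees missing values.
#'
#' @param counts Integer (or numeric) vector of per-genome counts,
#'   length >= 2.
#' @return A list of class `abundance_profile`: `a_n`, `a_avg`, `a_sdv`,
#'   `degenerate`.
#' @export
normalize_profile <- function(counts) {
  if (length(counts) < 2) stop("need counts for at least 2 genomes")
  a_avg <- mean(counts)
  a_sdv <- stats::sd(counts)
  if (is.na(a_sdv) || a_sdv == 0) {
    return(structure(list(a_n = rep(0, length(counts)), a_avg = a_avg,
                          a_sdv = 0, degenerate = TRUE),
                     class = "abundance_profile"))
  }
  structure(list(a_n = (counts - a_avg) / a_sdv, a_avg = a_avg,
                 a_sdv = a_sdv, degenerate = FALSE),
            class = "abundance_profile")
}

#' Correlate family abundance with genome size
#'
#' Pearson correlation between per-genome counts (equivalently the
#' normalized profile, to which the correlation is invariant) and genome
#' size in ORFs, classified as `strong` (R >= 0.70), `low` (R < 0.20), or
#' `intermediate` otherwise. Zero variance in either vector gives an
#' `undefined` class with `r = NA`.
#'
#' @param counts Per-genome counts (or normalized profile values).
#' @param n_orfs Per-genome ORF counts, same length.
#' @return A list of class `correlation_class`: `r`, `class`.
#' @export
correlate_size <- function(counts, n_orfs) {
  if (length(counts) != length(n_orfs)) stop("length mismatch")
  if (length(counts) < 3) stop("need at least 3 genomes")
  if (stats::sd(counts) == 0 || stats::sd(n_orfs) == 0)
    return(structure(list(r = NA_real_, class = "undefined"),
                     class = "correlation_class"))
  r <- stats::cor(counts, n_orfs)
  cls <- if (r >= 0.70) "strong" else if (r < 0.20) "low" else "intermediate"
  structure(list(r = r, class = cls), class = "correlation_class")
}

#' Family share of the dataset
#'
#' @param count Family total (may be a vector).
#' @param grand_total Dataset grand total, > 0.
#' @return Percentage(s), `100 * count / grand_total`.
#' @export
family_share <- function(count, grand_total) {
  stopifnot(grand_total > 0)
  100 * count / grand_total
}

#' Mean family members per genome
#'
#' @param count_total Family total across the dataset.
#' @param n_genomes Number of genomes, > 0.
#' @return `count_total / n_genomes`.
#' @export
per_genome_mean <- function(count_total, n_genomes) {
  stopifnot(n_genomes > 0)
  count_total / n_genomes
}

#' Partition families into abundance groups
#'
#' Two modes. `"reference"` returns the fixed four-group membership of the
#' reference dataset ([reference_abundance_groups()]), for the 19 canonical
#' families. `"rank"` orders the families by per-genome mean and places the
#' three group boundaries at the three largest gaps between consecutive
#' ranked means (earliest position wins ties), which recovers e.g. a single
#' dominant family as its own top group in synthetic data. If all means are
#' equal there are no gaps: a single group is returned with `tie = TRUE`.
#'
#' @param means Named numeric vector of per-genome means (one per family).
#' @param mode `"reference"` or `"rank"`.
#' @return A list: `groups` (list of character vectors, most abundant
#'   first), `tie` (logical).
#' @export
abundance_groups <- function(means, mode = c("reference", "rank")) {
  mode <- match.arg(mode)
  if (mode == "reference") {
    ref <- reference_abundance_groups()
    missing <- setdiff(unlist(ref), names(means))
    if (length(missing))
      stop("reference mode needs all 19 families; missing: ",
           paste(missing, collapse = ", "))
    return(list(groups = ref, tie = FALSE))
  }
  ord <- order(means, decreasing = TRUE)
  sorted <- means[ord]
  gaps <- -diff(sorted)
  if (all(gaps <= 0) || length(gaps) < 3)
    return(list(groups = list(group1 = names(sorted)),
                tie = all(gaps <= 0)))
  cutpos <- sort(order(gaps, decreasing = TRUE)[1:3])
  grp <- cut(seq_along(sorted), breaks = c(0, cutpos, length(sorted)),
             labels = FALSE)
  groups <- split(names(sorted), grp)
  names(groups) <- paste0("group", seq_along(groups))
  list(groups = groups, tie = FALSE)
}

#' Table-1-style family summary
#'
#' Combines the census with normalization and size correlation into one row
#' per family: total, percentage share, per-genome mean, Pearson R and its
#' class.
#'
#' @param abundance An `abundance_matrix` from [count_families()].
#' @param genomes Genome metadata (for `n_orfs`).
#' @return A `data.frame` with columns `family`, `total`, `share_pct`,
#'   `per_genome_mean`, `pearson_r`, `correlation_class`.
#' @export
family_summary <- function(abundance, genomes) {
  stopifnot(all(colnames(abundance) %in% genomes$genome_id))
  n_orfs <- genomes$n_orfs[match(colnames(abundance), genomes$genome_id)]
  totals <- rowSums(abundance)
  grand <- sum(totals)
  res <- lapply(rownames(abundance), function(f) {
    cc <- tryCatch(correlate_size(abundance[f, ], n_orfs),
                   error = function(e) list(r = NA_real_, class = "undefined"))
    data.frame(family = f, total = unname(totals[f]),
               share_pct = if (grand > 0) family_share(totals[[f]], grand)
                           else NA_real_,
               per_genome_mean = per_genome_mean(totals[[f]],
                                                 ncol(abundance)),
               pearson_r = cc$r, correlation_class = cc$class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
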