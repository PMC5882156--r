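#' One-tailed Fisher's exact test (enrichment direction)
#'
#' Upper-tail hypergeometric probability `P(X >= a)` for the 2x2 table
#' `(a, b; c, d)` with fixed margins: the probability, under independence,
#' of seeing at least `a` family proteins carrying the CD.
#'
#' @param a Family TFs containing the CD.
#' @param b Family TFs lacking it.
#' @param c Other TFs containing the CD.
#' @param d Other TFs lacking it.
#' @return The one-tailed p-value.
#' @export
fisher_one_tail <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (a + b + c + d < 1) stop("empty table")
  # X ~ Hypergeometric(white = a + c, black = b + d, drawn = a + b)
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj(i) = min over j >= rank(i) of (m / j) * p_(j)`, capped at 1;
#' preserves the order of the input vector.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) ||
      any(is.na(p_values)))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
  adj
}

#' DBD-CD enrichment across all families
#'
#' For every (family, CD) pair observed at least once, builds the 2x2 table
#' over the TF-protein universe (the counting unit is the protein: a CD
#' occurring twice in one protein counts once), runs the one-tailed Fisher
#' test, and applies Benjamini-Hochberg jointly across all tests. A pair is
#' `enriched` when its adjusted p-value (or the raw one, when
#' `threshold_on = "raw"`) is at or below `alpha`; a CD is `unique` to a
#' family when no other family's protein carries it.
#'
#' @param arch Architectures from [assemble_architectures()].
#' @param catalog Family catalog.
#' @param alpha Significance threshold (default `1e-10`).
#' @param threshold_on `"adjusted"` (default) or `"raw"`.
#' @param adjacency CD attribution mode: `"all"` (default; every non-DBD
#'   segment of the protein) or `"adjacent"`.
#' @return A `data.frame` of class `enrichment_result`: family, cd_model,
#'   a, b, c, d, p_raw, p_adj, enriched, unique.
#' @export
enrich_all <- function(arch, catalog = default_family_catalog(),
                       alpha = 1e-10,
                       threshold_on = c("adjusted", "raw"),
                       adjacency = c("all", "adjacent")) {
  threshold_on <- match.arg(threshold_on)
  adjacency <- match.arg(adjacency)
  tf <- arch[!is.na(arch$dbd_family) & arch$n_families == 1L, , drop = FALSE]
  if (nrow(tf) == 0) stop("no TFs available for enrichment")
  n_univ <- nrow(tf)
  cd_of_protein <- if (adjacency == "all") {
    lapply(strsplit(tf$cd_models, ";", fixed = TRUE),
           function(x) x[!is.na(x)])
  } else {
    lapply(seq_len(nrow(tf)), function(i) {
      models <- strsplit(tf$arch[i], "+", fixed = TRUE)[[1]]
      dbd_idx <- as.integer(strsplit(tf$dbd_index[i], ";", fixed = TRUE)[[1]])
      nb <- unique(c(dbd_idx - 1L, dbd_idx + 1L))
      nb <- nb[nb >= 1 & nb <= length(models) & !nb %in% dbd_idx]
      unique(models[nb])
    })
  }
  fam_of_protein <- tf$dbd_family
  # proteins per CD across the whole universe
  cd_long <- data.frame(protein = rep(seq_len(nrow(tf)),
                                      lengths(cd_of_protein)),
                        cd = unlist(cd_of_protein),
                        stringsAsFactors = FALSE)
  if (nrow(cd_long) == 0) stop("no companion domains observed")
  cd_long$family <- fam_of_protein[cd_long$protein]
  cd_total <- table(cd_long$cd)
  fam_total <- table(factor(fam_of_protein, levels = unique(catalog$family)))
  pair_count <- stats::aggregate(protein ~ family + cd, cd_long,
                                 function(x) length(unique(x)))
  names(pair_count)[3] <- "a"
  res <- pair_count
  res$fam_n <- as.integer(fam_total[res$family])
  res$cd_n <- as.integer(cd_total[res$cd])
  res$b <- res$fam_n - res$a
  res$c <- res$cd_n - res$a
  res$d <- n_univ - res$fam_n - res$c
  res$p_raw <- mapply(fisher_one_tail, res$a, res$b, res$c, res$d)
  res$p_adj <- bh_adjust(res$p_raw)
  res$enriched <- (if (threshold_on == "adjusted") res$p_adj else
                     res$p_raw) <= alpha
  res$unique <- res$c == 0L
  out <- res[order(res$family, res$p_adj, res$cd),
             c("family", "cd", "a", "b", "c", "d", "p_raw", "p_adj",
               "enriched", "unique")]
  names(out)[2] <- "cd_model"
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Enriched CD sets per family
#'
#' @param enrichment An `enrichment_result` from [enrich_all()].
#' @param families Families to report (default: all in the result).
#' @return Named list of character vectors of enriched CD models (possibly
#'   empty).
#' @export
enriched_cd_sets <- function(enrichment,
                             families = unique(enrichment$family)) {
  sets <- lapply(families, function(f)
    enrichment$cd_model[enrichment$family == f & enrichment$enriched])
  stats::setNames(sets, families)
}
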