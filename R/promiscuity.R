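#' Companion-domain repertoire of one family
#'
#' For each protein carrying the family's DBD, partner domains are taken
#' either as the segments immediately adjacent (N- and C-terminal
#' neighbours in linear order) to each DBD segment (`"adjacent"`, the
#' default used by the per-genome diversity count f_d) or as every non-DBD
#' segment on the protein (`"all"`, which matches dataset-wide distinct-CD
#' tallies). Proteins carrying DBDs of two or more families are excluded
#' from the pooling so no CD is attributed twice.
#'
#' @param arch Architectures from [assemble_architectures()].
#' @param family Family name.
#' @param adjacency `"adjacent"` or `"all"`.
#' @return A list: `per_genome` (`data.frame` genome_id, f_d), `partner_sets`
#'   (named list of per-genome partner model sets), `global` (character
#'   vector of all distinct non-DBD models on the family's proteins),
#'   `adjacency_counts` (named integer vector of partner occurrences).
#' @export
extract_cds <- function(arch, family, adjacency = c("adjacent", "all")) {
  adjacency <- match.arg(adjacency)
  has_fam <- !is.na(arch$dbd_family) &
    vapply(strsplit(arch$dbd_family, ";", fixed = TRUE),
           function(f) family %in% f, TRUE)
  members <- arch[has_fam & arch$n_families == 1L, , drop = FALSE]
  all_members <- arch[has_fam, , drop = FALSE]
  partner_by_genome <- list()
  partner_counts <- integer(0)
  if (nrow(members) > 0) {
    for (i in seq_len(nrow(members))) {
      models <- strsplit(members$arch[i], "+", fixed = TRUE)[[1]]
      dbd_idx <- as.integer(strsplit(members$dbd_index[i], ";",
                                     fixed = TRUE)[[1]])
      partners <- if (adjacency == "adjacent") {
        nb <- unique(c(dbd_idx - 1L, dbd_idx + 1L))
        nb <- nb[nb >= 1 & nb <= length(models) & !nb %in% dbd_idx]
        unique(models[nb])
      } else {
        unique(models[-dbd_idx])
      }
      if (length(partners)) {
        g <- members$genome_id[i]
        partner_by_genome[[g]] <- c(partner_by_genome[[g]], partners)
        for (p in partners)
          partner_counts[p] <- (if (is.na(partner_counts[p][1])) 0L
                                else partner_counts[p]) + 1L
      }
    }
    partner_by_genome <- lapply(partner_by_genome, unique)
  }
  global <- unique(unlist(lapply(strsplit(all_members$cd_models, ";",
                                          fixed = TRUE),
                                 function(x) x[!is.na(x)])))
  gids <- unique(all_members$genome_id)
  per_genome <- data.frame(
    genome_id = gids,
    f_d = vapply(gids, function(g)
      length(partner_by_genome[[g]] %||% character(0)), 1L),
    stringsAsFactors = FALSE)
  list(per_genome = per_genome, partner_sets = partner_by_genome,
       global = global, adjacency_counts = partner_counts)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse abundance frequency
#'
#' `IAF(d) = log2(P_t / P_d)`: high when the domain is rare in the genome.
#'
#' @param p_t Total proteins in the genome (positive integer).
#' @param p_d Proteins containing the domain, `1 <= p_d <= p_t`.
#' @return IAF in bits.
#' @export
iaf <- function(p_t, p_d) {
  stopifnot(all(p_t >= 1), all(p_d >= 1), all(p_d <= p_t))
  log2(p_t / p_d)
}

#' Inverse variability
#'
#' `IV(d) = 1 / f_d`, the reciprocal of the number of distinct partner
#' domain families adjacent to the domain. A domain with no partners at all
#' (`f_d = 0`, the DBD-only case) takes IV = 1 so that WS = IAF, its
#' maximum for the given abundance — consistent with high scores marking
#' absence of architectural diversity.
#'
#' @param f_d Non-negative integer count of distinct partner families.
#' @return IV in (0, 1].
#' @export
iv <- function(f_d) {
  if (any(f_d < 0)) stop("f_d must be non-negative")
  ifelse(f_d == 0, 1, 1 / f_d)
}

#' Weighted domain-architecture score
#'
#' `WS = IAF x IV`. Values close to 0 mark promiscuous domains (abundant
#' and/or architecture-diverse); high values mark monolithic ones.
#'
#' @param iaf_value IAF in bits.
#' @param iv_value IV, dimensionless.
#' @return WS.
#' @export
ws <- function(iaf_value, iv_value) iaf_value * iv_value

#' Per-family, per-genome promiscuity score table
#'
#' For every family and every genome where the family is present, computes
#' `P_t` (genome size in proteins, taken from metadata `n_orfs`), `P_d`
#' (proteins carrying the family DBD), `f_d` (distinct partner domains in
#' that genome, immediate-adjacency mode by default), and IAF, IV, WS.
#' Genomes where the family is absent yield no row.
#'
#' @param arch Architectures.
#' @param genomes Genome metadata.
#' @param catalog Family catalog (defines the family set).
#' @param adjacency Passed to [extract_cds()].
#' @return A `data.frame`: family, genome_id, p_t, p_d, f_d, iaf, iv, ws.
#' @export
ws_table <- function(arch, genomes, catalog = default_family_catalog(),
                     adjacency = c("adjacent", "all")) {
  adjacency <- match.arg(adjacency)
  abund <- count_families(arch, catalog, genomes)
  out <- lapply(unique(catalog$family), function(fam) {
    cds <- extract_cds(arch, fam, adjacency)
    present <- colnames(abund)[abund[fam, ] > 0]
    if (length(present) == 0) return(NULL)
    p_d <- abund[fam, present]
    p_t <- genomes$n_orfs[match(present, genomes$genome_id)]
    f_d <- cds$per_genome$f_d[match(present, cds$per_genome$genome_id)]
    f_d[is.na(f_d)] <- 0L
    iafs <- iaf(p_t, p_d)
    ivs <- iv(f_d)
    data.frame(family = fam, genome_id = present, p_t = p_t,
               p_d = as.integer(p_d), f_d = as.integer(f_d),
               iaf = iafs, iv = ivs, ws = ws(iafs, ivs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Families x genomes WS matrix
#'
#' Spreads a [ws_table()] into a matrix with one row per family and one
#' column per genome, mirroring the deposited per-genome score-table
#' layout: genomes where a family is absent carry WS = 0. This is the
#' vector on which the per-family coefficient of variation is computed, so
#' rarity and architectural uniformity both contribute to CV, as in the
#' reference dataset where the monolithic families are also the rare ones.
#'
#' @param ws_tbl Output of [ws_table()].
#' @param families Row order (default: families present in the table).
#' @param genomes Column order: metadata `data.frame` or character vector.
#' @param absent_as_zero Fill value handling; `FALSE` uses `NA` instead.
#' @return Numeric matrix families x genomes.
#' @export
ws_matrix <- function(ws_tbl, families = unique(ws_tbl$family),
                      genomes = unique(ws_tbl$genome_id),
                      absent_as_zero = TRUE) {
  gids <- if (is.data.frame(genomes)) genomes$genome_id else genomes
  m <- matrix(if (absent_as_zero) 0 else NA_real_,
              nrow = length(families), ncol = length(gids),
              dimnames = list(families, gids))
  keep <- ws_tbl$family %in% families & ws_tbl$genome_id %in% gids
  t <- ws_tbl[keep, ]
  m[cbind(t$family, t$genome_id)] <- t$ws
  m
}

#' Sturges binning of genome sizes
#'
#' `k = round(1 + log2(N))` equal-width classes of width `c = R / k` where
#' `R` is the genome-size range. Bins are left-closed, right-open, with the
#' last bin closed, so every genome falls in exactly one bin.
#'
#' @param n_orfs Vector of genome sizes (>= 2 distinct values).
#' @return A list of class `binning_scheme`: `k`, `n`, `width`, `range`,
#'   `edges` (length k + 1), `bin` (per-genome bin index).
#' @export
bin_genomes <- function(n_orfs) {
  n <- length(n_orfs)
  if (length(unique(n_orfs)) < 2) stop("all genome sizes equal: zero range")
  k <- as.integer(round(1 + log2(n)))
  r <- max(n_orfs) - min(n_orfs)
  width <- r / k
  edges <- min(n_orfs) + (0:k) * width
  bin <- pmin(floor((n_orfs - min(n_orfs)) / width) + 1L, k)
  structure(list(k = k, n = n, width = width, range = r, edges = edges,
                 bin = as.integer(bin)), class = "binning_scheme")
}

#' Classify a family's promiscuity from its WS dispersion
#'
#' The coefficient of variation CV = sd(WS) / mean(WS) (sample sd) over the
#' genome vector. Default boundaries assign every CV: below 1.55 highly
#' promiscuous, 1.55 to 3.0 intermediate, at or above 3.0 monolithic — the
#' midpoints of the gaps between the published class ranges (0.9-1.36,
#' 1.74-2.5, 3.5-4.5). `strict = TRUE` uses those printed ranges verbatim
#' and labels values falling in the gaps `"unclassified"`.
#'
#' @param ws_values Per-genome WS vector (length >= 2), zeros included for
#'   genomes lacking the family (see [ws_matrix()]).
#' @param strict Use the printed ranges instead of the gap midpoints.
#' @return A list of class `promiscuity_class`: `cv`, `class`.
#' @export
classify_promiscuity <- function(ws_values, strict = FALSE) {
  stopifnot(length(ws_values) >= 2)
  m <- mean(ws_values)
  if (m == 0)
    return(structure(list(cv = NA_real_, class = "undefined"),
                     class = "promiscuity_class"))
  cv <- stats::sd(ws_values) / m
  cls <- if (strict) {
    if (cv >= 0.9 && cv <= 1.36) "highly_promiscuous"
    else if (cv >= 1.74 && cv <= 2.5) "intermediate"
    else if (cv >= 3.5 && cv <= 4.5) "monolithic"
    else if (cv < 0.9) "highly_promiscuous"
    else "unclassified"
  } else {
    if (cv < 1.55) "highly_promiscuous"
    else if (cv < 3.0) "intermediate"
    else "monolithic"
  }
  structure(list(cv = cv, class = cls), class = "promiscuity_class")
}

#' Architecture-class census of the TF collection
#'
#' Fractions of TFs (proteins with a DBD assignment) that are monodomain,
#' two-domain, and multidomain (three or more segments).
#'
#' @param arch Architectures.
#' @return Named numeric vector `monodomain`, `two-domain`, `multidomain`,
#'   summing to 1.
#' @export
architecture_census <- function(arch) {
  tf <- arch[!is.na(arch$dbd_family), , drop = FALSE]
  if (nrow(tf) == 0) stop("no TFs in the architecture set")
  tab <- table(factor(tf$arch_class,
                      levels = c("monodomain", "two-domain", "multidomain")))
  stats::setNames(as.numeric(tab) / nrow(tf), names(tab))
}

#' CD-sharing matrix between families
#'
#' `S[a, b]` is the fraction of family a's enriched CDs that are also
#' enriched in family b. The matrix is not symmetric; a family with no
#' enriched CDs yields an all-`NA` row.
#'
#' @param enriched_sets Named list of character vectors: each family's
#'   enriched CD models.
#' @return Numeric matrix, families x families, values in `[0, 1]` or `NA`.
#' @export
cd_sharing <- function(enriched_sets) {
  fams <- names(enriched_sets)
  s <- matrix(NA_real_, length(fams), length(fams),
              dimnames = list(fams, fams))
  for (a in fams) {
    ea <- enriched_sets[[a]]
    if (length(ea) == 0) next
    for (b in fams)
      s[a, b] <- length(intersect(ea, enriched_sets[[b]])) / length(ea)
  }
  s
}
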