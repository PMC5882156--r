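#' Default per-family parameters for the synthetic generator
#'
#' One row per TF family with the knobs the generator uses. Defaults emulate
#' the reference dataset: `base_rate` (expected TF count per genome at the
#' mid-range genome size, divided by 1000 ORFs) is derived from the printed
#' family totals over 761 genomes; `size_slope` is the printed abundance vs
#' genome-size Pearson correlation; `cd_pool_size` is the printed number of
#' distinct CDs; `cd_concentration` encodes the family's promiscuity class
#' (low = promiscuous, CD usage spread over the pool; high = monolithic, one
#' dominant CD); `p_monodomain` and `p_second_cd` reproduce the 32% / 59% /
#' 9% monodomain / two-domain / multidomain architecture census.
#'
#' @param orf_range Genome-size range (ORFs) the rates are calibrated to.
#' @return A `data.frame` keyed by `family`.
#' @export
default_family_params <- function(orf_range = c(500, 9696)) {
  tab <- tf_family_table()
  groups <- reference_promiscuity_groups()
  conc <- ifelse(tab$family %in% groups$highly_promiscuous, 0.25,
                 ifelse(tab$family %in% groups$intermediate, 1.0, 4.0))
  mid_korf <- mean(orf_range) / 1000
  data.frame(
    family = tab$family,
    base_rate = (tab$total / 761) / mid_korf,
    size_slope = tab$pearson_r,
    cd_pool_size = tab$n_cds,
    cd_concentration = conc,
    p_monodomain = 0.32,
    p_second_cd = 0.09 / 0.68,
    cd_len_mean = tab$cd_len_mean,
    cd_len_sd = tab$cd_len_sd,
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-dataset configuration
#'
#' The stated world of the generator: 761 genomes spanning 500-9696 ORFs
#' (range 9196, i.e. eleven Sturges windows of 836 ORFs), a lifestyle mix of
#' 368 free-living / 187 pathogen / 158 extremophile / 48 intracellular,
#' lifestyle multipliers on total TF rate of 1.0 / 0.8 / 0.7 / 0.35, a
#' bacteria:archaea split of 672:89, negative-binomial family counts
#' (dispersion `nb_size`), and the per-family defaults of
#' [default_family_params()].
#'
#' @param n_genomes Number of genomes.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @param orf_range Length-2 integer vector, min and max ORFs per genome.
#' @param lifestyle_mix Named proportions over the four lifestyle labels
#'   (must sum to 1).
#' @param lifestyle_multiplier Named multipliers applied to every family's
#'   expected count, by lifestyle.
#' @param families Per-family parameter table as
#'   [default_family_params()]; may contain any subset of families.
#' @param planted_enrichments Optional `data.frame` with columns `family`,
#'   `cd_model`: these CDs receive boosted sampling weight inside their
#'   family and depressed weight elsewhere.
#' @param nb_size Negative-binomial dispersion parameter (smaller = more
#'   overdispersed).
#' @param n_cd_universe Number of distinct CD models in the global pool.
#' @param bacteria_fraction Fraction of genomes labelled bacterial
#'   (remainder archaeal); default 672/761.
#' @return A list of class `tf_synth_config`.
#' @export
synthetic_config <- function(n_genomes = 761L,
                             seed = 1L,
                             orf_range = c(500L, 9696L),
                             lifestyle_mix = c("free-living" = 368,
                                               "pathogen" = 187,
                                               "extremophile" = 158,
                                               "intracellular" = 48) / 761,
                             lifestyle_multiplier = c("free-living" = 1.0,
                                                      "pathogen" = 0.8,
                                                      "extremophile" = 0.7,
                                                      "intracellular" = 0.35),
                             families = default_family_params(orf_range),
                             planted_enrichments = NULL,
                             nb_size = 10,
                             n_cd_universe = 457L,
                             bacteria_fraction = 672 / 761) {
  if (orf_range[1] > orf_range[2])
    stop("degenerate orf_range: min > max")
  if (abs(sum(lifestyle_mix) - 1) > 1e-9)
    stop("lifestyle_mix must sum to 1")
  if (!setequal(names(lifestyle_mix), lifestyle_levels()))
    stop("lifestyle_mix must be named by the four lifestyle labels")
  stopifnot(n_genomes >= 1, all(families$base_rate >= 0),
            all(families$cd_pool_size >= 1), n_cd_universe >= 1)
  structure(list(n_genomes = as.integer(n_genomes), seed = as.integer(seed),
                 orf_range = as.integer(orf_range),
                 lifestyle_mix = lifestyle_mix[lifestyle_levels()],
                 lifestyle_multiplier = lifestyle_multiplier[lifestyle_levels()],
                 families = families,
                 planted_enrichments = planted_enrichments,
                 nb_size = nb_size, n_cd_universe = as.integer(n_cd_universe),
                 bacteria_fraction = bacteria_fraction),
            class = "tf_synth_config")
}

# Symmetric-Dirichlet CD usage weights. `conc` is the promiscuity knob:
# low -> near-uniform usage (promiscuous), high -> dominated by few CDs
# (monolithic). Internally the Dirichlet alpha is 1/conc.
#' @keywords internal
cd_usage_weights <- function(k, conc) {
  if (k == 1) return(1)
  if (conc <= 1e-8) return(rep(1 / k, k))
  g <- stats::rgamma(k, shape = 1 / conc) + 1e-12  # keep every CD reachable
  g / sum(g)
}

#' Generate a synthetic comparative-genomics dataset
#'
#' Draws genomes (size, lifestyle, taxon), per-family TF counts, and
#' per-protein domain architectures, and renders them as per-genome
#' assignment tables in the canonical dialect. For genome g and family f the
#' expected count is
#' `base_rate * (mid_orfs/1000) * max(0, 1 + size_slope * z_g) * m(lifestyle_g)`
#' where `z_g` is the standardized genome size and `m` the lifestyle
#' multiplier; counts are negative binomial around that mean, so
#' `size_slope = 0` plants no abundance-size correlation and
#' `size_slope = 1` a strong one. Each TF is monodomain with probability
#' `p_monodomain`, otherwise carries 1-2 CDs drawn from the family's CD pool
#' with Dirichlet-weighted usage (see [cd_usage_weights()]); planted
#' (family, CD) enrichments get 60% of their family's sampling mass and a
#' 50-fold depressed weight in other families.
#'
#' @param config A `tf_synth_config` from [synthetic_config()].
#' @return A list of class `tf_synth_dataset`: `genomes` (metadata
#'   `data.frame` with an extra `taxon` column), `hits` (named list of hit
#'   tables, one per genome), `catalog` (family catalog used), and `truth`
#'   (ledger of every planted quantity; see [truth_report()]).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "tf_synth_config"))
  set.seed(config$seed)
  n <- config$n_genomes
  fams <- config$families
  catalog <- default_family_catalog()
  catalog <- catalog[catalog$family %in% fams$family, , drop = FALSE]
  missing_dbd <- setdiff(fams$family, catalog$family)
  if (length(missing_dbd))
    catalog <- rbind(catalog, data.frame(
      family = missing_dbd,
      model_id = paste0("DBD.", gsub("[^A-Za-z0-9]", "_", missing_dbd))))
  dbd_of <- stats::setNames(catalog$model_id, catalog$family)

  genome_id <- sprintf("G%04d", seq_len(n))
  n_orfs <- as.integer(round(stats::runif(n, config$orf_range[1],
                                          config$orf_range[2])))
  lifestyle <- sample(lifestyle_levels(), n, replace = TRUE,
                      prob = config$lifestyle_mix)
  n_bact <- round(n * config$bacteria_fraction)
  taxon <- rep(c("Bacteria", "Archaea"), c(n_bact, n - n_bact))
  genomes <- data.frame(genome_id = genome_id,
                        organism = paste(taxon, "sp.", seq_len(n)),
                        n_orfs = n_orfs, lifestyle = lifestyle,
                        taxon = taxon, stringsAsFactors = FALSE)

  sd_orf <- stats::sd(n_orfs)
  z <- if (is.na(sd_orf) || sd_orf == 0) rep(0, n) else
    (n_orfs - mean(n_orfs)) / sd_orf
  mid_korf <- mean(config$orf_range) / 1000
  mult <- config$lifestyle_multiplier[lifestyle]

  # global CD universe and per-family pools with usage weights
  universe <- sprintf("SSF%05d", 10000 + seq_len(config$n_cd_universe))
  planted <- config$planted_enrichments
  pools <- list(); weights <- list()
  for (i in seq_len(nrow(fams))) {
    fam <- fams$family[i]
    k <- min(fams$cd_pool_size[i], config$n_cd_universe)
    pool <- sample(universe, k)
    if (!is.null(planted)) {
      extra <- setdiff(planted$cd_model[planted$family == fam], pool)
      pool <- c(extra, pool)[seq_len(max(k, length(extra)))]
    }
    w <- cd_usage_weights(length(pool), fams$cd_concentration[i])
    w <- sort(w, decreasing = TRUE)  # rank-aligned: first pool entries dominate
    if (!is.null(planted)) {
      own <- pool %in% planted$cd_model[planted$family == fam]
      if (any(own)) {
        w[own] <- 0.6 / sum(own) * sum(w)
        w[!own] <- w[!own] / sum(w[!own]) * 0.4
        w <- w / sum(w)
      }
      foreign <- pool %in% setdiff(planted$cd_model, planted$cd_model[planted$family == fam])
      if (any(foreign) && sum(w[!foreign]) > 0) {
        w[foreign] <- w[foreign] * 0.02
        w <- w / sum(w)
      }
    }
    pools[[fam]] <- pool; weights[[fam]] <- w
  }

  mu_mat <- matrix(0, nrow = nrow(fams), ncol = n,
                   dimnames = list(fams$family, genome_id))
  count_mat <- mu_mat
  hits <- vector("list", n); names(hits) <- genome_id
  truth_rows <- vector("list", n * nrow(fams)); tr <- 0L

  for (g in seq_len(n)) {
    gid <- genome_id[g]
    acc <- list(); pid_counter <- 0L
    for (i in seq_len(nrow(fams))) {
      fam <- fams$family[i]
      mu <- fams$base_rate[i] * mid_korf *
        max(0, 1 + fams$size_slope[i] * z[g]) * mult[g]
      cnt <- stats::rnbinom(1, mu = mu, size = config$nb_size)
      mu_mat[i, g] <- mu; count_mat[i, g] <- cnt
      fam_cds <- character(0); n_arch <- c(mono = 0L, two = 0L, multi = 0L)
      if (cnt > 0) {
        pool <- pools[[fam]]; w <- weights[[fam]]
        # vectorized over the cnt TFs of this family in this genome
        n_cds <- ifelse(stats::runif(cnt) < fams$p_monodomain[i], 0L,
                        1L + stats::rbinom(cnt, 1, fams$p_second_cd[i]))
        n_cds <- pmin(n_cds, length(pool))
        cd1 <- character(cnt); cd2 <- character(cnt)
        has1 <- n_cds >= 1L; has2 <- n_cds >= 2L
        if (any(has1))
          cd1[has1] <- sample(pool, sum(has1), replace = TRUE, prob = w)
        for (t in which(has2)) {  # second CD is distinct from the first
          excl <- pool != cd1[t]
          cd2[t] <- if (sum(excl) == 1) pool[excl] else
            sample(pool[excl], 1, prob = w[excl])
        }
        fam_cds <- c(cd1[has1], cd2[has2])
        n_arch <- c(mono = sum(n_cds == 0L), two = sum(n_cds == 1L),
                    multi = sum(n_cds >= 2L))
        n_seg <- n_cds + 1L
        dbd_pos <- 1L + floor(stats::runif(cnt) * n_seg)
        prot <- rep(seq_len(cnt), n_seg)
        seg <- sequence(n_seg)
        is_dbd <- seg == dbd_pos[prot]
        models <- character(length(seg))
        models[is_dbd] <- dbd_of[[fam]]
        first_cd <- !is_dbd & (seg == 1L | (seg == 2L & dbd_pos[prot] == 1L))
        models[first_cd] <- cd1[prot[first_cd]]
        second_cd <- !is_dbd & !first_cd
        models[second_cd] <- cd2[prot[second_cd]]
        lens <- integer(length(seg))
        lens[is_dbd] <- pmax(40L, as.integer(round(
          stats::rnorm(sum(is_dbd), 70, 15))))
        if (any(!is_dbd))
          lens[!is_dbd] <- pmax(30L, as.integer(round(stats::rnorm(
            sum(!is_dbd), fams$cd_len_mean[i], fams$cd_len_sd[i]))))
        gaps <- sample.int(20L, length(seg), replace = TRUE)
        cs <- cumsum(gaps + lens)
        offset <- c(0, cs[cumsum(n_seg)])[prot]
        ends <- as.integer(cs - offset)
        starts <- as.integer(ends - lens + 1L)
        pid <- sprintf("%s_p%05d", gid, pid_counter + prot)
        pid_counter <- pid_counter + cnt
        acc[[length(acc) + 1L]] <- data.frame(
          genome_id = gid, protein_id = pid, model_id = models,
          start = starts, end = ends,
          e_value = 10^-stats::runif(length(seg), 4, 20),
          model_description = ifelse(is_dbd,
                                     paste(fam, "DNA-binding domain"),
                                     "companion domain"),
          family_id = ifelse(is_dbd, fam, NA_character_),
          family_e_value = ifelse(is_dbd,
                                  10^-stats::runif(length(seg), 5, 25),
                                  NA_real_),
          coverage = ifelse(is_dbd, stats::runif(length(seg), 0.62, 1),
                            NA_real_),
          pdb_ref = NA_character_, stringsAsFactors = FALSE)
      }
      tr <- tr + 1L
      truth_rows[[tr]] <- data.frame(
        genome_id = gid, family = fam, planted_mu = mu, count = cnt,
        n_monodomain = n_arch[["mono"]], n_two_domain = n_arch[["two"]],
        n_multidomain = n_arch[["multi"]],
        n_distinct_cds = length(unique(fam_cds)),
        size_slope = fams$size_slope[i],
        cd_concentration = fams$cd_concentration[i],
        planted_cds = if (!is.null(planted) &&
                          any(planted$family == fam))
          paste(planted$cd_model[planted$family == fam], collapse = ";")
        else NA_character_,
        stringsAsFactors = FALSE)
    }
    hits[[gid]] <- if (length(acc)) do.call(rbind, acc) else empty_hits()
    rownames(hits[[gid]]) <- NULL
  }

  truth <- list(config = config,
                per_genome_family = do.call(rbind, truth_rows),
                pools = pools, weights = weights,
                z = stats::setNames(z, genome_id))
  rownames(truth$per_genome_family) <- NULL
  structure(list(genomes = genomes, hits = hits, catalog = catalog,
                 truth = truth),
            class = "tf_synth_dataset")
}

#' Render the truth ledger as a machine-readable table
#'
#' One row per genome and family with every planted quantity: the expected
#' count, the realized count, realized architecture-class tallies, distinct
#' CDs used, the planted size slope and CD concentration, and any planted
#' enrichment CDs (flagged in `planted_cds`).
#'
#' @param ledger The `truth` element of a [generate_dataset()] result (or
#'   the dataset itself).
#' @param path Optional path; when given, the table is written as TSV.
#' @return The truth `data.frame`, invisibly when `path` is given.
#' @export
truth_report <- function(ledger, path = NULL) {
  if (inherits(ledger, "tf_synth_dataset")) ledger <- ledger$truth
  df <- ledger$per_genome_family
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(df)
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits `metadata.tsv`, `catalog.tsv`, `truth.tsv`, and one assignment
#' table `<genome_id>.tsv` per genome. Output is byte-identical across runs
#' with the same configuration.
#'
#' @param dataset A `tf_synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tf_synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_metadata(dataset$genomes, file.path(dir, "metadata.tsv"))
  utils::write.table(dataset$catalog, file.path(dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_report(dataset$truth, file.path(dir, "truth.tsv"))
  for (gid in names(dataset$hits))
    write_assignment_file(dataset$hits[[gid]],
                          file.path(dir, paste0(gid, ".tsv")))
  invisible(dir)
}
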