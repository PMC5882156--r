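#' Assemble a pipeline configuration
#'
#' Paths, thresholds and mode switches for an end-to-end run. Defaults are
#' the thresholds of the reference analysis: DBD hits at family E-value
#' <= 1e-4 and model coverage >= 60%, companion-domain hits at E-value
#' <= 1e-3, enrichment at BH-adjusted p <= 1e-10.
#'
#' @param input_dir Directory of per-genome assignment tables
#'   (`<genome_id>.tsv`).
#' @param out_dir Output directory.
#' @param metadata,catalog Paths to the metadata and family-catalog TSVs
#'   (default: inside `input_dir`).
#' @param dbd_e_max,dbd_min_cov,sf_e_max,enrich_alpha Thresholds.
#' @param fd_adjacency Partner-domain mode for f_d: `"adjacent"` or
#'   `"all"`.
#' @param enrich_adjacency CD attribution for enrichment: `"all"` or
#'   `"adjacent"`.
#' @param cv_strict Use the printed CV class ranges (gap values become
#'   `"unclassified"`).
#' @param cluster_metric `"manhattan"` or `"uncentered"`.
#' @param group_mode Abundance grouping: `"rank"` or `"reference"`.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `tf_pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            metadata = file.path(input_dir, "metadata.tsv"),
                            catalog = file.path(input_dir, "catalog.tsv"),
                            dbd_e_max = 1e-4, dbd_min_cov = 0.60,
                            sf_e_max = 1e-3, enrich_alpha = 1e-10,
                            fd_adjacency = "adjacent",
                            enrich_adjacency = "all",
                            cv_strict = FALSE,
                            cluster_metric = "manhattan",
                            group_mode = "rank",
                            seed = 1L) {
  stopifnot(dbd_e_max > 0, sf_e_max > 0, enrich_alpha > 0,
            dbd_min_cov >= 0, dbd_min_cov <= 1)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 metadata = metadata, catalog = catalog,
                 dbd_e_max = dbd_e_max, dbd_min_cov = dbd_min_cov,
                 sf_e_max = sf_e_max, enrich_alpha = enrich_alpha,
                 fd_adjacency = fd_adjacency,
                 enrich_adjacency = enrich_adjacency,
                 cv_strict = cv_strict, cluster_metric = cluster_metric,
                 group_mode = group_mode, seed = as.integer(seed)),
            class = "tf_pipeline_config")
}

# 32-bit FNV-1a over the deparsed analysis parameters (paths excluded, so
# the same analysis in a different location keeps the same fingerprint);
# stamped into every output so a TSV can be traced to the run's settings.
#' @keywords internal
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[setdiff(names(cfg),
                     c("input_dir", "out_dir", "metadata", "catalog"))]
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (16777619 * lo + ((16777619 * hi) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' @keywords internal
write_stage_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate pipeline inputs without running the pipeline
#'
#' Checks file presence, header conformity, the closed lifestyle
#' vocabulary, genomes present in hit files but absent from metadata (and
#' vice versa), and duplicate protein ids. Non-fatal issues are reported,
#' never raised.
#'
#' @param config A `tf_pipeline_config`.
#' @return A `data.frame` of issues: `level` (`"error"`/`"warning"`),
#'   `message`. Zero rows means a clean input set.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  add <- function(level, msg)
    issues[[length(issues) + 1]] <<- data.frame(level = level,
                                                message = msg,
                                                stringsAsFactors = FALSE)
  if (!dir.exists(config$input_dir))
    add("error", paste("input directory missing:", config$input_dir))
  meta <- NULL
  if (!file.exists(config$metadata)) {
    add("error", paste("metadata file missing:", config$metadata))
  } else {
    raw <- utils::read.delim(config$metadata, stringsAsFactors = FALSE,
                             comment.char = "#")
    need <- c("genome_id", "organism", "n_orfs", "lifestyle")
    if (!all(need %in% names(raw))) {
      add("error", paste("metadata lacks column(s):",
                         paste(setdiff(need, names(raw)), collapse = ", ")))
    } else {
      meta <- raw
      bad <- unique(raw$lifestyle[!raw$lifestyle %in% lifestyle_levels()])
      for (b in bad)
        add("error", paste0("lifestyle label outside the closed ",
                            "vocabulary: '", b, "'"))
      if (anyDuplicated(raw$genome_id))
        add("error", "duplicate genome_id in metadata")
    }
  }
  if (!file.exists(config$catalog))
    add("error", paste("family catalog missing:", config$catalog))
  if (dir.exists(config$input_dir)) {
    files <- list.files(config$input_dir, pattern = "\\.tsv$")
    files <- setdiff(files, c("metadata.tsv", "catalog.tsv", "truth.tsv"))
    hit_genomes <- sub("\\.tsv$", "", files)
    if (!is.null(meta)) {
      for (g in setdiff(hit_genomes, meta$genome_id))
        add("warning", paste("hit file without metadata row:", g))
      for (g in setdiff(meta$genome_id, hit_genomes))
        add("warning", paste("metadata row without hit file:", g))
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(level = character(), message = character(),
               stringsAsFactors = FALSE)
  out
}

#' Run the whole analysis pipeline
#'
#' Executes reading/filtering, architecture assembly, the abundance census,
#' lifestyle stratification, promiscuity scoring and DBD-CD enrichment, and
#' writes every stage table plus a consolidated per-family report and a run
#' manifest into `out_dir`. Any stage failure aborts with the stage name in
#' the error.
#'
#' @param config A `tf_pipeline_config`.
#' @return Invisibly, a list with every stage result: `hits`, `arch`,
#'   `abundance`, `summary`, `groups`, `proportions`, `kruskal`, `rates`,
#'   `clustering`, `ws`, `cv`, `census`, `binning`, `enrichment`,
#'   `sharing`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tf_pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genomes <- stage("io", read_genome_metadata(config$metadata))
  catalog <- stage("io", read_family_catalog(config$catalog))
  hits <- stage("io", {
    pieces <- lapply(genomes$genome_id, function(g) {
      p <- file.path(config$input_dir, paste0(g, ".tsv"))
      if (!file.exists(p)) return(empty_hits())
      h <- read_assignment_file(p, genome_id = g)
      filter_superfam_hits(
        filter_dbd_hits(h, config$dbd_e_max, config$dbd_min_cov),
        config$sf_e_max)
    })
    do.call(rbind, pieces)
  })
  arch <- stage("architectures", assemble_architectures(hits, catalog))

  abund <- stage("abundance", count_families(arch, catalog, genomes))
  summary_tbl <- stage("abundance", family_summary(abund, genomes))
  groups <- stage("abundance", abundance_groups(
    stats::setNames(summary_tbl$per_genome_mean, summary_tbl$family),
    mode = config$group_mode))

  props <- stage("lifestyle", tf_proportions(abund, genomes))
  kw <- stage("lifestyle", {
    by_ls <- split(props$per_genome$proportion,
                   props$per_genome$lifestyle)
    by_ls <- by_ls[lengths(by_ls) > 0]
    if (length(by_ls) >= 2) kruskal_wallis(by_ls) else NULL
  })
  rates <- stage("lifestyle", family_lifestyle_rates(abund, genomes))
  clust <- stage("lifestyle", if (nrow(rates) >= 2)
    cluster_families(rates, metric = config$cluster_metric) else NULL)

  ws_tbl <- stage("promiscuity",
                  ws_table(arch, genomes, catalog,
                           adjacency = config$fd_adjacency))
  wsm <- stage("promiscuity",
               ws_matrix(ws_tbl, families = unique(catalog$family),
                         genomes = genomes))
  cv_tbl <- stage("promiscuity", {
    rows <- lapply(rownames(wsm), function(f) {
      pc <- classify_promiscuity(wsm[f, ], strict = config$cv_strict)
      data.frame(family = f, cv = pc$cv, class = pc$class,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  census <- stage("promiscuity", architecture_census(arch))
  binning <- stage("promiscuity", if (length(unique(genomes$n_orfs)) >= 2)
    bin_genomes(genomes$n_orfs) else NULL)

  enr <- stage("enrichment",
               enrich_all(arch, catalog, alpha = config$enrich_alpha,
                          adjacency = config$enrich_adjacency))
  sets <- stage("enrichment", enriched_cd_sets(enr,
                                               unique(catalog$family)))
  sharing <- stage("enrichment", cd_sharing(sets))

  report <- stage("report", {
    fams <- unique(catalog$family)
    cd_stats <- lapply(fams, function(f) {
      members <- arch$protein_id[!is.na(arch$dbd_family) &
                                   arch$dbd_family == f]
      cd_hits <- hits[hits$protein_id %in% members &
                        is.na(hits$family_id), , drop = FALSE]
      lens <- cd_hits$end - cd_hits$start + 1
      glob <- extract_cds(arch, f, adjacency = "all")$global
      data.frame(family = f, n_distinct_cds = length(glob),
                 cd_len_mean = if (length(lens)) mean(lens) else NA_real_,
                 cd_len_sd = if (length(lens) > 1) stats::sd(lens)
                             else NA_real_,
                 stringsAsFactors = FALSE)
    })
    cd_stats <- do.call(rbind, cd_stats)
    n_enr <- vapply(fams, function(f) length(sets[[f]]), 1L)
    grp_of <- rep(names(groups$groups), lengths(groups$groups))
    names(grp_of) <- unlist(groups$groups)
    rep_tbl <- merge(summary_tbl, cd_stats, by = "family")
    rep_tbl$n_enriched <- n_enr[match(rep_tbl$family, fams)]
    rep_tbl$abundance_group <- unname(grp_of[rep_tbl$family])
    rep_tbl <- merge(rep_tbl, cv_tbl, by = "family")
    names(rep_tbl)[names(rep_tbl) == "class"] <- "promiscuity_class"
    rep_tbl[order(-rep_tbl$total), ]
  })

  # stage outputs
  write_stage_tsv(as.data.frame(as.table(unclass(abund)),
                                responseName = "count",
                                stringsAsFactors = FALSE),
                  file.path(config$out_dir, "abundance_matrix.tsv"), hash)
  write_stage_tsv(summary_tbl,
                  file.path(config$out_dir, "family_summary.tsv"), hash)
  write_stage_tsv(props$summary,
                  file.path(config$out_dir, "lifestyle_summary.tsv"), hash)
  write_stage_tsv(as.data.frame(as.table(rates), responseName = "rate",
                                stringsAsFactors = FALSE),
                  file.path(config$out_dir, "family_lifestyle_rates.tsv"),
                  hash)
  if (!is.null(clust))
    writeLines(clust$newick,
               file.path(config$out_dir, "family_dendrogram.nwk"))
  write_stage_tsv(ws_tbl, file.path(config$out_dir, "ws_scores.tsv"), hash)
  write_stage_tsv(cv_tbl,
                  file.path(config$out_dir, "promiscuity_classes.tsv"),
                  hash)
  write_stage_tsv(enr, file.path(config$out_dir, "enrichment.tsv"), hash)
  write_stage_tsv(as.data.frame(as.table(sharing),
                                responseName = "shared_fraction",
                                stringsAsFactors = FALSE),
                  file.path(config$out_dir, "sharing_matrix.tsv"), hash)
  write_stage_tsv(report, file.path(config$out_dir, "family_report.tsv"),
                  hash)
  manifest <- data.frame(
    key = c("config_hash", "package_version", "seed", "n_genomes",
            "n_hits", "n_proteins", "n_tfs", "grand_total",
            "kruskal_wallis_h", "kruskal_wallis_p"),
    value = c(hash, as.character(utils::packageVersion("tfcensus")),
              config$seed, nrow(genomes), nrow(hits), nrow(arch),
              sum(!is.na(arch$dbd_family)), sum(abund),
              if (is.null(kw)) NA else signif(kw$h, 8),
              if (is.null(kw)) NA else signif(kw$p_value, 8)),
    stringsAsFactors = FALSE)
  write_stage_tsv(manifest, file.path(config$out_dir, "manifest.tsv"),
                  hash)

  invisible(list(hits = hits, arch = arch, abundance = abund,
                 summary = summary_tbl, groups = groups,
                 proportions = props, kruskal = kw, rates = rates,
                 clustering = clust, ws = ws_tbl, ws_matrix = wsm,
                 cv = cv_tbl, census = census, binning = binning,
                 enrichment = enr, sharing = sharing, report = report,
                 manifest = manifest, config_hash = hash))
}
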