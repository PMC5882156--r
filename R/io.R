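#' @keywords internal
hit_columns <- function() {
  c("genome_id", "protein_id", "model_id", "start", "end", "e_value",
    "model_description", "family_id", "family_e_value", "coverage",
    "pdb_ref")
}

#' @keywords internal
empty_hits <- function() {
  data.frame(genome_id = character(), protein_id = character(),
             model_id = character(), start = integer(), end = integer(),
             e_value = numeric(), model_description = character(),
             family_id = character(), family_e_value = numeric(),
             coverage = numeric(), pdb_ref = character(),
             stringsAsFactors = FALSE)
}

#' Read a per-genome domain-assignment table
#'
#' Reads one tab-separated assignment file (one row per domain hit on a
#' protein). The canonical dialect is headered, with the amino-acid position
#' encoded either as a single `position` column (`"12-80"`, 1-based
#' inclusive) or as separate `start`/`end` columns. Optional columns
#' (`family_id`, `family_e_value`, `coverage`, `pdb_ref`,
#' `model_description`) may be absent or `NA`: a row lacking `family_id` is
#' a candidate companion domain, not a DBD hit. Rows whose coordinates or
#' E-values fail to parse, or with `start > end` or negative E-values, are
#' dropped with a message reporting the count.
#'
#' @param path Path to the file.
#' @param genome_id Optional genome identifier; overrides (or supplies) the
#'   `genome_id` column.
#' @return A hits `data.frame` (columns [hit_columns()]), with attribute
#'   `n_rejected` giving the number of dropped rows.
#' @export
read_assignment_file <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("assignment file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    warning("assignment file is empty: ", path)
    return(structure(empty_hits(), n_rejected = 0L))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", na.strings = c("NA", ""))
  if (nrow(df) == 0) {
    warning("assignment file has zero data rows: ", path)
    return(structure(empty_hits(), n_rejected = 0L))
  }
  if ("position" %in% names(df) && !all(c("start", "end") %in% names(df))) {
    pos <- strsplit(as.character(df$position), "-", fixed = TRUE)
    df$start <- suppressWarnings(as.integer(vapply(pos, function(p) p[1], "")))
    df$end <- suppressWarnings(as.integer(vapply(pos, function(p)
      if (length(p) >= 2) p[2] else NA_character_, "")))
  }
  for (col in hit_columns()) if (!col %in% names(df)) df[[col]] <- NA
  if (!is.null(genome_id)) df$genome_id <- genome_id
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df$e_value <- suppressWarnings(as.numeric(df$e_value))
  df$family_e_value <- suppressWarnings(as.numeric(df$family_e_value))
  df$coverage <- suppressWarnings(as.numeric(df$coverage))
  for (col in c("genome_id", "protein_id", "model_id", "model_description",
                "family_id", "pdb_ref"))
    df[[col]] <- as.character(df[[col]])
  ok <- !is.na(df$start) & !is.na(df$end) & df$start <= df$end &
    !is.na(df$e_value) & df$e_value >= 0 &
    !is.na(df$protein_id) & !is.na(df$model_id)
  n_rejected <- sum(!ok)
  if (n_rejected > 0)
    message(n_rejected, " unparseable row(s) rejected in ", basename(path))
  out <- df[ok, hit_columns()]
  if (nrow(out) == 0) warning("zero parseable rows in ", path)
  rownames(out) <- NULL
  structure(out, n_rejected = n_rejected)
}

#' Write a hits table in the canonical assignment dialect
#'
#' Writes tab-separated with a header; `start`/`end` are folded into a
#' single `position` column (`"start-end"`). [read_assignment_file()] on the
#' result reproduces the input hit list exactly.
#'
#' @param hits A hits `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assignment_file <- function(hits, path) {
  out <- hits[, setdiff(hit_columns(), c("start", "end"))]
  out$position <- if (nrow(hits)) paste0(hits$start, "-", hits$end)
                  else character(0)
  out <- out[, c("genome_id", "protein_id", "model_id", "position",
                 "e_value", "model_description", "family_id",
                 "family_e_value", "coverage", "pdb_ref")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read the genome metadata table
#'
#' Tab-separated with header `genome_id`, `organism`, `n_orfs`, `lifestyle`.
#' Lifestyle labels come from the closed vocabulary `free-living`,
#' `pathogen`, `extremophile`, `intracellular`.
#'
#' @param path Path to the metadata TSV.
#' @return A `data.frame` with the four columns above.
#' @export
read_genome_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("genome_id", "organism", "n_orfs", "lifestyle")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$n_orfs <- as.integer(df$n_orfs)
  bad <- !df$lifestyle %in% lifestyle_levels()
  if (any(bad))
    stop("unknown lifestyle label(s): ",
         paste(unique(df$lifestyle[bad]), collapse = ", "),
         " (genome ", df$genome_id[which(bad)[1]], ")")
  if (any(is.na(df$n_orfs) | df$n_orfs < 1))
    stop("n_orfs must be a positive integer for every genome")
  df
}

#' Write the genome metadata table
#'
#' @param genomes Metadata `data.frame` as from [read_genome_metadata()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_metadata <- function(genomes, path) {
  utils::write.table(genomes[, c("genome_id", "organism", "n_orfs",
                                 "lifestyle")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter DBD hits by family E-value and model coverage
#'
#' Keeps family-assigned (DBD) hits with `family_e_value <= e_max` and
#' `coverage >= min_coverage`. Hits without a `family_id` are candidate
#' companion domains and pass through unchanged (they are filtered by
#' [filter_superfam_hits()]). When the table carries no coverage values at
#' all, the coverage condition is skipped with a warning, matching inputs in
#' the deposited-table dialect that lack a coverage column.
#'
#' @param hits Hits `data.frame`.
#' @param e_max Family E-value ceiling (default `1e-4`).
#' @param min_coverage Minimum fraction of the family model length aligned
#'   (default `0.60`).
#' @return Filtered hits `data.frame`.
#' @export
filter_dbd_hits <- function(hits, e_max = 1e-4, min_coverage = 0.60) {
  stopifnot(e_max > 0, min_coverage >= 0, min_coverage <= 1)
  if (nrow(hits) == 0) return(hits)
  is_dbd <- !is.na(hits$family_id)
  keep_e <- !is.na(hits$family_e_value) & hits$family_e_value <= e_max
  if (all(is.na(hits$coverage[is_dbd]))) {
    if (any(is_dbd))
      warning("no coverage values present; coverage filter skipped")
    keep_cov <- TRUE
  } else {
    keep_cov <- !is.na(hits$coverage) & hits$coverage >= min_coverage
  }
  out <- hits[!is_dbd | (keep_e & keep_cov), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter non-family (superfamily) hits by E-value
#'
#' Keeps candidate companion-domain hits (no `family_id`) with
#' `e_value <= e_max`; DBD hits pass through unchanged.
#'
#' @param hits Hits `data.frame`.
#' @param e_max E-value ceiling (default `1e-3`).
#' @return Filtered hits `data.frame`.
#' @export
filter_superfam_hits <- function(hits, e_max = 1e-3) {
  stopifnot(e_max > 0)
  if (nrow(hits) == 0) return(hits)
  is_dbd <- !is.na(hits$family_id)
  keep <- !is.na(hits$e_value) & hits$e_value <= e_max
  out <- hits[is_dbd | keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Greedy best-hit-wins overlap resolution on one protein's hits.
# Candidates ranked by (e_value, start, model_id); a candidate is dropped
# when it overlaps an already-kept hit by more than `max_frac` of the
# shorter of the two.
#' @keywords internal
resolve_overlaps <- function(hits, max_frac = 0.5) {
  n <- nrow(hits)
  if (n <= 1) return(hits)
  ord <- order(hits$e_value, hits$start, hits$model_id)
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov > 0) {
        shorter <- min(hits$end[i] - hits$start[i],
                       hits$end[j] - hits$start[j]) + 1L
        if (ov > max_frac * shorter) { clash <- TRUE; break }
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  out <- hits[sort(kept), , drop = FALSE]
  out[order(out$start, out$model_id), , drop = FALSE]
}

#' Assemble per-protein domain architectures from filtered hits
#'
#' Groups hits by protein, resolves overlapping assignments (best-hit-wins:
#' when two hits overlap by more than half the shorter one, the smaller
#' E-value is kept; ties broken by start, then model id), orders segments by
#' start, and classifies each protein as `monodomain` (one segment),
#' `two-domain` (two), or `multidomain` (three or more). A protein is a TF
#' when at least one resolved segment carries a family DBD assignment; its
#' companion domains (CDs) are the distinct non-DBD model ids. Proteins
#' with DBDs of two or more different families are retained (they count once
#' per family in the abundance census) and flagged via `n_families`.
#'
#' @param hits Filtered hits `data.frame`.
#' @param catalog Family catalog (`family`, `model_id`), used to validate
#'   family assignments.
#' @return A `data.frame` with one row per protein: `protein_id`,
#'   `genome_id`, `n_domains`, `arch` (ordered model ids joined by `"+"`),
#'   `dbd_family` (`;`-joined when several), `n_families`, `dbd_index`
#'   (`;`-joined 1-based positions of DBD segments within `arch`),
#'   `cd_models` (`;`-joined distinct non-DBD model ids), `arch_class`.
#' @export
assemble_architectures <- function(hits, catalog = default_family_catalog()) {
  if (nrow(hits) == 0)
    return(data.frame(protein_id = character(), genome_id = character(),
                      n_domains = integer(), arch = character(),
                      dbd_family = character(), n_families = integer(),
                      dbd_index = character(), cd_models = character(),
                      arch_class = character(), stringsAsFactors = FALSE))
  known <- !is.na(hits$family_id) & !hits$family_id %in% catalog$family
  if (any(known))
    stop("family_id not in catalog: ",
         paste(unique(hits$family_id[known]), collapse = ", "))
  h <- hits[order(hits$genome_id, hits$protein_id, hits$start,
                  hits$model_id), , drop = FALSE]
  rownames(h) <- NULL
  gi <- cumsum(c(TRUE, h$genome_id[-1] != h$genome_id[-nrow(h)] |
                   h$protein_id[-1] != h$protein_id[-nrow(h)]))
  # proteins whose sorted segments overlap need explicit resolution;
  # everything else passes through untouched
  cm <- stats::ave(h$end, gi, FUN = cummax)
  prev_cm <- c(-Inf, cm[-nrow(h)])
  prev_cm[c(TRUE, gi[-1] != gi[-nrow(h)])] <- -Inf
  clash_grp <- unique(gi[h$start <= prev_cm])
  if (length(clash_grp)) {
    keep <- rep(TRUE, nrow(h))
    for (g in clash_grp) {
      idx <- which(gi == g)
      res <- resolve_overlaps(h[idx, , drop = FALSE])
      keep[idx] <- rownames(h)[idx] %in% rownames(res)
    }
    h <- h[keep, , drop = FALSE]
    gi <- gi[keep]
  }
  gi <- match(gi, unique(gi))
  firsts <- which(!duplicated(gi))
  model_s <- split(h$model_id, gi)
  fam_s <- split(h$family_id, gi)
  dbd_family <- vapply(fam_s, function(f) {
    u <- unique(f[!is.na(f)])
    if (length(u)) paste(u, collapse = ";") else NA_character_
  }, "")
  n_domains <- lengths(model_s)
  out <- data.frame(
    protein_id = h$protein_id[firsts],
    genome_id = h$genome_id[firsts],
    n_domains = unname(n_domains),
    arch = vapply(model_s, paste, "", collapse = "+"),
    dbd_family = dbd_family,
    n_families = vapply(fam_s, function(f) length(unique(f[!is.na(f)])), 1L),
    dbd_index = vapply(fam_s, function(f) {
      w <- which(!is.na(f))
      if (length(w)) paste(w, collapse = ";") else NA_character_
    }, ""),
    cd_models = mapply(function(m, f) {
      cds <- unique(m[is.na(f)])
      if (length(cds)) paste(cds, collapse = ";") else NA_character_
    }, model_s, fam_s, USE.NAMES = FALSE),
    arch_class = ifelse(n_domains == 1, "monodomain",
                        ifelse(n_domains == 2, "two-domain", "multidomain")),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$genome_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write assembled architectures as TSV
#'
#' @param arch Architectures `data.frame` from [assemble_architectures()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_architectures <- function(arch, path) {
  utils::write.table(arch, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
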