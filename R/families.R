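#' Reference table of the 19 prokaryotic TF families
#'
#' Published summary statistics for the 19 DNA-binding transcription factor
#' (TF) families identified across 761 non-redundant bacterial and archaeal
#' genomes: total member counts, number of distinct companion domains (CDs),
#' CD length mean and standard deviation (amino acids), number of enriched
#' CDs, and the Pearson correlation between family abundance and genome size
#' (in ORFs). These printed values are inputs to the reporting layer (family
#' shares, per-genome means, abundance groups) and to the defaults of the
#' synthetic-data generator.
#'
#' @return A `data.frame` with one row per family and columns `family`,
#'   `total`, `n_cds`, `cd_len_mean`, `cd_len_sd`, `n_enriched`, `pearson_r`.
#' @export
#' @examples
#' tf_family_table()$family
tf_family_table <- function() {
  df <- data.frame(
    family      = c("PhoB", "GerE", "GntR", "MarR", "SinR", "ArsR",
                    "TetR/AcrR", "LysR", "AraC/XylS", "Crp", "Lrp", "LexA",
                    "IclR", "GalR/LacI", "Fur", "Fis", "BirA", "ArgR", "TrmB"),
    total       = c(4948L, 6074L, 6639L, 6305L, 5939L, 3314L,
                    12097L, 11610L, 6860L, 2264L, 4119L, 611L,
                    1323L, 3504L, 1428L, 4143L, 1076L, 485L, 746L),
    n_cds       = c(72L, 96L, 76L, 126L, 133L, 86L,
                    70L, 24L, 106L, 53L, 126L, 36L,
                    80L, 25L, 14L, 65L, 58L, 22L, 84L),
    cd_len_mean = c(136.08, 134.32, 188.69, 149.56, 126.99, 138.97,
                    111.91, 201.09, 136.78, 133.14, 109.55, 119.99,
                    164.31, 258.52, 84.50, 192.78, 121.56, 84.42, 139.84),
    cd_len_sd   = c(42.06, 43.21, 91.35, 72.11, 62.05, 56.56,
                    25.01, 15.79, 52.77, 31.75, 51.13, 31.21,
                    44.13, 32.84, 71.21, 53.01, 62.46, 38.25, 69.73),
    n_enriched  = c(8L, 24L, 9L, 30L, 35L, 21L,
                    4L, 1L, 46L, 4L, 30L, 6L,
                    11L, 1L, 1L, 20L, 9L, 2L, 19L),
    pearson_r   = c(0.73, 0.71, 0.71, 0.69, 0.65, 0.65,
                    0.65, 0.62, 0.61, 0.61, 0.60, 0.53,
                    0.51, 0.51, 0.50, 0.47, 0.47, 0.17, 0.12),
    stringsAsFactors = FALSE
  )
  df
}

#' Grand total of TF proteins in the reference dataset
#'
#' @return Integer scalar: the sum of the 19 family totals.
#' @export
tf_grand_total <- function() sum(tf_family_table()$total)

#' Reference abundance-group memberships
#'
#' The four abundance groups of the 19 families in the reference dataset:
#' group 1 the two dominant families, group 2 six abundant families, group 3
#' four families of intermediate abundance, group 4 seven families with few
#' members per genome.
#'
#' @return Named list of four character vectors.
#' @export
reference_abundance_groups <- function() {
  list(
    group1 = c("LysR", "TetR/AcrR"),
    group2 = c("AraC/XylS", "GntR", "MarR", "GerE", "PhoB", "SinR"),
    group3 = c("Lrp", "Fis", "GalR/LacI", "ArsR"),
    group4 = c("ArgR", "Fur", "LexA", "IclR", "Crp", "BirA", "TrmB")
  )
}

#' Reference promiscuity-class memberships
#'
#' CV-based grouping of the 19 families: highly promiscuous families have
#' diverse companion-domain repertoires (WS values close to 0 across
#' genomes), monolithic families are dominated by the bare DBD or a single
#' invariant CD.
#'
#' @return Named list of three character vectors.
#' @export
reference_promiscuity_groups <- function() {
  list(
    highly_promiscuous = c("LysR", "TetR/AcrR", "AraC/XylS", "GerE",
                           "GalR/LacI", "MarR", "PhoB", "Fis", "GntR",
                           "SinR", "Lrp"),
    intermediate       = c("BirA", "Crp", "TrmB", "IclR", "ArsR"),
    monolithic         = c("ArgR", "Fur", "LexA")
  )
}

#' Default family catalog mapping families to DBD model identifiers
#'
#' Each TF family is defined by one DNA-binding-domain (DBD) model. Real
#' assignment tables carry structural-domain model identifiers; this default
#' catalog uses synthetic, self-describing model ids (`DBD.<family>`) that
#' the synthetic generator emits. Supply your own two-column table (via
#' [read_family_catalog()]) to map real model identifiers.
#'
#' @return A `data.frame` with columns `family` and `model_id`.
#' @export
default_family_catalog <- function() {
  fam <- tf_family_table()$family
  data.frame(family = fam,
             model_id = paste0("DBD.", gsub("[^A-Za-z0-9]", "_", fam)),
             stringsAsFactors = FALSE)
}

#' Read a family catalog from a two-column TSV
#'
#' @param path Path to a tab-separated file with header columns `family` and
#'   `model_id`.
#' @return A `data.frame` with columns `family`, `model_id`.
#' @export
read_family_catalog <- function(path) {
  if (!file.exists(path)) stop("family catalog not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "model_id")
  if (!all(need %in% names(df)))
    stop("family catalog must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$model_id))
    stop("each DBD model_id must map to exactly one family")
  df
}

#' @keywords internal
lifestyle_levels <- function() {
  c("free-living", "pathogen", "extremophile", "intracellular")
}
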