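# In-code fixture builders shared across the suite.

# One hit row with sensible defaults; override any field.
make_hit <- function(protein_id = "p1", genome_id = "G1",
                     model_id = "SSF10001", start = 1L, end = 100L,
                     e_value = 1e-10, model_description = "domain",
                     family_id = NA_character_, family_e_value = NA_real_,
                     coverage = NA_real_, pdb_ref = NA_character_) {
  data.frame(genome_id = genome_id, protein_id = protein_id,
             model_id = model_id, start = as.integer(start),
             end = as.integer(end), e_value = e_value,
             model_description = model_description, family_id = family_id,
             family_e_value = family_e_value, coverage = coverage,
             pdb_ref = pdb_ref, stringsAsFactors = FALSE)
}

make_hits <- function(...) do.call(rbind, list(...))

# A two-family toy catalog used by hand-built architecture tests.
toy_catalog <- function() {
  data.frame(family = c("LysR", "TetR/AcrR"),
             model_id = c("DBD.LysR", "DBD.TetR_AcrR"),
             stringsAsFactors = FALSE)
}

# Small synthetic world: fast enough for unit tests, big enough to carry
# signal. Scaled down from the 761-genome defaults.
tiny_config <- function(seed = 1, n_genomes = 25, ...) {
  fams <- default_family_params()[c(7, 8, 15), ]  # TetR/AcrR, LysR, Fur
  synthetic_config(n_genomes = n_genomes, seed = seed, families = fams,
                   ...)
}

tiny_dataset <- function(seed = 1, n_genomes = 25, ...) {
  generate_dataset(tiny_config(seed = seed, n_genomes = n_genomes, ...))
}

dataset_architectures <- function(ds) {
  assemble_architectures(do.call(rbind, ds$hits), ds$catalog)
}
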