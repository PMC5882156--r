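arch_row <- function(protein_id, genome_id, models, dbd_idx, family) {
  n <- length(models)
  data.frame(protein_id = protein_id, genome_id = genome_id,
             n_domains = n, arch = paste(models, collapse = "+"),
             dbd_family = family, n_families = 1L,
             dbd_index = paste(dbd_idx, collapse = ";"),
             cd_models = {
               cds <- unique(models[-dbd_idx])
               if (length(cds)) paste(cds, collapse = ";") else NA_character_
             },
             arch_class = c("monodomain", "two-domain",
                            "multidomain")[min(n, 3)],
             stringsAsFactors = FALSE)
}

test_that("partner extraction uses immediate adjacency around the DBD", {
  arch <- rbind(
    arch_row("p1", "G1", "DBD.LysR", 1, "LysR"),                  # no CDs
    arch_row("p2", "G1", c("CD1", "DBD.LysR", "CD2"), 2, "LysR"),
    arch_row("p3", "G2", c("CD1", "DBD.LysR"), 2, "LysR"),
    arch_row("p4", "G2", c("DBD.LysR", "CD1"), 1, "LysR"))
  cds <- extract_cds(arch, "LysR")
  expect_setequal(cds$partner_sets[["G1"]], c("CD1", "CD2"))
  # both orientations of the same CD count once per genome
  expect_equal(cds$per_genome$f_d[cds$per_genome$genome_id == "G2"], 1L)
  expect_setequal(cds$global, c("CD1", "CD2"))
  # non-adjacent domains count in "all" mode only
  arch2 <- arch_row("q1", "G3", c("DBD.LysR", "CDa", "CDb"), 1, "LysR")
  adj <- extract_cds(arch2, "LysR", "adjacent")
  all_mode <- extract_cds(arch2, "LysR", "all")
  expect_equal(adj$per_genome$f_d, 1L)
  expect_setequal(all_mode$partner_sets[["G3"]], c("CDa", "CDb"))
})

test_that("IAF, IV and WS match their definitions", {
  expect_equal(iaf(1024, 1), 10)
  expect_equal(iaf(500, 500), 0)
  # frozen arbitrary-precision value of log2(250)
  expect_equal(iaf(3000, 12), 7.96578428466208704, tolerance = 1e-15)
  expect_error(iaf(10, 0))
  expect_error(iaf(5, 10))

  expect_equal(iv(1), 1)
  expect_equal(iv(4), 0.25)
  expect_equal(iv(0), 1)  # DBD-only family scores WS = IAF
  expect_error(iv(-1))

  expect_equal(ws(10, 0.2), 2)
  expect_equal(ws(7.3, 1), 7.3)
  # WS strictly decreases as partner diversity grows
  sweep <- ws(iaf(3000, 12), iv(1:10))
  expect_true(all(diff(sweep) < 0))
})

test_that("WS table satisfies its arithmetic invariants", {
  ds <- tiny_dataset(seed = 14, n_genomes = 20)
  arch <- dataset_architectures(ds)
  wst <- ws_table(arch, ds$genomes, ds$catalog)
  expect_true(all(wst$p_d <= wst$p_t))
  expect_true(all(wst$iv > 0 & wst$iv <= 1))
  expect_equal(wst$ws, wst$iaf * wst$iv, tolerance = 1e-12)
  expect_equal(wst$iaf, log2(wst$p_t / wst$p_d), tolerance = 1e-12)
  # global distinct-CD count bounds every per-genome f_d
  for (fam in unique(wst$family)) {
    glob <- length(extract_cds(arch, fam, "all")$global)
    expect_gte(glob, max(wst$f_d[wst$family == fam]))
  }
  # absent families yield no rows; ws_matrix fills zeros
  m <- ws_matrix(wst, unique(ds$catalog$family), ds$genomes)
  ab <- count_families(arch, ds$catalog, ds$genomes)
  expect_true(all(m[ab == 0] == 0))
})

test_that("Sturges binning gives the published window count", {
  set.seed(3)
  sizes761 <- sample(500:9696, 761, replace = TRUE)
  b <- bin_genomes(sizes761)
  expect_equal(b$k, 11L)
  expect_equal(bin_genomes(c(1000, 2000))$k, 2L)
  expect_equal(bin_genomes(sample(500:9696, 1000, TRUE))$k, 11L)
  expect_error(bin_genomes(rep(5, 10)), "zero range")
  # width formula and exhaustive partition: each genome in exactly one bin
  expect_equal(b$width, (max(sizes761) - min(sizes761)) / 11)
  expect_true(all(b$bin >= 1 & b$bin <= b$k))
  for (i in seq_along(sizes761)[1:50]) {
    x <- sizes761[i]; bi <- b$bin[i]
    expect_true(x >= b$edges[bi] &&
                  (x < b$edges[bi + 1] || bi == b$k))
  }
})

test_that("CV classes follow the gap-midpoint boundaries", {
  expect_equal(classify_promiscuity(rep(2.5, 10))$cv, 0)
  expect_equal(classify_promiscuity(rep(2.5, 10))$class,
               "highly_promiscuous")
  # two-point vectors hit any target CV: sd = |diff| / sqrt(2), mean = 1
  for (case in list(c(1.2, "highly_promiscuous"),
                    c(2.0, "intermediate"),
                    c(4.0, "monolithic"))) {
    target <- as.numeric(case[1])
    x <- 1 + c(-1, 1) * target / sqrt(2)
    pc <- classify_promiscuity(x)
    expect_equal(pc$cv, target, tolerance = 1e-12)
    expect_equal(pc$class, case[2])
  }
  # strict mode keeps the printed ranges and flags the gaps
  x_gap <- 1 + c(-1, 1) * 1.5 / sqrt(2)
  expect_equal(classify_promiscuity(x_gap, strict = TRUE)$class,
               "unclassified")
  expect_equal(classify_promiscuity(rep(0, 5))$class, "undefined")
  # independent two-pass moments oracle
  set.seed(9)
  v <- rexp(40)
  mu <- sum(v) / length(v)
  cv_oracle <- sqrt(sum((v - mu)^2) / (length(v) - 1)) / mu
  expect_equal(classify_promiscuity(v)$cv, cv_oracle, tolerance = 1e-12)
})

test_that("architecture census fractions behave and sum to one", {
  arch <- rbind(arch_row("p1", "G1", "DBD.LysR", 1, "LysR"),
                arch_row("p2", "G1", c("DBD.LysR", "CD1"), 1, "LysR"))
  cen <- architecture_census(arch)
  expect_equal(unname(cen), c(0.5, 0.5, 0))
  expect_equal(sum(cen), 1)
  expect_error(architecture_census(arch[0, ]), "no TFs")
  # planted monodomain probability is recovered at scale
  fams <- default_family_params()[c(7, 8), ]
  ds <- generate_dataset(synthetic_config(n_genomes = 150, seed = 44,
                                          families = fams))
  cen2 <- architecture_census(dataset_architectures(ds))
  expect_lt(abs(cen2[["monodomain"]] - 0.32), 0.02)
  expect_equal(sum(cen2), 1, tolerance = 1e-9)
})

test_that("CD sharing is the directed overlap of enriched sets", {
  sets <- list(A = c("x", "y", "z"), B = "x", C = c("u", "v"),
               D = character(0))
  s <- cd_sharing(sets)
  expect_equal(s["A", "B"], 1 / 3)
  expect_equal(s["B", "A"], 1)
  expect_equal(s["A", "C"], 0)
  expect_equal(s["A", "A"], 1)
  expect_true(all(is.na(s["D", ])))
})
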