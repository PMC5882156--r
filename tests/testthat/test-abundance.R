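# x standardized, then y built to have an exact Pearson correlation r with x
vector_with_cor <- function(x, r, seed = 1) {
  set.seed(seed)
  e <- rnorm(length(x))
  e <- residuals(lm(e ~ x))
  xs <- (x - mean(x)) / sd(x)
  r * xs + sqrt(1 - r^2) * e / sd(e)
}

test_that("census counts proteins once per family", {
  # three LysR proteins, one with a repeated LysR DBD segment
  h <- make_hits(
    make_hit(protein_id = "a", model_id = "DBD.LysR", family_id = "LysR",
             start = 1, end = 60),
    make_hit(protein_id = "a", model_id = "DBD.LysR", family_id = "LysR",
             start = 200, end = 260),
    make_hit(protein_id = "b", model_id = "DBD.LysR", family_id = "LysR",
             start = 1, end = 60),
    make_hit(protein_id = "c", model_id = "DBD.LysR", family_id = "LysR",
             start = 1, end = 60))
  arch <- assemble_architectures(h, toy_catalog())
  ab <- count_families(arch, toy_catalog())
  expect_equal(unname(ab["LysR", "G1"]), 3L)
  expect_equal(unname(ab["TetR/AcrR", "G1"]), 0L)
})

test_that("census of an empty dataset is an all-zero matrix", {
  arch <- assemble_architectures(empty_hits <- make_hits(make_hit())[0, ],
                                 toy_catalog())
  genomes <- data.frame(genome_id = c("G1", "G2"), organism = "x",
                        n_orfs = c(1000L, 2000L), lifestyle = "pathogen")
  ab <- count_families(arch, toy_catalog(), genomes)
  expect_equal(dim(ab), c(2L, 2L))
  expect_true(all(ab == 0L))
})

test_that("census equals the generator's truth ledger", {
  ds <- tiny_dataset(seed = 21, n_genomes = 15)
  ab <- count_families(dataset_architectures(ds), ds$catalog, ds$genomes)
  tru <- ds$truth$per_genome_family
  expect_equal(unname(ab[cbind(tru$family, tru$genome_id)]), tru$count)
  # sum of family totals equals the grand total of TFs
  expect_equal(sum(ab), sum(tru$count))
})

test_that("profile normalization matches the analytic cases", {
  p <- normalize_profile(c(1, 2, 3))
  expect_equal(p$a_avg, 2)
  expect_equal(p$a_sdv, 1)
  expect_equal(p$a_n, c(-1, 0, 1))
  expect_false(p$degenerate)

  q <- normalize_profile(c(5, 5, 5, 5))
  expect_equal(q$a_n, rep(0, 4))
  expect_true(q$degenerate)

  expect_error(normalize_profile(3), "at least 2")
})

test_that("normalized profiles have mean 0 and sd 1", {
  set.seed(31)
  for (i in 1:20) {
    x <- rpois(sample(5:60, 1), lambda = runif(1, 1, 40))
    if (sd(x) == 0) next
    p <- normalize_profile(x)
    expect_lt(abs(mean(p$a_n)), 1e-9)
    expect_lt(abs(sd(p$a_n) - 1), 1e-9)
    # independent two-pass recomputation
    mu <- sum(x) / length(x)
    sdv <- sqrt(sum((x - mu)^2) / (length(x) - 1))
    expect_equal(p$a_n, (x - mu) / sdv, tolerance = 1e-12)
  }
})

test_that("size correlation classes follow the published thresholds", {
  n_orfs <- seq(500, 9500, length.out = 200)
  expect_equal(correlate_size(0.005 * n_orfs, n_orfs)$r, 1.0)
  expect_equal(correlate_size(0.005 * n_orfs, n_orfs)$class, "strong")
  for (case in list(c(0.71, NA), c(0.12, NA), c(0.53, NA))) {
    r <- case[1]
    y <- vector_with_cor(n_orfs, r, seed = round(100 * r))
    cc <- correlate_size(y, n_orfs)
    expect_equal(cc$r, r, tolerance = 1e-9)
  }
  expect_equal(correlate_size(vector_with_cor(n_orfs, 0.71), n_orfs)$class,
               "strong")
  expect_equal(correlate_size(vector_with_cor(n_orfs, 0.12), n_orfs)$class,
               "low")
  expect_equal(correlate_size(vector_with_cor(n_orfs, 0.53), n_orfs)$class,
               "intermediate")
  expect_equal(correlate_size(rep(4, 10), 1:10)$class, "undefined")
})

test_that("Pearson r matches the textbook formula and is normalization-invariant", {
  set.seed(17)
  for (i in 1:25) {
    x <- rnorm(5); y <- rnorm(5)
    r_text <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(correlate_size(x, y)$r, r_text, tolerance = 1e-12)
    xn <- normalize_profile(x)$a_n
    expect_equal(correlate_size(xn, y)$r, correlate_size(x, y)$r,
                 tolerance = 1e-12)
  }
})

test_that("family shares and per-genome means reproduce printed values", {
  expect_equal(round(family_share(12097, 83485), 2), 14.49)
  expect_equal(round(family_share(12097 + 11610, 83485), 1), 28.4)
  expect_equal(family_share(0, 1000), 0)
  expect_equal(round(per_genome_mean(12097, 761), 1), 15.9)
  expect_equal(round(per_genome_mean(11610, 761), 2), 15.26)
  expect_equal(per_genome_mean(0, 761), 0)
})

test_that("abundance grouping: reference lists and rank-based cuts", {
  tab <- tf_family_table()
  means <- setNames(per_genome_mean(tab$total, 761), tab$family)
  ref <- abundance_groups(means, mode = "reference")
  expect_equal(ref$groups$group4,
               c("ArgR", "Fur", "LexA", "IclR", "Crp", "BirA", "TrmB"))
  # rank mode: one dominant family sits alone in the top group
  m <- c(Dom = 50, a = 5, b = 4.5, c = 4.4, d = 1, e = 0.9, f = 0.8)
  rk <- abundance_groups(m, mode = "rank")
  expect_equal(rk$groups$group1, "Dom")
  # all-equal means collapse to a single flagged group
  eq <- abundance_groups(setNames(rep(2, 6), letters[1:6]), mode = "rank")
  expect_length(eq$groups, 1)
  expect_true(eq$tie)
})

test_that("family summary is internally consistent on synthetic data", {
  ds <- tiny_dataset(seed = 8, n_genomes = 20)
  ab <- count_families(dataset_architectures(ds), ds$catalog, ds$genomes)
  fs <- family_summary(ab, ds$genomes)
  expect_equal(sum(fs$total), sum(ab))
  expect_equal(sum(fs$share_pct), 100, tolerance = 1e-9)
  expect_equal(fs$per_genome_mean, fs$total / ncol(ab))
})
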