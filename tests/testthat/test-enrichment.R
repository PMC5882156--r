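# Exhaustive hypergeometric enumeration: P(X >= a) with margins fixed,
# computed from binomial coefficients only.
fisher_enum <- function(a, b, c, d) {
  n <- a + b + c + d
  k1 <- a + b   # family proteins drawn
  m <- a + c    # CD-bearing proteins
  xs <- max(0, k1 - (n - m)):min(k1, m)
  probs <- choose(m, xs) * choose(n - m, k1 - xs) / choose(n, k1)
  sum(probs[xs >= a])
}

test_that("one-tailed Fisher p matches hand enumeration", {
  expect_equal(fisher_one_tail(3, 0, 0, 3), 0.05, tolerance = 1e-12)
  expect_equal(fisher_one_tail(0, 5, 3, 9), 1.0)
  expect_error(fisher_one_tail(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p equals exhaustive enumeration on all small tables", {
  # every table with total <= 12
  for (n in 1:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      expect_equal(fisher_one_tail(a, b, c, d), fisher_enum(a, b, c, d),
                   tolerance = 1e-12)
    }
  }
})

test_that("Fisher p matches enumeration on random tables up to total 200", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(4:200, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
    d <- n - cuts[3]
    expect_equal(fisher_one_tail(a, b, c, d), fisher_enum(a, b, c, d),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up recursion", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    # independent step-up recursion, smallest rank last
    m <- length(p)
    o <- order(p)
    adj_sorted <- numeric(m)
    prev <- 1
    for (j in m:1) {
      prev <- min(prev, m / j * p[o[j]])
      adj_sorted[j] <- prev
    }
    expect_equal(bh_adjust(p)[o], adj_sorted, tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
    expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  }
})

test_that("BH controls the false-discovery proportion on uniform nulls", {
  set.seed(77)
  reps <- 400; m <- 100; alpha <- 0.05
  fdp <- replicate(reps, {
    p <- runif(m)
    mean(bh_adjust(p) <= alpha)  # all nulls: every rejection is false
  })
  expect_lt(mean(fdp), alpha + 0.02)
})

test_that("enrichment tables have consistent margins and flags", {
  ds <- tiny_dataset(seed = 25, n_genomes = 30)
  arch <- dataset_architectures(ds)
  enr <- enrich_all(arch, ds$catalog)
  tf <- arch[!is.na(arch$dbd_family) & arch$n_families == 1, ]
  fam_n <- table(tf$dbd_family)
  expect_equal(enr$a + enr$b, as.integer(fam_n[enr$family]),
               ignore_attr = TRUE)
  expect_true(all(enr$p_adj >= enr$p_raw - 1e-15))
  expect_true(all(enr$p_raw >= 0 & enr$p_raw <= 1))
  expect_equal(enr$unique, enr$c == 0L)
  # a + c equals the number of distinct proteins carrying the CD
  cd_count <- sapply(seq_len(nrow(enr))[1:10], function(i) {
    sum(vapply(strsplit(tf$cd_models, ";", fixed = TRUE),
               function(x) enr$cd_model[i] %in% x, TRUE))
  })
  expect_equal(enr$a[1:10] + enr$c[1:10], as.integer(cd_count))
})

test_that("uniformly shared CDs are never called enriched", {
  fams <- data.frame(family = c("LysR", "TetR/AcrR", "Fur"),
                     base_rate = 2, size_slope = 0.5, cd_pool_size = 20,
                     cd_concentration = 1e-9, p_monodomain = 0.32,
                     p_second_cd = 0.13, cd_len_mean = 140, cd_len_sd = 40)
  ds <- generate_dataset(synthetic_config(n_genomes = 80, seed = 31,
                                          families = fams,
                                          n_cd_universe = 20))
  enr <- enrich_all(dataset_architectures(ds), ds$catalog)
  expect_false(any(enr$enriched))
  expect_gt(median(enr$p_raw), 0.1)
})

test_that("a strongly planted DBD-CD pair is detected and unique CDs flagged", {
  fams <- data.frame(family = c("LysR", "TetR/AcrR"),
                     base_rate = 2.5, size_slope = 0.5, cd_pool_size = 25,
                     cd_concentration = 1e-9, p_monodomain = 0.32,
                     p_second_cd = 0.13, cd_len_mean = 140, cd_len_sd = 40)
  planted <- data.frame(family = "LysR", cd_model = "SSF10001",
                        stringsAsFactors = FALSE)
  ds <- generate_dataset(synthetic_config(n_genomes = 120, seed = 32,
                                          families = fams,
                                          n_cd_universe = 25,
                                          planted_enrichments = planted))
  enr <- enrich_all(dataset_architectures(ds), ds$catalog)
  hit <- enr[enr$family == "LysR" & enr$cd_model == "SSF10001", ]
  expect_true(hit$enriched)
  # CD observed in exactly one family is unique there
  solo <- enr[enr$c == 0, ]
  if (nrow(solo) > 0) expect_true(all(solo$unique))
})
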