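test_that("missingness filter keeps accessions at or under the threshold", {
  m <- rbind(
    ok = c(rep("A", 19), "N"),          # 5% missing
    bad = c(rep("A", 17), rep("N", 3))  # 15% missing
  )
  res <- filter_genotypes_by_missingness(panel_from_matrix(m))
  expect_equal(res$retained$accession, "ok")
  expect_equal(res$removed, "bad")

  # brute-force retention on random matrices + idempotence
  for (seed in 1:5) {
    panel <- random_panel(seed, 10, 40, p_missing = 0.12)
    cfg <- qc_config(max_genotype_missing = 0.1)
    res <- filter_genotypes_by_missingness(panel, cfg)
    manual <- panel$accession[
      apply(geno_calls(panel), 1, function(r) mean(r == "N")) <= 0.1
    ]
    expect_equal(res$retained$accession, manual)
    twice <- filter_genotypes_by_missingness(res$retained, cfg)
    expect_equal(twice$retained, res$retained)
    expect_equal(twice$removed, character(0))
  }
})

test_that("raising the missingness threshold never removes more", {
  panel <- random_panel(42, 12, 50, p_missing = 0.15)
  kept <- vapply(c(0.05, 0.1, 0.2, 0.5), function(th) {
    nrow(filter_genotypes_by_missingness(
      panel, qc_config(max_genotype_missing = th))$retained)
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("marker statistics match direct tabulation", {
  panel <- panel_from_matrix(matrix(c("A", "A", "R", "G"), ncol = 1),
                             loci = "L1")
  st <- marker_stats(panel)
  expect_equal(st$n_called, 4L)
  expect_equal(st$het_fraction, 0.25)
  expect_equal(st$maf, 3 / 8)   # A:5, G:3

  mono <- marker_stats(panel_from_matrix(matrix("A", 5, 1)))
  expect_equal(mono$maf, 0)
  expect_equal(mono$het_fraction, 0)
  expect_equal(mono$hwe_p, 1)

  # random matrices against an independent per-locus tabulation
  for (seed in 1:3) {
    panel <- random_panel(seed, 12, 30)
    st <- marker_stats(panel)
    m <- geno_calls(panel)
    for (l in sample(ncol(m), 5)) {
      calls <- m[, l][m[, l] != "N"]
      a_count <- 2 * sum(calls == "A") + sum(calls == "R")
      g_count <- 2 * sum(calls == "G") + sum(calls == "R")
      expect_equal(st$n_called[l], length(calls))
      expect_equal(st$het_fraction[l], mean(calls == "R"))
      expect_equal(st$maf[l],
                   min(a_count, g_count) / (a_count + g_count))
    }
  }
})

test_that("HWE chi-square matches the df-1 survival function", {
  exact <- hwe_test(25, 50, 25)
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)

  off <- hwe_test(30, 40, 30)
  expect_equal(off$chi2, 4.0)
  expect_equal(off$p, pchisq(4, df = 1, lower.tail = FALSE))
  expect_equal(off$p, 0.0455, tolerance = 1e-3)

  mono <- hwe_test(10, 0, 0)
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p, 1)

  expect_error(hwe_test(-1, 0, 5), "non-negative")
  expect_error(hwe_test(0, 0, 0), "at least 1")
  vec <- hwe_test(c(25, 30), c(50, 40), c(25, 30))
  expect_equal(vec$chi2, c(0, 4))
})

test_that("ld_r2 equals the textbook pairwise-complete correlation", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_true(is.na(ld_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))))
  withr::with_seed(14, {
    for (rep in 1:50) {
      x <- sample(c(0, 1, 2, NA), 30, replace = TRUE)
      y <- sample(c(0, 1, 2, NA), 30, replace = TRUE)
      expect_equal(ld_r2(x, y), oracle_r2(x, y))
    }
  })
})

test_that("LD pruning drops exactly one of a duplicated column", {
  withr::with_seed(19, {
    base <- matrix(sample(c("A", "G"), 8 * 6, replace = TRUE), 8, 6)
  })
  m <- cbind(base, base[, 3])   # duplicate column
  panel <- panel_from_matrix(m)
  st <- marker_stats(panel)
  kept <- ld_prune(panel, st)
  expect_true(xor("L003" %in% kept, "L007" %in% kept))
})

test_that("LD pruning matches the naive window-rule oracle", {
  for (seed in 1:5) {
    sim <- simulate_panel(seed + 500, n_accessions = 12, n_loci = 30,
                          n_duplicate_pairs = 0, het_rate = 0.2,
                          missing_rate = 0.05)
    cfg <- qc_config(ld_window = 8, ld_step = 3, ld_r2_max = 0.5)
    st <- marker_stats(sim$panel)
    kept <- ld_prune(sim$panel, st, cfg)
    dos <- geno_dosage(sim$panel, st)
    manual <- oracle_ld_prune(dos, setNames(st$maf, st$locus_id),
                              r2_max = 0.5, window = 8, step = 3)
    expect_equal(kept, manual)
  }
})

test_that("independent loci survive pruning untouched", {
  withr::with_seed(77, {
    m <- matrix(sample(c("A", "G"), 40 * 12, replace = TRUE), 40, 12)
  })
  panel <- panel_from_matrix(m)
  st <- marker_stats(panel)
  kept <- ld_prune(panel, st, qc_config(ld_r2_max = 0.95))
  expect_equal(kept, st$locus_id)
})

test_that("homozygous difference counts only dual-homozygous sites", {
  expect_equal(hom_diff(c("A", "A", "C", "G"), c("A", "A", "C", "G")), 0)
  expect_equal(hom_diff(c("A", "A", "C", "G"), c("A", "T", "C", "G")),
               0.25)
  expect_equal(hom_diff(c("A", "R", "N", "G"), c("A", "A", "C", "G")), 0)
  expect_warning(res <- hom_diff(c("R", "N"), c("A", "A")), "homozygous")
  expect_true(is.na(res))
  withr::with_seed(23, {
    for (rep in 1:50) {
      x <- sample(c("A", "C", "G", "T", "R", "N"), 40, replace = TRUE)
      y <- sample(c("A", "C", "G", "T", "Y", "N"), 40, replace = TRUE)
      expect_equal(suppressWarnings(hom_diff(x, y)),
                   oracle_homdiff(x, y))
    }
  })
})

test_that("duplicate groups are the components of the threshold graph", {
  sim <- simulate_panel(9, n_accessions = 6, n_loci = 3000,
                        n_duplicate_pairs = 2, missing_rate = 0)
  dup <- find_duplicates(sim$panel)
  expect_equal(length(dup$retained), 4L)
  truth <- sim$truth$pairs
  for (k in seq_len(nrow(truth))) {
    g <- dup$groups
    expect_equal(g$group[g$accession == truth$accession[k]],
                 g$group[g$accession == truth$source[k]])
  }

  # no pair under threshold -> everything retained
  far <- simulate_panel(10, n_accessions = 8, n_loci = 500,
                        n_duplicate_pairs = 0)
  expect_equal(length(find_duplicates(far$panel)$retained), 8L)

  # component structure equals brute-force closure of the edge list
  hd <- hom_diff_matrix(sim$panel)
  edges <- which(upper.tri(hd) & hd < 0.001, arr.ind = TRUE)
  comp <- oracle_components(nrow(hd), edges)
  got <- dup$groups$group
  expect_equal(length(unique(got)), length(unique(comp)))
  expect_true(all(tapply(comp, got, function(v) length(unique(v))) == 1))
})

test_that("relaxing the duplicate threshold only merges groups", {
  sim <- simulate_panel(12, n_accessions = 10, n_loci = 1000,
                        n_duplicate_pairs = 2)
  strict <- find_duplicates(sim$panel, qc_config(dup_homdiff_max = 1e-4))
  loose <- find_duplicates(sim$panel, qc_config(dup_homdiff_max = 0.01))
  expect_true(length(loose$retained) <= length(strict$retained))
})

test_that("the full screen reports consistent nested stages", {
  sim <- simulate_panel(31, n_accessions = 8, n_loci = 400,
                        n_duplicate_pairs = 1)
  rep <- suppressWarnings(ibs_dedup(sim$panel))
  expect_s3_class(rep, "qc_report")
  expect_true(all(rep$retained_after_ld %in% rep$retained_after_het_hwe))
  expect_true(all(rep$retained_genotypes %in%
                    rep$retained_after_missingness))
  g <- glance(rep)
  expect_equal(g$n_markers_after_ld, length(rep$retained_after_ld))
  expect_equal(nrow(tidy(rep)), 8L)
})
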