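simple_probe <- function(seq, id = "p1", offset = 0L) {
  tibble::tibble(probe_id = id, sequence = seq, snp_offset = offset,
                 allele_a = "A", allele_b = "G",
                 chrom_hint = NA_character_, pos_hint = NA_real_)
}

test_that("a repeated substring yields an ambiguous placement", {
  genome <- tibble::tibble(id = "g", sequence = "ACGTACGTAC")
  pl <- place_probe(simple_probe("GTAC"), genome, k = 4, min_identity = 1)
  expect_equal(pl$status, "ambiguous")
  expect_equal(pl$n_best, 2L)
  expect_equal(pl$start, 2L)   # first of the tied best starts (2 and 6)
})

test_that("a probe present only as reverse complement places on minus", {
  probe <- "ACCTGACCTGAAGGTTCAAGG"
  genome <- tibble::tibble(
    id = "g",
    sequence = paste0("TTTTTTTTTTTT", revcomp(probe), "CCCCCCCCCCCC")
  )
  pl <- place_probe(simple_probe(probe), genome, k = 21, min_identity = 1)
  expect_equal(pl$status, "unique")
  expect_equal(pl$strand, "-")
  expect_equal(pl$identity, 1)
  expect_equal(pl$start, 12L)
  expect_equal(pl$end, 12L + nchar(probe))
})

test_that("SNP projection follows the strand-aware coordinate formulas", {
  placements <- tibble::tibble(
    probe_id = c("p1", "p2"), target_id = "g",
    start = c(100L, 100L), end = c(150L, 150L),
    strand = c("+", "-"), identity = 1, n_best = 1L, status = "unique"
  )
  probes <- tibble::tibble(probe_id = c("p1", "p2"), snp_offset = 17L)
  loci <- project_snp(placements, probes)
  expect_equal(loci$snp_pos, c(117L, 132L))
  placements$status[2] <- "ambiguous"
  expect_error(project_snp(placements, probes), "non-unique.*'p2'")
})

test_that("placement agrees with the exhaustive Hamming-scan oracle", {
  genome0 <- make_genome(101, length = 8000, n_chrom = 2)
  imp <- implant_probes(genome0, 102, n_probes = 25,
                        mutations_per_probe = 2)
  pl <- place_all(imp$probes, imp$genome)
  for (i in seq_len(nrow(pl))) {
    oracle <- oracle_place(imp$probes$sequence[i], imp$genome)
    expect_equal(pl$status[i], oracle$status)
    expect_equal(pl$n_best[i], oracle$n_best)
    if (oracle$status != "unplaced") {
      expect_equal(pl$start[i], oracle$start)
      expect_equal(pl$strand[i], oracle$strand)
      expect_equal(pl$identity[i], oracle$identity)
    }
  }
  # truth recovery: every implant found where it was written
  expect_equal(pl$start[match(imp$truth$probe_id, pl$probe_id)],
               imp$truth$start)
})

test_that("exact matching equals naive substring search on both strands", {
  g <- make_genome(55, length = 3000)
  imp <- implant_probes(g, 56, n_probes = 10, probe_len = 40,
                        mutations_per_probe = 0)
  pl <- place_all(imp$probes, imp$genome, min_identity = 1)
  for (i in seq_len(nrow(pl))) {
    fwd <- gregexpr(imp$probes$sequence[i], imp$genome$sequence,
                    fixed = TRUE)[[1]]
    rev <- gregexpr(revcomp(imp$probes$sequence[i]), imp$genome$sequence,
                    fixed = TRUE)[[1]]
    n_naive <- sum(fwd > 0) + sum(rev > 0)
    expect_equal(pl$n_best[i], n_naive)
  }
})

test_that("lowering min_identity never decreases placeable probes", {
  g <- make_genome(77, length = 6000)
  imp <- implant_probes(g, 78, n_probes = 20, probe_len = 50,
                        mutations_per_probe = 2)
  placed_at <- function(mi) {
    sum(place_all(imp$probes, imp$genome,
                  min_identity = mi)$status != "unplaced")
  }
  n <- vapply(c(1, 0.98, 0.95, 0.9), placed_at, numeric(1))
  expect_true(all(diff(n) >= 0))
})

test_that("short probes are rejected singly but logged in batch", {
  genome <- tibble::tibble(id = "g", sequence = strrep("ACGT", 100))
  expect_error(place_probe(simple_probe("ACGTACGT"), genome, k = 21),
               "shorter than")
  probes <- dplyr::bind_rows(
    simple_probe(substr(genome$sequence, 1, 40), "ok"),
    simple_probe("ACGTACGT", "short")
  )
  pl <- place_all(probes, genome)
  expect_equal(pl$status, c("ambiguous", "unplaced"))  # ACGT repeat
  expect_match(pl$reason[2], "length 8 < k")
})

test_that("uncalled-locus clustering matches single-linkage closure", {
  regions <- cluster_uncalled(
    tibble::tibble(chrom = c("1A", "1A", "5A"),
                   pos = c(12e6, 15e6, 413e6)),
    max_gap = 1e7
  )
  expect_equal(nrow(regions), 2L)
  expect_equal(regions$n_loci, c(2L, 1L))
  expect_equal(regions$min_pos, c(12e6, 413e6))

  one <- cluster_uncalled(tibble::tibble(chrom = "2B", pos = 5), 10)
  expect_equal(one$max_pos - one$min_pos, 0)
  expect_equal(one$n_loci, 1L)

  expect_equal(nrow(cluster_uncalled(
    tibble::tibble(chrom = character(), pos = numeric()), 10)), 0L)

  withr::with_seed(9, {
    for (rep in 1:5) {
      chrom <- sample(c("c1", "c2"), 40, replace = TRUE)
      pos <- sample(1e6, 40)
      gap <- sample(c(1e3, 1e4, 1e5), 1)
      got <- cluster_uncalled(tibble::tibble(chrom = chrom, pos = pos), gap)
      comp <- oracle_cluster(chrom, pos, gap)
      # same number of regions and same membership sizes per chromosome
      expect_equal(nrow(got), length(unique(comp)))
      expect_equal(sort(got$n_loci), sort(as.integer(table(comp))))
    }
  })
})
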