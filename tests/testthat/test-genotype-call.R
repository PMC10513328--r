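probe_row <- function(id, a, b, offset = 0L) {
  tibble::tibble(probe_id = id, sequence = "ACGT", snp_offset = offset,
                 allele_a = a, allele_b = b)
}

locus_row <- function(id, target, pos, strand) {
  tibble::tibble(probe_id = id, target_id = target, snp_pos = pos,
                 strand = strand)
}

test_that("calls are complemented into chip orientation on minus strand", {
  genome <- tibble::tibble(id = "g", sequence = "TTGTT")
  # genome base G at pos 2; minus-strand probe with alleles A/C -> C
  calls <- extract_call(locus_row("p1", "g", 2L, "-"), genome,
                        probe_row("p1", "A", "C"))
  expect_equal(calls$call, "C")
  expect_equal(calls$status, "called")
})

test_that("missing and mismatching genome bases follow the call policy", {
  genome <- tibble::tibble(id = "g", sequence = "ANTRC")
  probes <- dplyr::bind_rows(
    probe_row("p1", "A", "C"), probe_row("p2", "A", "C"),
    probe_row("p3", "A", "C"), probe_row("p4", "A", "G")
  )
  loci <- dplyr::bind_rows(
    locus_row("p1", "g", 1L, "+"),   # N -> missing_base
    locus_row("p2", "g", 2L, "+"),   # T vs A/C -> mismatch
    locus_row("p3", "g", 0L, "+"),   # A -> called
    locus_row("p4", "g", 3L, "+")    # R = het A/G -> called
  )
  calls <- extract_call(loci, genome, probes)
  expect_equal(calls$status[match(paste0("p", 1:4), calls$probe_id)],
               c("missing_base", "allele_mismatch", "called", "called"))
  expect_equal(calls$call[calls$probe_id == "p2"], "N")
  expect_equal(calls$call[calls$probe_id == "p4"], "R")
  kept <- extract_call(loci, genome, probes, keep_mismatch = TRUE)
  expect_equal(kept$call[kept$probe_id == "p2"], "T")
  expect_error(extract_call(locus_row("p1", "g", 9L, "+"), genome,
                            probes), "outside")
})

test_that("complementing the genome and flipping strands leaves calls fixed", {
  g0 <- make_genome(31, length = 5000)
  imp <- implant_probes(g0, 32, n_probes = 15)
  pl <- place_all(imp$probes, imp$genome)
  loci <- project_snp(pl, imp$probes)
  base <- extract_call(loci, imp$genome, imp$probes)
  comp_genome <- dplyr::mutate(
    imp$genome,
    sequence = chartr("ACGT", "TGCA", .data$sequence)
  )
  flipped <- dplyr::mutate(loci,
                           strand = ifelse(.data$strand == "+", "-", "+"))
  again <- extract_call(flipped, comp_genome, imp$probes)
  expect_equal(again$call, base$call)
  expect_equal(again$status, base$status)
})

test_that("pseudomolecules follow panel order and N-pad uncalled loci", {
  calls <- tibble::tibble(probe_id = c("L1", "L3"), call = c("A", "G"))
  ps <- build_pseudomolecule(calls, c("L1", "L2", "L3"), "query")
  expect_equal(ps$sequence, "ANG")
  expect_error(
    build_pseudomolecule(
      tibble::tibble(probe_id = c("L1", "L1"), call = c("A", "C")),
      c("L1", "L2"), "q"),
    "duplicate call"
  )
  expect_error(
    build_pseudomolecule(tibble::tibble(probe_id = "LX", call = "A"),
                         c("L1", "L2"), "q"),
    "not in the panel"
  )
})

test_that("a synthetic accession rebuilds its generating genotype string", {
  g0 <- make_genome(61, length = 8000)
  imp <- implant_probes(g0, 62, n_probes = 40)
  pl <- place_all(imp$probes, imp$genome)
  loci <- project_snp(pl, imp$probes)
  calls <- extract_call(loci, imp$genome, imp$probes)
  ps <- build_pseudomolecule(calls[, c("probe_id", "call")],
                             imp$probes$probe_id, "query")
  truth_string <- paste(
    imp$truth$genome_allele[match(imp$probes$probe_id,
                                  imp$truth$probe_id)],
    collapse = ""
  )
  expect_equal(ps$sequence, truth_string)
  expect_equal(nchar(ps$sequence), nrow(imp$probes))
})

test_that("call_summary reconciles percentages at two decimals", {
  expect_equal(call_summary(3541, 32),
               tibble::tibble(called_count = 3509L, called_pct = 99.10,
                              uncalled_pct = 0.90))
  expect_equal(call_summary(100, 0)$called_pct, 100.00)
  expect_equal(call_summary(7, 3),
               tibble::tibble(called_count = 4L, called_pct = 57.14,
                              uncalled_pct = 42.86))
  s <- call_summary(7, 3)
  expect_equal(s$called_pct + s$uncalled_pct, 100.00)
  expect_error(call_summary(0, 0), "positive")
  expect_error(call_summary(10, 11), "between")
})

test_that("merging a pseudomolecule appends one row and is invertible", {
  panel <- random_panel(5, 6, 20, p_missing = 0.05)
  pseudo <- tibble::tibble(id = "query",
                           sequence = strrep("A", 20))
  merged <- merge_into_panel(panel, pseudo)
  expect_equal(nrow(merged), 7L)
  expect_equal(merged$accession[7], "query")
  expect_equal(merged[1:6, ], panel)   # original rows untouched
  expect_error(merge_into_panel(merged, pseudo), "already")
  expect_error(
    merge_into_panel(panel, tibble::tibble(id = "q2", sequence = "AAA")),
    "length"
  )
  restored <- merged[merged$accession != "query", ]
  expect_equal(restored, panel)
})

test_that("merged matrices keep genotype invariants on random inputs", {
  for (seed in 1:5) {
    panel <- random_panel(seed, 5, 15)
    pseudo <- build_pseudomolecule(
      tibble::tibble(probe_id = geno_loci(panel)[1:10],
                     call = strsplit(strrep("A", 10), "")[[1]]),
      geno_loci(panel), sprintf("q%d", seed)
    )
    merged <- merge_into_panel(panel, pseudo)
    expect_silent(panelkin:::validate_genotype_panel(merged))
    expect_equal(sum(merged[nrow(merged), -1] == "N"), 5L)
  }
})
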