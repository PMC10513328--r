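# Seeded generators for every input the pipeline consumes, with recorded
# ground truth: a random genome with implanted probe sites and known
# alleles, a genotype panel with controlled allele frequencies,
# heterozygosity, missingness and implanted duplicate pairs, and a
# descriptor table with a controlled covariance. All generators are pure
# functions of their seed and parameters (base RNG via withr::with_seed,
# so no global state leaks). Default sizes mirror a 1/10-scale germplasm
# study: ~26 accessions and ~354 loci.

#' Simulate a random genome
#'
#' Uniform random A/C/G/T sequence split over `n_chrom` chromosomes;
#' deterministic per seed.
#'
#' @param seed Integer seed.
#' @param length Total genome length in bp (>= 1000).
#' @param n_chrom Number of chromosomes (default 1), ids `chr1`, `chr2`, ...
#' @return A sequence tibble (`id`, `sequence`).
#' @export
make_genome <- function(seed, length = 100000, n_chrom = 1) {
  stopifnot(length >= 1000, n_chrom >= 1)
  per <- diff(floor(seq(0, length, length.out = n_chrom + 1)))
  withr::with_seed(seed, {
    tibble(
      id = paste0("chr", seq_len(n_chrom)),
      sequence = vapply(per, function(n) {
        paste(sample(HOM_LETTERS, n, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

#' Implant probe sites into a genome
#'
#' Generates `n_probes` random chip probes (SNP at the central offset, two
#' random distinct alleles) and writes each into the genome at a
#' non-overlapping random position and strand: the genome copy carries one
#' of the two alleles at the SNP site and exactly `mutations_per_probe`
#' substitutions elsewhere in the probe footprint. The recorded truth lets
#' placement, projection and allele extraction be checked end to end.
#'
#' @param genome Sequence tibble from [make_genome()].
#' @param seed Integer seed.
#' @param n_probes Number of probes (default 100).
#' @param probe_len Probe length in bp (default 91; long enough that two
#'   substitutions plus the SNP-site allele difference always leave an
#'   exact 21-mer seed).
#' @param mutations_per_probe Substitutions between each probe and its
#'   genomic copy, placed away from the SNP offset (default 0).
#' @param strand_mix Probability that a probe is implanted on the minus
#'   strand (default 0.5).
#' @return List with `genome` (modified), `probes` (probe tibble) and
#'   `truth`: tibble `probe_id`, `target_id`, `start` (0-based), `strand`,
#'   `snp_pos` (0-based genome coordinate), `genome_allele` (chip
#'   orientation).
#' @export
implant_probes <- function(genome, seed, n_probes = 100, probe_len = 91,
                           mutations_per_probe = 0, strand_mix = 0.5) {
  stopifnot(probe_len >= 21, mutations_per_probe >= 0,
            mutations_per_probe <= probe_len - 1)
  chrom_len <- nchar(genome$sequence)
  slots_per <- chrom_len %/% probe_len
  if (sum(slots_per) < n_probes) {
    abort(sprintf(
      "genome too small: %d non-overlapping slots of %d bp for %d probes",
      sum(slots_per), probe_len, n_probes
    ))
  }
  slot_chrom <- rep(seq_along(chrom_len), slots_per)
  slot_ofs <- unlist(lapply(slots_per, function(s) seq_len(s) - 1L))
  snp_offset <- probe_len %/% 2L
  withr::with_seed(seed, {
    pick <- sample(length(slot_chrom), n_probes)
    seqs <- strsplit(genome$sequence, "", fixed = TRUE)
    probes <- vector("list", n_probes)
    truth <- vector("list", n_probes)
    for (i in seq_len(n_probes)) {
      chrom <- slot_chrom[pick[i]]
      start0 <- slot_ofs[pick[i]] * probe_len          # 0-based
      probe_seq <- sample(HOM_LETTERS, probe_len, replace = TRUE)
      alleles <- sample(HOM_LETTERS, 2)
      probe_seq[snp_offset + 1L] <- alleles[1]
      genome_allele <- sample(alleles, 1)
      strand <- if (stats::runif(1) < strand_mix) "-" else "+"
      site <- probe_seq
      site[snp_offset + 1L] <- genome_allele
      if (mutations_per_probe > 0) {
        mut_pos <- sample(setdiff(seq_len(probe_len), snp_offset + 1L),
                          mutations_per_probe)
        for (p in mut_pos) {
          site[p] <- sample(setdiff(HOM_LETTERS, site[p]), 1)
        }
      }
      if (strand == "-") {
        site <- rev(unname(IUPAC_COMPLEMENT[site]))
      }
      seqs[[chrom]][(start0 + 1L):(start0 + probe_len)] <- site
      probes[[i]] <- tibble(
        probe_id = sprintf("probe%04d", i),
        sequence = paste(probe_seq, collapse = ""),
        snp_offset = snp_offset,
        allele_a = alleles[1], allele_b = alleles[2],
        chrom_hint = genome$id[chrom],
        pos_hint = if (strand == "+") start0 + snp_offset
                   else start0 + probe_len - 1L - snp_offset
      )
      truth[[i]] <- tibble(
        probe_id = sprintf("probe%04d", i),
        target_id = genome$id[chrom],
        start = start0,
        strand = strand,
        snp_pos = if (strand == "+") start0 + snp_offset
                  else start0 + probe_len - 1L - snp_offset,
        genome_allele = genome_allele
      )
    }
    list(
      genome = tibble(
        id = genome$id,
        sequence = vapply(seqs, paste, character(1), collapse = "")
      ),
      probes = dplyr::bind_rows(probes),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Simulate a chip-genotype panel with implanted duplicates
#'
#' Base accessions are drawn independently per locus: two random distinct
#' alleles per locus, a heterozygote with probability `het_rate`,
#' otherwise a homozygote for the first allele with the locus's allele
#' frequency; calls are masked to N with probability `missing_rate`.
#' Duplicate (and optionally divergent) accessions are then appended by
#' copying a base row and flipping exactly `round(noise * n_hom)` of its
#' homozygous non-missing sites to the other allele, so the realized
#' homozygous difference of each implanted pair is controlled rather than
#' sampled.
#'
#' @param seed Integer seed.
#' @param n_accessions Total accessions including copies (default 26).
#' @param n_loci Number of loci (default 354); ids `L0001`, ...
#' @param allele_freqs Optional numeric vector (length `n_loci`) of
#'   first-allele frequencies; default uniform in \[0.1, 0.9\].
#' @param alleles Optional data frame with columns `allele_a`, `allele_b`
#'   (one row per locus) fixing the allele pair of each locus, e.g. the
#'   probe alleles of an implanted probe set; default random pairs.
#' @param het_rate Per-call heterozygote probability (default 0.05; selfing
#'   crops run low).
#' @param missing_rate Per-call missing probability (default 0.02).
#' @param n_duplicate_pairs Implanted near-identical pairs (default 2).
#' @param dup_noise Homozygous-difference level of duplicate copies
#'   (default 5e-4, under the 0.001 duplicate threshold).
#' @param n_divergent_pairs Implanted clearly-distinct copies (default 0).
#' @param divergent_noise Homozygous-difference level of divergent copies
#'   (default 0.05).
#' @return List with `panel` (genotype tibble) and `truth`: `alleles`
#'   (tibble `locus_id`, `allele_a`, `allele_b`, `freq_a`) and `pairs`
#'   (tibble `accession`, `source`, `type`, `n_flips`, `n_hom_sites`,
#'   `realized_homdiff`).
#' @export
simulate_panel <- function(seed, n_accessions = 26, n_loci = 354,
                           allele_freqs = NULL, alleles = NULL,
                           het_rate = 0.05,
                           missing_rate = 0.02, n_duplicate_pairs = 2,
                           dup_noise = 5e-4, n_divergent_pairs = 0,
                           divergent_noise = 0.05) {
  rates <- c(het_rate, missing_rate, dup_noise, divergent_noise)
  stopifnot(all(rates >= 0 & rates <= 1))
  n_copies <- n_duplicate_pairs + n_divergent_pairs
  n_base <- n_accessions - n_copies
  if (n_base < max(1, n_copies)) {
    abort("n_accessions too small for the requested implanted pairs")
  }
  withr::with_seed(seed, {
    freq <- allele_freqs %||% stats::runif(n_loci, 0.1, 0.9)
    stopifnot(length(freq) == n_loci)
    locus_ids <- sprintf("L%04d", seq_len(n_loci))
    pair_alleles <- if (is.null(alleles)) {
      t(replicate(n_loci, sample(HOM_LETTERS, 2)))
    } else {
      stopifnot(nrow(alleles) == n_loci)
      cbind(alleles$allele_a, alleles$allele_b)
    }
    het_code <- iupac_het(pair_alleles[, 1], pair_alleles[, 2])
    base_ids <- sprintf("ACC%03d", seq_len(n_base))
    m <- matrix("N", n_base, n_loci, dimnames = list(base_ids, locus_ids))
    for (i in seq_len(n_base)) {
      u <- stats::runif(n_loci)
      call <- ifelse(u < het_rate, het_code,
                     ifelse(stats::runif(n_loci) < freq,
                            pair_alleles[, 1], pair_alleles[, 2]))
      call[stats::runif(n_loci) < missing_rate] <- "N"
      m[i, ] <- call
    }
    copy_types <- c(rep("duplicate", n_duplicate_pairs),
                    rep("divergent", n_divergent_pairs))
    copy_noise <- c(rep(dup_noise, n_duplicate_pairs),
                    rep(divergent_noise, n_divergent_pairs))
    pairs <- vector("list", n_copies)
    if (n_copies > 0) {
      copies <- matrix("N", n_copies, n_loci)
      copy_ids <- character(n_copies)
      for (j in seq_len(n_copies)) {
        src <- j   # copy the j-th base accession
        row <- m[src, ]
        hom_sites <- which(row %in% HOM_LETTERS)
        n_flips <- round(copy_noise[j] * length(hom_sites))
        if (n_flips > 0) {
          flip <- sample(hom_sites, n_flips)
          other <- ifelse(row[flip] == pair_alleles[flip, 1],
                          pair_alleles[flip, 2], pair_alleles[flip, 1])
          row[flip] <- other
        }
        copies[j, ] <- row
        copy_ids[j] <- sprintf("%s_%s", base_ids[src],
                               if (copy_types[j] == "duplicate") "dup"
                               else "div")
        pairs[[j]] <- tibble(
          accession = copy_ids[j], source = base_ids[src],
          type = copy_types[j], n_flips = as.integer(n_flips),
          n_hom_sites = length(hom_sites),
          realized_homdiff = n_flips / length(hom_sites)
        )
      }
      rownames(copies) <- copy_ids
      colnames(copies) <- locus_ids
      m <- rbind(m, copies)
    }
    list(
      panel = geno_tibble(m),
      truth = list(
        alleles = tibble(locus_id = locus_ids,
                         allele_a = pair_alleles[, 1],
                         allele_b = pair_alleles[, 2],
                         freq_a = freq),
        pairs = dplyr::bind_rows(pairs)
      )
    )
  })
}

#' Simulate a morphological descriptor table
#'
#' Multivariate normal draws around a CPVO-like midpoint of 5 with a
#' controlled covariance: supply a full covariance matrix, or an
#' eigenvalue spectrum (rotated by a seeded random orthogonal basis), or
#' accept a geometrically decaying default spectrum. With `exact = TRUE`
#' the empirical covariance of the generated table equals the requested
#' covariance exactly (useful for validating variance-decomposition
#' reporting); with `ordinal = TRUE` (default) scores are rounded and
#' clamped to the 1-9 ordinal scale, which perturbs the covariance the way
#' real ordinal scoring does.
#'
#' @param seed Integer seed.
#' @param n_accessions Number of accessions (default 30).
#' @param n_descriptors Number of descriptors (default 24; CPVO protocol
#'   size), ids `D01`, ...
#' @param eigenvalues Optional spectrum (length `n_descriptors`,
#'   positive).
#' @param covariance Optional full covariance matrix (overrides
#'   `eigenvalues`).
#' @param ordinal Round to the 1-9 ordinal scale (default TRUE).
#' @param exact Make the empirical covariance exactly the requested one
#'   (default FALSE; forces `ordinal = FALSE` semantics and requires
#'   `n_accessions > n_descriptors`).
#' @return List with `table` (descriptor tibble) and `truth`:
#'   `covariance`, `eigenvalues`.
#' @export
simulate_descriptors <- function(seed, n_accessions = 30,
                                 n_descriptors = 24, eigenvalues = NULL,
                                 covariance = NULL, ordinal = TRUE,
                                 exact = FALSE) {
  stopifnot(n_accessions >= 3, n_descriptors >= 2)
  if (exact && n_accessions <= n_descriptors) {
    abort("exact covariance mode needs n_accessions > n_descriptors")
  }
  withr::with_seed(seed, {
    if (is.null(covariance)) {
      lambda <- eigenvalues %||% exp(-0.25 * (seq_len(n_descriptors) - 1))
      stopifnot(length(lambda) == n_descriptors, all(lambda > 0))
      Q <- qr.Q(qr(matrix(stats::rnorm(n_descriptors^2), n_descriptors)))
      covariance <- Q %*% diag(lambda) %*% t(Q)
    }
    ok <- tryCatch({ chol(covariance); TRUE }, error = function(e) FALSE)
    if (!ok) abort("covariance specification is not positive definite")
    x <- MASS::mvrnorm(n_accessions, mu = rep(5, n_descriptors),
                       Sigma = covariance, empirical = exact)
    if (ordinal && !exact) {
      x <- pmin(pmax(round(x), 1), 9)
    }
    colnames(x) <- sprintf("D%02d", seq_len(n_descriptors))
    table <- dplyr::bind_cols(
      tibble(accession = sprintf("ACC%03d", seq_len(n_accessions))),
      as_tibble(x)
    )
    list(
      table = table,
      truth = list(covariance = covariance,
                   eigenvalues = sort(eigen(covariance,
                                            symmetric = TRUE,
                                            only.values = TRUE)$values,
                                      decreasing = TRUE))
    )
  })
}

#' Write a complete synthetic fixture set to a directory
#'
#' Generates a genome with implanted probes, a genotype panel and a
#' descriptor table under one seed and writes them as plain-text files
#' (`genome.fasta`, `probes.csv`, `panel.csv`, `descriptors.csv`) plus a
#' `truth.json` with the generating ground truth.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed.
#' @param n_probes,probe_len,mutations_per_probe Passed to
#'   [implant_probes()].
#' @param genome_length,n_chrom Passed to [make_genome()].
#' @param ... Passed to [simulate_panel()]. The panel's loci are renamed
#'   to the implanted probe ids so the two halves of the fixture share a
#'   locus namespace.
#' @return The list of generated objects, invisibly.
#' @export
simulate_fixtures <- function(dir, seed, n_probes = 100, probe_len = 71,
                              mutations_per_probe = 0,
                              genome_length = 100000, n_chrom = 2, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome0 <- make_genome(seed, length = genome_length, n_chrom = n_chrom)
  imp <- implant_probes(genome0, seed + 1L, n_probes = n_probes,
                        probe_len = probe_len,
                        mutations_per_probe = mutations_per_probe)
  sim <- simulate_panel(seed + 2L, n_loci = n_probes,
                        alleles = imp$probes, ...)
  loci_map <- imp$probes$probe_id
  names(sim$panel) <- c("accession", loci_map)
  sim$truth$alleles$locus_id <- loci_map
  write_fasta(imp$genome, file.path(dir, "genome.fasta"))
  readr::write_csv(imp$probes, file.path(dir, "probes.csv"),
                   progress = FALSE)
  write_genotype_table(sim$panel, file.path(dir, "panel.csv"))
  desc <- simulate_descriptors(seed + 3L)
  readr::write_csv(desc$table, file.path(dir, "descriptors.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(seed = seed, placement = imp$truth, pairs = sim$truth$pairs),
    file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(list(genome = imp$genome, probes = imp$probes,
                 placement_truth = imp$truth, panel = sim$panel,
                 panel_truth = sim$truth, descriptors = desc))
}
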