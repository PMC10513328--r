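# Probe placement on a consensus genome: exact k-mer seeding of probe
# k-mers on both strands, followed by full-length ungapped extension scored
# by identity. N in the genome never counts as a match. The location(s) of
# maximal identity >= min_identity are reported; one winner -> unique,
# several -> ambiguous (never resolved arbitrarily), none -> unplaced.

N_INT <- utf8ToInt("N")

# Seed index for one target sequence: hashed environment k-mer -> 1-based
# start positions, plus the integer-encoded sequence for fast comparison.
index_target <- function(sequence, k) {
  n <- nchar(sequence)
  ints <- utf8ToInt(sequence)
  if (n < k) {
    return(list(env = new.env(parent = emptyenv()), ints = ints, n = n))
  }
  kmers <- substring(sequence, 1:(n - k + 1), k:n)
  env <- list2env(split(seq_along(kmers), kmers), hash = TRUE,
                  parent = emptyenv())
  list(env = env, ints = ints, n = n)
}

build_genome_index <- function(genome, k) {
  stopifnot(is.data.frame(genome), nrow(genome) > 0)
  idx <- lapply(genome$sequence, index_target, k = k)
  names(idx) <- genome$id
  idx
}

# Candidate 1-based alignment starts of `query` on the plus strand of one
# indexed target, from exact k-mer seeds.
seed_starts <- function(query, target_idx, k) {
  L <- nchar(query)
  qk <- substring(query, 1:(L - k + 1), k:L)
  env <- target_idx$env
  hits <- lapply(seq_along(qk), function(i) {
    pos <- env[[qk[i]]]
    if (is.null(pos)) NULL else pos - i + 1L
  })
  starts <- unique(unlist(hits))
  starts[starts >= 1L & starts + L - 1L <= target_idx$n]
}

# Identity of an ungapped full-length alignment at each candidate start.
extension_identity <- function(query_ints, target_idx, starts) {
  L <- length(query_ints)
  vapply(starts, function(s) {
    g <- target_idx$ints[s:(s + L - 1L)]
    sum(g == query_ints & g != N_INT) / L
  }, numeric(1))
}

place_one <- function(probe_seq, index, min_identity, k) {
  L <- nchar(probe_seq)
  rc <- revcomp(probe_seq)
  fwd_ints <- utf8ToInt(probe_seq)
  rev_ints <- utf8ToInt(rc)
  cand <- list()
  for (t in seq_along(index)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") probe_seq else rc
      qi <- if (strand == "+") fwd_ints else rev_ints
      starts <- seed_starts(q, index[[t]], k)
      if (length(starts) == 0) next
      ident <- extension_identity(qi, index[[t]], starts)
      keep <- ident >= min_identity
      if (!any(keep)) next
      cand[[length(cand) + 1L]] <- tibble(
        target_ord = t, target_id = names(index)[t],
        start = starts[keep] - 1L,       # 0-based
        end = starts[keep] - 1L + L,     # half-open
        strand = strand, identity = ident[keep]
      )
    }
  }
  if (length(cand) == 0) {
    return(tibble(
      target_id = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_, identity = NA_real_, n_best = 0L,
      status = "unplaced"
    ))
  }
  cand <- dplyr::bind_rows(cand)
  # a palindromic probe can hit the same interval on both strands; that is
  # one genomic location, reported once (plus strand preferred on a tie)
  cand <- cand[order(cand$target_ord, cand$start, -cand$identity,
                     cand$strand), , drop = FALSE]
  cand <- cand[!duplicated(cand[c("target_ord", "start", "end")]), ,
               drop = FALSE]
  best <- cand[cand$identity == max(cand$identity), , drop = FALSE]
  best <- best[order(best$target_ord, best$start, best$strand), , drop = FALSE]
  tibble(
    target_id = best$target_id[1], start = best$start[1], end = best$end[1],
    strand = best$strand[1], identity = best$identity[1],
    n_best = nrow(best),
    status = if (nrow(best) == 1L) "unique" else "ambiguous"
  )
}

#' Place one probe on a genome
#'
#' Finds candidate locations by exact k-mer seeding (both strands) and
#' scores each by ungapped full-length identity; see [place_all()] for the
#' batch interface that shares the seed index across probes.
#'
#' @param probe A one-row probe tibble (see [read_probe_table()]).
#' @param genome Sequence tibble from [read_fasta()].
#' @param k Seed length (default 21).
#' @param min_identity Minimum reportable identity fraction (default 0.95).
#' @return A one-row placement tibble: `probe_id`, `target_id`,
#'   `start` (0-based), `end` (half-open), `strand`, `identity`, `n_best`,
#'   `status` in unique/ambiguous/unplaced.
#' @export
place_probe <- function(probe, genome, k = 21, min_identity = 0.95) {
  stopifnot(is.data.frame(probe), nrow(probe) == 1)
  if (nchar(probe$sequence) < k) {
    abort(sprintf(
      "probe '%s' (length %d) is shorter than the seed length k=%d",
      probe$probe_id, nchar(probe$sequence), k
    ))
  }
  index <- build_genome_index(genome, k)
  dplyr::bind_cols(tibble(probe_id = probe$probe_id),
                   place_one(probe$sequence, index, min_identity, k))
}

#' Place a probe set on a genome
#'
#' Batch probe placement: one placement row per probe, input order
#' preserved, deterministic for fixed inputs. Probes shorter than the seed
#' length are reported `unplaced` with a `reason` rather than failing the
#' batch. Use [placement_summary()] for per-status counts.
#'
#' @inheritParams place_probe
#' @param probes Probe tibble.
#' @return Placement tibble with one row per probe (columns as in
#'   [place_probe()] plus `reason`).
#' @export
place_all <- function(probes, genome, k = 21, min_identity = 0.95) {
  stopifnot(is.data.frame(probes), nrow(probes) > 0)
  validate_probes(probes)
  index <- build_genome_index(genome, k)
  rows <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    if (nchar(probes$sequence[i]) < k) {
      rows[[i]] <- tibble(
        target_id = NA_character_, start = NA_integer_, end = NA_integer_,
        strand = NA_character_, identity = NA_real_, n_best = 0L,
        status = "unplaced",
        reason = sprintf("probe length %d < k=%d", nchar(probes$sequence[i]), k)
      )
    } else {
      rows[[i]] <- dplyr::mutate(
        place_one(probes$sequence[i], index, min_identity, k),
        reason = NA_character_
      )
    }
  }
  dplyr::bind_cols(tibble(probe_id = probes$probe_id), dplyr::bind_rows(rows))
}

#' Per-status placement counts
#'
#' @param placements Placement tibble from [place_all()].
#' @return A tibble with columns `status`, `n` and `pct` (percent of
#'   probes, two decimals), covering all three statuses.
#' @export
placement_summary <- function(placements) {
  counts <- table(factor(placements$status,
                         levels = c("unique", "ambiguous", "unplaced")))
  tibble(
    status = names(counts),
    n = as.integer(counts),
    pct = round_half_up(100 * as.integer(counts) / nrow(placements), 2)
  )
}

#' Project probe SNP offsets into genome coordinates
#'
#' For uniquely placed probes, converts the probe-local SNP offset into a
#' 0-based genome coordinate: `start + snp_offset` on the plus strand,
#' `end - 1 - snp_offset` on the minus strand.
#'
#' @param placements Placement tibble (all rows must have status "unique").
#' @param probes Probe tibble supplying `snp_offset` per `probe_id`.
#' @return SNP locus tibble: `probe_id`, `target_id`, `snp_pos` (0-based),
#'   `strand`.
#' @export
project_snp <- function(placements, probes) {
  bad <- placements$status != "unique"
  if (any(bad)) {
    abort(sprintf(
      "cannot project SNP for non-unique placement of probe '%s' (status %s)",
      placements$probe_id[bad][1], placements$status[bad][1]
    ))
  }
  j <- dplyr::inner_join(
    placements,
    dplyr::select(probes, "probe_id", "snp_offset"),
    by = "probe_id"
  )
  tibble(
    probe_id = j$probe_id,
    target_id = j$target_id,
    snp_pos = ifelse(j$strand == "+",
                     j$start + j$snp_offset,
                     j$end - 1L - j$snp_offset),
    strand = j$strand
  )
}

#' Cluster uncalled loci into genomic regions
#'
#' Single-linkage grouping of positions per chromosome: consecutive sorted
#' positions at most `max_gap` apart join one region. Used to ask whether
#' loci that failed to place or call fall in contiguous stretches of the
#' genome (suggesting low coverage or structural variation) rather than
#' scattering at random.
#'
#' @param uncalled Tibble with columns `chrom` and `pos` (numeric, bp).
#' @param max_gap Maximum within-region gap in bp.
#' @return Tibble of regions: `chrom`, `min_pos`, `max_pos`, `n_loci`,
#'   ordered by chromosome then position. Empty input gives zero rows.
#' @export
cluster_uncalled <- function(uncalled, max_gap) {
  stopifnot(all(c("chrom", "pos") %in% names(uncalled)))
  if (nrow(uncalled) == 0) {
    return(tibble(chrom = character(), min_pos = numeric(),
                  max_pos = numeric(), n_loci = integer()))
  }
  uncalled |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(region = cumsum(c(1, diff(.data$pos) > max_gap))) |>
    dplyr::group_by(.data$chrom, .data$region) |>
    dplyr::summarise(min_pos = min(.data$pos), max_pos = max(.data$pos),
                     n_loci = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"region")
}
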