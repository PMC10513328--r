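# Independent reference implementations used as oracles. These stay
# deliberately naive (full scans, all-pairs closures, textbook formulas)
# and share no code with the package internals they check.

# Exhaustive both-strand Hamming scan of one probe over a genome tibble.
# Every offset of every target is scored; the scan is organised as a
# shifted-window matrix (one column per offset) so a whole genome is
# compared in one vectorised operation per strand. Probes contain no N, so
# a genome N mismatches automatically. `index` (from oracle_windows())
# lets many same-length probes share the window matrices.
oracle_windows <- function(genome, L) {
  lapply(genome$sequence, function(s) {
    tint <- utf8ToInt(s)
    n <- length(tint)
    if (n < L) return(NULL)
    matrix(tint[outer(1:L, 0:(n - L), "+")], nrow = L)
  })
}

oracle_place <- function(probe_seq, genome, min_identity = 0.95,
                         index = NULL) {
  L <- nchar(probe_seq)
  if (is.null(index)) index <- oracle_windows(genome, L)
  revcomp_chr <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  hits <- list()
  for (t in seq_len(nrow(genome))) {
    G <- index[[t]]
    if (is.null(G)) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") probe_seq else revcomp_chr(probe_seq)
      p <- utf8ToInt(q)
      mism <- colSums(G != p)
      ident <- (L - mism) / L
      keep <- which(ident >= min_identity)
      if (length(keep) > 0) {
        hits[[length(hits) + 1]] <- data.frame(
          target_ord = t, target_id = genome$id[t],
          start = keep - 1L, strand = strand, identity = ident[keep]
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(list(status = "unplaced", n_best = 0L))
  }
  hits <- do.call(rbind, hits)
  # a palindromic probe hits the same interval on both strands: one locus
  hits <- hits[order(hits$target_ord, hits$start, -hits$identity,
                     hits$strand), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("target_ord", "start")]), , drop = FALSE]
  best <- hits[hits$identity == max(hits$identity), , drop = FALSE]
  best <- best[order(best$target_ord, best$start, best$strand), ,
               drop = FALSE]
  list(
    status = if (nrow(best) == 1) "unique" else "ambiguous",
    n_best = nrow(best),
    target_id = best$target_id[1], start = best$start[1],
    strand = best$strand[1], identity = best$identity[1]
  )
}

# All-pairs transitive closure over the "within max_gap on same chrom"
# graph, via iterated boolean closure.
oracle_cluster <- function(chrom, pos, max_gap) {
  n <- length(pos)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    chrom[i] == chrom[j] & abs(pos[i] - pos[j]) <= max_gap
  })
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  k <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      k <- k + 1
      comp[reach[i, ]] <- k
    }
  }
  comp
}

# Connected components from an edge list on 1..n by label propagation to
# a fixed point.
oracle_components <- function(n, edges) {
  comp <- seq_len(n)
  if (nrow(edges) > 0) {
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(edges))) {
        a <- comp[edges[e, 1]]
        b <- comp[edges[e, 2]]
        if (a != b) {
          comp[comp == max(a, b)] <- min(a, b)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(comp, unique(comp))
}

# Textbook squared Pearson correlation on pairwise-complete entries.
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  (sum((x - mean(x)) * (y - mean(y))))^2 / (sx * sy)
}

# Direct count of differing calls over sites where both are homozygous.
oracle_homdiff <- function(x, y) {
  hom <- c("A", "C", "G", "T")
  num <- 0L
  den <- 0L
  for (i in seq_along(x)) {
    if (x[i] %in% hom && y[i] %in% hom) {
      den <- den + 1L
      if (x[i] != y[i]) num <- num + 1L
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Naive transcription of the sliding-window LD pruning rule, using the
# per-pair oracle r2 (undefined treated as 1).
oracle_ld_prune <- function(dos, maf, r2_max, window, step) {
  n <- ncol(dos)
  retained <- rep(TRUE, n)
  for (s in seq(1, n, by = step)) {
    win <- s:min(s + window - 1, n)
    repeat {
      act <- win[retained[win]]
      if (length(act) < 2) break
      best <- NULL
      best_r2 <- -1
      for (a in seq_len(length(act) - 1)) {
        for (b in (a + 1):length(act)) {
          r2 <- oracle_r2(dos[, act[a]], dos[, act[b]])
          if (is.na(r2)) r2 <- 1
          if (r2 > r2_max && r2 > best_r2) {
            best_r2 <- r2
            best <- c(act[a], act[b])
          }
        }
      }
      if (is.null(best)) break
      drop <- if (maf[best[1]] < maf[best[2]]) best[1]
              else if (maf[best[2]] < maf[best[1]]) best[2]
              else max(best)
      retained[drop] <- FALSE
    }
    if (max(win) == n) break
  }
  colnames(dos)[retained]
}

# Build a genotype tibble from a character matrix of calls.
panel_from_matrix <- function(m, accessions = rownames(m), loci = NULL) {
  if (is.null(accessions)) accessions <- sprintf("a%02d", seq_len(nrow(m)))
  if (is.null(loci)) loci <- sprintf("L%03d", seq_len(ncol(m)))
  dimnames(m) <- list(accessions, loci)
  dplyr::bind_cols(tibble::tibble(accession = accessions),
                   tibble::as_tibble(m))
}

# Random genotype matrix of plain calls with controlled missingness.
random_panel <- function(seed, n_acc, n_loci, p_missing = 0.1,
                         p_het = 0.1) {
  withr::with_seed(seed, {
    pool <- c("A", "C", "G", "T", "R", "Y")
    m <- matrix(sample(c("A", "G"), n_acc * n_loci, replace = TRUE),
                n_acc, n_loci)
    m[matrix(runif(n_acc * n_loci) < p_het, n_acc, n_loci)] <- "R"
    m[matrix(runif(n_acc * n_loci) < p_missing, n_acc, n_loci)] <- "N"
    panel_from_matrix(m)
  })
}
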