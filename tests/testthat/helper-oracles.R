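# Independent oracles used by the test suite. These deliberately use
# different algorithms from the package code paths they check.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# reverse complement, coded independently of the package helper
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# ---- scanner oracle ----------------------------------------------------
# Regex-based brute search: for every period k, repeatedly take the
# leftmost backreference match ([ACGT]{k})\1{thr-1,} (greedy, so full
# units are maximal to the right), keep matches whose motif is primitive
# and that cannot be extended left with the same periodicity, and resume
# one unit after each match start so overlapping tracts are found.
oracle_scan <- function(seq, min_repeats = c(12, 8, 5, 5, 5, 5)) {
  s <- toupper(seq)
  chars <- strsplit(s, "")[[1]]
  n <- nchar(s)
  rows <- list()
  for (k in 1:6) {
    thr <- min_repeats[k]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, thr - 1L)
    pos <- 1L
    repeat {
      if (pos > n - k * thr + 1L) break
      m <- regexpr(pat, substr(s, pos, n), perl = TRUE)
      if (m == -1L) break
      a <- pos + as.integer(m) - 1L
      len <- attr(m, "match.length")
      motif <- substr(s, a, a + k - 1L)
      nrep <- len %/% k
      keep <- TRUE
      for (p in seq_len(k - 1L)) {
        if (k %% p == 0L &&
            identical(strrep(substr(motif, 1L, p), k %/% p), motif)) {
          keep <- FALSE
          break
        }
      }
      if (keep && a > 1L) {
        prev <- chars[a - 1L]
        if (prev %in% BASES && prev == chars[a - 1L + k]) keep <- FALSE
      }
      if (keep) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = a, end = a + nrep * k - 1L, motif = motif,
          motif_length = k, n_repeats = nrep, stringsAsFactors = FALSE)
      }
      pos <- a + k
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), motif_length = integer(0),
                      n_repeats = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif_length), ]
  rownames(out) <- NULL
  out
}

# GRanges scan result as a plain comparable frame
scan_frame <- function(gr) {
  df <- data.frame(start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   motif = S4Vectors::mcols(gr)$motif,
                   motif_length = S4Vectors::mcols(gr)$motifLength,
                   n_repeats = S4Vectors::mcols(gr)$nRepeats,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$motif_length), ]
  rownames(df) <- NULL
  df
}

# ---- melting-temperature oracle ----------------------------------------
# Second implementation of the unified nearest-neighbor model, coded from
# the published parameter table with a matrix lookup instead of named
# vectors.
oracle_tm <- function(s, Na = 0.05, CT = 5e-8) {
  dH <- matrix(NA_real_, 4, 4, dimnames = list(BASES, BASES))
  dS <- matrix(NA_real_, 4, 4, dimnames = list(BASES, BASES))
  set_nn <- function(din, h, sv) {
    a <- substr(din, 1, 1); b <- substr(din, 2, 2)
    dH[a, b] <<- h; dS[a, b] <<- sv
    rc <- oracle_revcomp(din)
    dH[substr(rc, 1, 1), substr(rc, 2, 2)] <<- h
    dS[substr(rc, 1, 1), substr(rc, 2, 2)] <<- sv
  }
  set_nn("AA", -7.9, -22.2); set_nn("AT", -7.2, -20.4)
  set_nn("TA", -7.2, -21.3); set_nn("CA", -8.5, -22.7)
  set_nn("GT", -8.4, -22.4); set_nn("CT", -7.8, -21.0)
  set_nn("GA", -8.2, -22.2); set_nn("CG", -10.6, -27.2)
  set_nn("GC", -9.8, -24.4); set_nn("GG", -8.0, -19.9)
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  H <- 0; S <- 0
  for (i in seq_len(L - 1)) {
    H <- H + dH[ch[i], ch[i + 1]]
    S <- S + dS[ch[i], ch[i + 1]]
  }
  for (endBase in ch[c(1, L)]) {
    if (endBase %in% c("G", "C")) {
      H <- H + 0.1; S <- S - 2.8
    } else {
      H <- H + 2.3; S <- S + 4.1
    }
  }
  sym <- identical(s, oracle_revcomp(s))
  if (sym) S <- S - 1.4
  S <- S + 0.368 * (L - 1) * log(Na)
  H * 1000 / (S + 1.987 * log(CT / if (sym) 1 else 4)) - 273.15
}

# ---- primer constraint validator ---------------------------------------
# Re-checks every design constraint of a returned pair from scratch.
validate_pair <- function(row, genomeSeq, cn = designConstraints()) {
  ok <- TRUE
  note <- function(cond, what) {
    if (!cond) {
      ok <<- FALSE
      message("constraint failed: ", what)
    }
  }
  f <- row$forward; r <- row$reverse
  note(nchar(f) >= cn$lenMin && nchar(f) <= cn$lenMax, "forward length")
  note(nchar(r) >= cn$lenMin && nchar(r) <= cn$lenMax, "reverse length")
  fStart <- row$forward_start
  fEnd <- fStart + nchar(f) - 1L
  rEnd <- row$reverse_end
  rStart <- rEnd - nchar(r) + 1L
  note(substr(genomeSeq, fStart, fEnd) == f, "forward matches genome")
  note(oracle_revcomp(substr(genomeSeq, rStart, rEnd)) == r,
       "reverse matches genome (opposite strand)")
  note(fEnd < row$start, "forward left of tract")
  note(rStart > row$end, "reverse right of tract")
  prod <- rEnd - fStart + 1L
  note(prod == row$product_size, "product size bookkeeping")
  note(prod >= cn$productMin && prod <= cn$productMax, "product size range")
  tf <- oracle_tm(f); tr <- oracle_tm(r)
  note(abs(tf - row$tm_forward) < 0.01, "forward Tm")
  note(abs(tr - row$tm_reverse) < 0.01, "reverse Tm")
  note(tf >= cn$tmMin && tf <= cn$tmMax, "forward Tm range")
  note(tr >= cn$tmMin && tr <= cn$tmMax, "reverse Tm range")
  note(abs(tf - tr) <= cn$maxPairTmDiff, "pair Tm difference")
  for (p in c(f, r)) {
    note(!grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", cn$maxHomopolymer,
                        cn$maxHomopolymer, cn$maxHomopolymer,
                        cn$maxHomopolymer), p), "homopolymer filter")
  }
  ok
}

# ---- diversity oracle ---------------------------------------------------
# Direct enumeration over allele copies for small matrices.
oracle_locus_stats <- function(a1, a2) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  copies <- c(a1, a2)
  tab <- table(copies)
  p <- as.numeric(tab) / length(copies)
  het <- sum(a1 != a2)
  S2 <- sum(p^2)
  picsum <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (j > i) picsum <- picsum + 2 * p[i]^2 * p[j]^2
    }
  }
  list(na = length(p), ng = length(unique(paste(pmin(a1, a2), pmax(a1, a2)))),
       major_freq = max(p), ho = het / length(a1),
       he = 1 - S2, pic = 1 - S2 - picsum)
}

# explicit band-count Dice for one pair of individuals
oracle_dice_pair <- function(g1, g2) {
  # g1, g2: lists of length-2 allele vectors (or NULL when missing)
  a <- 0; b <- 0; cc <- 0
  for (l in seq_along(g1)) {
    if (is.null(g1[[l]]) || is.null(g2[[l]])) next
    s1 <- unique(g1[[l]]); s2 <- unique(g2[[l]])
    a <- a + length(intersect(s1, s2))
    b <- b + length(setdiff(s1, s2))
    cc <- cc + length(setdiff(s2, s1))
  }
  2 * a / (2 * a + b + cc)
}

# small toy GFF3 writer for context tests
write_toy_gff <- function(path, rows) {
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    attrs <- if (is.na(r$parent)) {
      sprintf("ID=%s", r$id)
    } else {
      sprintf("ID=%s;Parent=%s", r$id, r$parent)
    }
    writeLines(paste(r$seqid, "toy", r$type, r$start, r$end, ".",
                     r$strand, ".", attrs, sep = "\t"), con)
  }
  close(con)
  path
}

toy_gene_row <- function(seqid, type, start, end, strand, id, parent = NA) {
  data.frame(seqid = seqid, type = type, start = start, end = end,
             strand = strand, id = id, parent = parent,
             stringsAsFactors = FALSE)
}
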