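## Unified nearest-neighbor duplex parameters (dH kcal/mol, dS cal/mol/K),
## keyed by the dinucleotide read 5'->3' on one strand; each entry equals
## its reverse-complement pair's entry.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # terminal G.C / A.T initiation
.NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic parameter set with terminal initiation terms, a sodium
#' entropy correction and a fixed oligo concentration:
#' \deqn{Tm = \Delta H \cdot 1000 / (\Delta S + 0.368 (L-1) \ln[Na^+]
#'   + R \ln(C_T/x)) - 273.15}
#' with R = 1.987 cal/(mol K) and x = 4 (x = 1 for self-complementary
#' oligos, which also gain the symmetry entropy term).
#'
#' @param oligo character vector of primer sequences (>= 8 bases, ACGT).
#' @param Na monovalent cation concentration, mol/L (default 0.05).
#' @param oligoConc total oligo concentration, mol/L (default 5e-8, 50 nM).
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @export
meltingTemperature <- function(oligo, Na = 0.05, oligoConc = 5e-8) {
  oligo <- toupper(as.character(oligo))
  if (any(!grepl("^[ACGT]+$", oligo))) {
    stop("oligo must contain only A/C/G/T")
  }
  if (any(nchar(oligo) < 8L)) stop("oligo must be at least 8 bases")
  R <- 1.987
  vapply(oligo, function(s) {
    L <- nchar(s)
    nn <- substring(s, 1:(L - 1L), 2:L)
    dH <- sum(.NN_DH[nn])
    dS <- sum(.NN_DS[nn])
    ends <- ifelse(substring(s, c(1L, L), c(1L, L)) %in% c("G", "C"),
                   "GC", "AT")
    dH <- dH + sum(.NN_INIT_DH[ends])
    dS <- dS + sum(.NN_INIT_DS[ends])
    selfComp <- identical(s, revcompChar(s))
    if (selfComp) dS <- dS - 1.4
    x <- if (selfComp) 1 else 4
    dS <- dS + 0.368 * (L - 1L) * log(Na)
    dH * 1000 / (dS + R * log(oligoConc / x)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer-design constraint set
#'
#' The constraint box used for locus-specific primer design: primer length
#' 18--28 bases (optimum 20), product size 100--300 bases, melting
#' temperature 55--65 degrees C (optimum 60) and a maximum pair Tm
#' difference of 1 degree C. Two sequence-quality filters may be toggled:
#' no homopolymer run of 5 or more bases, and no self-reverse-complement
#' stretch of 8 or more bases.
#'
#' @param lenMin,lenOpt,lenMax primer length bounds and optimum (bases).
#' @param productMin,productMax amplicon size bounds (bases).
#' @param tmMin,tmOpt,tmMax melting temperature bounds and optimum (C).
#' @param maxPairTmDiff maximum |Tm(forward) - Tm(reverse)| (C).
#' @param maxHomopolymer reject primers containing a run of this many
#'   identical bases or more; \code{Inf} disables the filter.
#' @param maxSelfComplement reject primers containing a self
#'   reverse-complementary stretch of this length or more; \code{Inf}
#'   disables the filter.
#' @return a named list of constraints.
#' @export
designConstraints <- function(lenMin = 18L, lenOpt = 20L, lenMax = 28L,
                              productMin = 100L, productMax = 300L,
                              tmMin = 55, tmOpt = 60, tmMax = 65,
                              maxPairTmDiff = 1,
                              maxHomopolymer = 5L,
                              maxSelfComplement = 8L) {
  stopifnot(lenMin <= lenOpt, lenOpt <= lenMax,
            tmMin <= tmOpt, tmOpt <= tmMax,
            productMin <= productMax, maxPairTmDiff > 0)
  list(lenMin = lenMin, lenOpt = lenOpt, lenMax = lenMax,
       productMin = productMin, productMax = productMax,
       tmMin = tmMin, tmOpt = tmOpt, tmMax = tmMax,
       maxPairTmDiff = maxPairTmDiff,
       maxHomopolymer = maxHomopolymer,
       maxSelfComplement = maxSelfComplement)
}

#' Design locus-specific primer pairs for microsatellite loci
#'
#' For each non-compound locus, exhaustively enumerates candidate forward
#' primers in the left flank and reverse primers in the right flank (both
#' within the constraint box), and returns the feasible pair minimizing the
#' penalty |len_F - opt| + |len_R - opt| + |Tm_F - opt| + |Tm_R - opt| +
#' |Tm_F - Tm_R|. The amplified product always contains the full repeat
#' tract. The search is deterministic; penalty ties are broken by leftmost,
#' then shortest, forward primer, then leftmost-starting, then shortest,
#' reverse primer.
#'
#' @param loci \code{GRanges} from \code{\link{scanSSRs}} (with
#'   \code{compound} column).
#' @param genome \code{DNAStringSet} or named character vector holding the
#'   sequences the loci were scanned from.
#' @param constraints from \code{\link{designConstraints}}.
#' @return a \code{data.frame}, one row per input locus, with columns
#'   seq_id, start, end, motif, canonical_motif, motif_length, n_repeats,
#'   status (\code{designed}, \code{compound_skipped} or
#'   \code{no_valid_pair}), forward, reverse (both 5'->3'), forward_start,
#'   reverse_end, tm_forward, tm_reverse, product_size, ta.
#' @export
designPrimers <- function(loci, genome, constraints = designConstraints()) {
  stopifnot(is(loci, "GRanges"))
  seqs <- .as_sequences(genome)
  n <- length(loci)
  out <- data.frame(
    seq_id = as.character(seqnames(loci)),
    start = start(loci), end = end(loci),
    motif = mcols(loci)$motif,
    canonical_motif = mcols(loci)$canonicalMotif,
    motif_length = mcols(loci)$motifLength,
    n_repeats = mcols(loci)$nRepeats,
    status = rep("no_valid_pair", n),
    forward = NA_character_, reverse = NA_character_,
    forward_start = NA_integer_, reverse_end = NA_integer_,
    tm_forward = NA_real_, tm_reverse = NA_real_,
    product_size = NA_integer_, ta = NA_real_,
    stringsAsFactors = FALSE)
  compound <- mcols(loci)$compound
  if (is.null(compound)) compound <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (isTRUE(compound[i])) {
      out$status[i] <- "compound_skipped"
      next
    }
    seqId <- out$seq_id[i]
    if (!seqId %in% names(seqs)) next
    pair <- .design_one(seqs[[seqId]], out$start[i], out$end[i], constraints)
    if (is.null(pair)) next
    out$status[i] <- "designed"
    out$forward[i] <- pair$forward
    out$reverse[i] <- pair$reverse
    out$forward_start[i] <- pair$forward_start
    out$reverse_end[i] <- pair$reverse_end
    out$tm_forward[i] <- pair$tm_forward
    out$tm_reverse[i] <- pair$tm_reverse
    out$product_size[i] <- pair$product_size
    out$ta[i] <- annealingTemperature(pair$tm_forward, pair$tm_reverse)
  }
  out
}

#' Annealing temperature from a primer pair's melting temperatures
#'
#' \code{round(min(tmForward, tmReverse)) - 3}, clipped to [50, 65] C.
#'
#' @param tmForward,tmReverse melting temperatures in degrees C.
#' @return annealing temperature(s) in degrees C.
#' @export
annealingTemperature <- function(tmForward, tmReverse) {
  pmin(65, pmax(50, round(pmin(tmForward, tmReverse)) - 3))
}

#' Remove primer pairs whose primer sequences recur across pairs
#'
#' Any primer sequence (forward or reverse, compared as exact strings)
#' occurring in more than one designed candidate marks all involved
#' candidates non-unique; markers sharing no primer with any other pair are
#' unique. Idempotent. Non-designed rows get \code{unique = NA}.
#'
#' @param markers data.frame from \code{\link{designPrimers}}.
#' @return the input with a logical \code{unique} column added/updated.
#' @export
deduplicatePairs <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("status", "forward", "reverse") %in% names(markers)))
  designed <- markers$status == "designed"
  primers <- c(markers$forward[designed], markers$reverse[designed])
  counts <- table(primers)
  dup <- names(counts)[counts > 1L]
  markers$unique <- NA
  markers$unique[designed] <-
    !(markers$forward[designed] %in% dup |
        markers$reverse[designed] %in% dup)
  markers
}

#' Primer retention bookkeeping
#'
#' Counts loci through the design stages (input, designed,
#' compound-skipped, no valid pair, removed by cross-pair deduplication,
#' retained) with percentages of the input total rounded to two decimals.
#' The stage counts (compound_skipped + no_valid_pair + dedup_removed +
#' retained) sum to the input count.
#'
#' @param markers data.frame from \code{\link{deduplicatePairs}} (or from
#'   \code{\link{designPrimers}}, in which case no pair is dedup-removed).
#' @return data.frame with columns stage, count, percent.
#' @export
retentionSummary <- function(markers) {
  n <- nrow(markers)
  designed <- sum(markers$status == "designed")
  compound <- sum(markers$status == "compound_skipped")
  nopair <- sum(markers$status == "no_valid_pair")
  uniq <- if ("unique" %in% names(markers)) {
    sum(markers$unique %in% TRUE)
  } else {
    designed
  }
  counts <- c(input = n, designed = designed, compound_skipped = compound,
              no_valid_pair = nopair, dedup_removed = designed - uniq,
              retained = uniq)
  data.frame(stage = names(counts), count = as.integer(counts),
             percent = .pct(counts, n), row.names = NULL)
}

## ---- internal search --------------------------------------------------

.design_one <- function(seq, tractStart, tractEnd, cn) {
  n <- nchar(seq)
  reach <- cn$productMax - cn$lenMin - 1L
  fWinStart <- max(1L, tractEnd - reach)
  fWinEnd <- tractStart - 1L
  rWinStart <- tractEnd + 1L
  rWinEnd <- min(n, tractStart + reach)
  fwd <- .candidates(seq, fWinStart, fWinEnd, cn, rightAnchor = FALSE)
  if (is.null(fwd)) return(NULL)
  rev <- .candidates(seq, rWinStart, rWinEnd, cn, rightAnchor = TRUE)
  if (is.null(rev)) return(NULL)
  ## pairwise product-size / Tm-difference feasibility
  prod <- outer(rev$end, fwd$start, "-") + 1L           # nrev x nfwd
  dTm <- abs(outer(rev$tm, fwd$tm, "-"))
  ok <- prod >= cn$productMin & prod <= cn$productMax &
    dTm <= cn$maxPairTmDiff
  if (!any(ok)) return(NULL)
  pen <- outer(rev$penalty, fwd$penalty, "+") + dTm
  pen[!ok] <- Inf
  ## ties: candidates are ordered by (position, length), forward varying
  ## along columns; pick smallest forward order, then smallest reverse order
  best <- which(pen == min(pen), arr.ind = TRUE)
  best <- best[order(best[, "col"], best[, "row"]), , drop = FALSE]
  ri <- best[1L, "row"]; fi <- best[1L, "col"]
  fseq <- substr(seq, fwd$start[fi], fwd$end[fi])
  rseq <- revcompChar(substr(seq, rev$start[ri], rev$end[ri]))
  list(forward = fseq, reverse = rseq,
       forward_start = fwd$start[fi], reverse_end = rev$end[ri],
       tm_forward = fwd$tm[fi], tm_reverse = rev$tm[ri],
       product_size = as.integer(rev$end[ri] - fwd$start[fi] + 1L))
}

## all constraint-passing primer candidates in a window; deterministic
## order: 5'-most genomic start first, then shorter primers first
.candidates <- function(seq, winStart, winEnd, cn, rightAnchor) {
  if (winEnd - winStart + 1L < cn$lenMin) return(NULL)
  lens <- cn$lenMin:cn$lenMax
  grid <- expand.grid(start = winStart:(winEnd - cn$lenMin + 1L),
                      len = lens)
  grid$end <- grid$start + grid$len - 1L
  grid <- grid[grid$end <= winEnd, ]
  if (!nrow(grid)) return(NULL)
  grid <- grid[order(grid$start, grid$len), ]
  oligo <- substring(seq, grid$start, grid$end)
  keep <- !grepl("N", oligo, fixed = TRUE)
  if (is.finite(cn$maxHomopolymer)) {
    hp <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                  cn$maxHomopolymer, cn$maxHomopolymer,
                  cn$maxHomopolymer, cn$maxHomopolymer)
    keep <- keep & !grepl(hp, oligo)
  }
  grid <- grid[keep, ]; oligo <- oligo[keep]
  if (!nrow(grid)) return(NULL)
  tm <- meltingTemperature(oligo)
  keep <- tm >= cn$tmMin & tm <= cn$tmMax
  grid <- grid[keep, ]; oligo <- oligo[keep]; tm <- tm[keep]
  if (!nrow(grid)) return(NULL)
  if (is.finite(cn$maxSelfComplement)) {
    keep <- !vapply(oligo, .has_self_rc, logical(1), k = cn$maxSelfComplement)
    grid <- grid[keep, ]; oligo <- oligo[keep]; tm <- tm[keep]
    if (!nrow(grid)) return(NULL)
  }
  list(start = grid$start, end = grid$end,
       tm = tm,
       penalty = abs(grid$len - cn$lenOpt) + abs(tm - cn$tmOpt))
}

## TRUE if any k-mer of the oligo also occurs reverse-complemented
.has_self_rc <- function(oligo, k) {
  L <- nchar(oligo)
  if (L < k) return(FALSE)
  kmers <- substring(oligo, 1:(L - k + 1L), k:L)
  any(vapply(kmers, function(x) {
    grepl(revcompChar(x), oligo, fixed = TRUE)
  }, logical(1)))
}
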