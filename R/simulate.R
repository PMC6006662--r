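#' Synthetic genome with planted microsatellites
#'
#' Builds a random background sequence guaranteed (by rejection sampling)
#' to contain no microsatellite at or above the scan thresholds, then
#' overwrites it with the requested repeat tracts verbatim. Junction bases
#' flanking each tract are set so the tract cannot extend by even a
#' partial unit, which makes the truth table exactly recoverable by
#' \code{\link{scanSSRs}}; assembly is re-sampled (bounded retries) in the
#' rare event a junction fix still creates or perturbs a detectable
#' repeat.
#'
#' @param planted data.frame with columns \code{motif}, \code{nRepeats},
#'   \code{start} (1-based offset of the tract) and optionally
#'   \code{seq_id} (default one sequence \code{"synth1"}). Tracts must not
#'   overlap and, unless a compound is wanted, should be separated by more
#'   than \code{compoundGap}.
#' @param length background length in bases (per sequence).
#' @param seed integer seed; the genome is byte-identical given it.
#' @param minRepeats scan thresholds the background must stay below.
#' @param maxTries resampling attempts before giving up.
#' @return list with \code{genome} (named character vector of sequences)
#'   and \code{truth} (\code{GRanges} of the planted tracts with motif
#'   annotations, as \code{scanSSRs} reports them).
#' @export
simulateGenome <- function(planted, length = 10000L, seed = 1L,
                           minRepeats = defaultMinRepeats(),
                           maxTries = 50L) {
  stopifnot(is.data.frame(planted) || is.null(planted))
  if (is.null(planted) || nrow(planted) == 0L) {
    planted <- data.frame(motif = character(0), nRepeats = integer(0),
                          start = integer(0))
  }
  if (is.null(planted$seq_id)) planted$seq_id <- rep("synth1",
                                                     nrow(planted))
  seqIds <- if (nrow(planted)) unique(planted$seq_id) else "synth1"
  tractLen <- nchar(planted$motif) * planted$nRepeats
  if (nrow(planted) && any(planted$start + tractLen - 1L > length)) {
    stop("planted tract does not fit in the sequence length")
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  genome <- list()
  truth <- list()
  for (sid in seqIds) {
    sel <- planted[planted$seq_id == sid, , drop = FALSE]
    ord <- order(sel$start)
    sel <- sel[ord, , drop = FALSE]
    if (nrow(sel) > 1L) {
      ends <- sel$start + nchar(sel$motif) * sel$nRepeats - 1L
      if (any(sel$start[-1L] <= ends[-nrow(sel)])) {
        stop("planted tracts overlap on sequence ", sid)
      }
    }
    done <- FALSE
    for (try in seq_len(maxTries)) {
      bg <- paste(sample(bases, length, replace = TRUE), collapse = "")
      if (length(scanSSRs(setNames(bg, sid), minRepeats = minRepeats,
                          flagCompounds = FALSE)) > 0L) next
      s <- strsplit(bg, "")[[1L]]
      inTract <- rep(FALSE, length)
      for (r in seq_len(nrow(sel))) {
        a <- sel$start[r]
        b <- a + nchar(sel$motif[r]) * sel$nRepeats[r] - 1L
        inTract[a:b] <- TRUE
      }
      for (r in seq_len(nrow(sel))) {
        tract <- strrep(sel$motif[r], sel$nRepeats[r])
        a <- sel$start[r]; b <- a + nchar(tract) - 1L
        k <- nchar(sel$motif[r])
        s[a:b] <- strsplit(tract, "")[[1L]]
        ## break periodicity at the junctions (never inside another tract)
        if (a > 1L && !inTract[a - 1L]) {
          avoid <- unique(c(s[a + k - 1L],
                            if (a > 2L) s[a - 2L] else character(0)))
          s[a - 1L] <- setdiff(bases, avoid)[1L]
        }
        if (b < length && !inTract[b + 1L]) {
          avoid <- unique(c(s[b - k + 1L], s[b],
                            if (b + 2L <= length) s[b + 2L]
                            else character(0)))
          s[b + 1L] <- setdiff(bases, avoid)[1L]
        }
      }
      candidate <- paste(s, collapse = "")
      found <- scanSSRs(setNames(candidate, sid), minRepeats = minRepeats,
                        flagCompounds = FALSE)
      expected <- data.frame(
        start = sel$start,
        end = sel$start + nchar(sel$motif) * sel$nRepeats - 1L,
        motif = sel$motif, n = sel$nRepeats)
      okSame <- length(found) == nrow(expected) &&
        (nrow(expected) == 0L ||
           (all(start(found) == expected$start) &&
              all(end(found) == expected$end) &&
              all(mcols(found)$motif == expected$motif) &&
              all(mcols(found)$nRepeats == expected$n)))
      if (okSame) {
        genome[[sid]] <- candidate
        truth[[sid]] <- found
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not assemble a clean background for ", sid,
                    " in ", maxTries, " tries (infeasible packing?)")
  }
  truthGr <- if (base::length(truth)) {
    suppressWarnings(do.call(c, unname(truth)))
  } else {
    scanSSRs(setNames("", "synth1"))
  }
  list(genome = unlist(genome), truth = truthGr)
}

#' Simulate a codominant genotype panel with known population structure
#'
#' Per locus, a base allele-frequency vector is drawn and each
#' population's frequencies are drawn from a Dirichlet distribution
#' centered on it; the \code{divergence} parameter scales the Dirichlet
#' concentration (total concentration = alleles/divergence), so larger
#' values give more strongly diverged populations and 0 recovers identical
#' populations. Outlier individuals draw from a private frequency set:
#' each allele copy is, with probability \code{outlierPrivateFraction}, a
#' private allele absent from both populations (distinct fragment sizes on
#' the same ladder) and otherwise a draw from frequencies diverged from
#' population 1 by \code{outlierDivergence} times the population
#' divergence. The outlier is thus related to population 1 but distant
#' from both groups, emulating a distinct germplasm accession that
#' branches basally in a cluster analysis while siding with population 1
#' at K = 2. Individuals draw two allele copies per locus; allele states
#' are emitted as plausible fragment sizes.
#' A locus is redrawn when fewer than the minimum number of alleles
#' segregates in the sample, so the realized per-locus allele counts stay
#' within the requested range.
#'
#' The default preset emulates a diversity panel of 44 individuals typed
#' at 18 loci carrying 5--15 alleles each: two diverged populations of
#' 14 and 29 plus one outlier individual.
#'
#' @param nIndividuals total individuals (including outliers).
#' @param nLoci number of loci.
#' @param allelesPerLocus length-2 integer range of alleles per locus.
#' @param kTrue number of populations (excluding outliers).
#' @param popSizes sizes of the \code{kTrue} populations (must sum to
#'   \code{nIndividuals - outliers}); near-equal split when NULL.
#' @param divergence between-population divergence (> 0 for structure;
#'   0 gives a single panmictic pool).
#' @param outliers number of outlier individuals with private frequencies.
#' @param outlierDivergence outlier divergence from population 1, as a
#'   multiple of \code{divergence} (default 3).
#' @param outlierPrivateFraction probability that an outlier allele copy
#'   is a private allele (default 0.5).
#' @param missingRate per-cell missing probability in [0, 1).
#' @param seed integer seed; the matrix is identical given it.
#' @return list with \code{genotypes} (an \code{SSRGenotypes}) and
#'   \code{labels} (character vector: \code{pop1}.., or \code{outlier}).
#' @export
simulateGenotypes <- function(nIndividuals = 44L, nLoci = 18L,
                              allelesPerLocus = c(5L, 15L), kTrue = 2L,
                              popSizes = if (nIndividuals == 44L &&
                                             kTrue == 2L &&
                                             outliers == 1L) c(14L, 29L)
                                         else NULL,
                              divergence = 1.5, outliers = 1L,
                              outlierDivergence = 3,
                              outlierPrivateFraction = 0.7,
                              missingRate = 0.02, seed = 1L) {
  stopifnot(nIndividuals >= kTrue, divergence >= 0,
            missingRate >= 0, missingRate < 1,
            length(allelesPerLocus) == 2L)
  if (allelesPerLocus[2L] < 2L && kTrue > 1L) {
    stop("at least 2 alleles per locus are needed for structure")
  }
  nCore <- nIndividuals - outliers
  if (is.null(popSizes)) {
    popSizes <- diff(round(seq(0, nCore, length.out = kTrue + 1L)))
  }
  stopifnot(sum(popSizes) == nCore)
  set.seed(as.integer(seed))
  labels <- c(rep(paste0("pop", seq_len(kTrue)), popSizes),
              rep("outlier", outliers))
  popOf <- c(rep(seq_len(kTrue), popSizes),
             rep(kTrue + seq_len(outliers), outliers > 0))
  a1 <- matrix(NA_integer_, nLoci, nIndividuals)
  a2 <- matrix(NA_integer_, nLoci, nIndividuals)
  nGroups <- kTrue + outliers
  for (l in seq_len(nLoci)) {
    for (try in seq_len(100L)) {
      A <- sample(allelesPerLocus[1L]:allelesPerLocus[2L], 1L)
      base <- .rdirichlet(rep(1.5, A))
      freqs <- matrix(0, A, nGroups)
      for (g in seq_len(kTrue)) {
        freqs[, g] <- if (divergence > 0) {
          .rdirichlet(base * A / divergence)
        } else {
          base
        }
      }
      for (g in seq.int(kTrue + 1L, length.out = nGroups - kTrue)) {
        ## outliers diverge from population 1, further than the
        ## populations diverge from each other
        d <- divergence * outlierDivergence
        freqs[, g] <- if (d > 0) {
          .rdirichlet(freqs[, 1L] * A / d)
        } else {
          freqs[, 1L]
        }
      }
      nPrivate <- if (outliers > 0L) 2L else 0L
      motifStep <- 2L
      nLadder <- A + nPrivate
      sizeStart <- sample(100:(300 - motifStep * (nLadder - 1L)), 1L)
      sizes <- sizeStart + motifStep * (0:(nLadder - 1L))
      privFreq <- if (nPrivate) .rdirichlet(rep(1, nPrivate))
      g1 <- integer(nIndividuals); g2 <- integer(nIndividuals)
      for (i in seq_len(nIndividuals)) {
        p <- freqs[, popOf[i]]
        draws <- sample.int(A, 2L, replace = TRUE, prob = p)
        if (popOf[i] > kTrue && nPrivate) {
          priv <- runif(2L) < outlierPrivateFraction
          draws[priv] <- A + sample.int(nPrivate, sum(priv),
                                        replace = TRUE, prob = privFreq)
        }
        g1[i] <- sizes[draws[1L]]
        g2[i] <- sizes[draws[2L]]
      }
      nObs <- length(unique(c(g1, g2)))
      if (nObs >= allelesPerLocus[1L] && nObs <= allelesPerLocus[2L]) break
    }
    a1[l, ] <- g1
    a2[l, ] <- g2
  }
  if (missingRate > 0) {
    miss <- matrix(runif(nLoci * nIndividuals) < missingRate,
                   nLoci, nIndividuals)
    ## keep at least one call per locus
    for (l in seq_len(nLoci)) if (all(miss[l, ])) miss[l, 1L] <- FALSE
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  rownames(a1) <- rownames(a2) <- sprintf("locus%02d", seq_len(nLoci))
  colnames(a1) <- colnames(a2) <- sprintf("ind%02d", seq_len(nIndividuals))
  list(genotypes = SSRGenotypes(a1, a2), labels = labels)
}

.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-6))
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}
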