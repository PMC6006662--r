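#' Default minimum repeat-number thresholds per motif-length class
#'
#' Twelve repeats for mononucleotide motifs, eight for dinucleotide and
#' five for tri- through hexanucleotide motifs.
#'
#' @return named integer vector of length 6 (mono..hexa).
#' @export
defaultMinRepeats <- function() {
  c(mono = 12L, di = 8L, tri = 5L, tetra = 5L, penta = 5L, hexa = 5L)
}

.CLASS_NAMES <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' Scan sequences for perfect microsatellites
#'
#' Detects every maximal perfect tandem repeat of period 1--6 whose number
#' of full repeat units meets the per-class threshold. Motifs are reported
#' at their minimal period (a poly-A run is mono, never (AA)n), only full
#' units are counted (a trailing partial unit terminates the tract), and
#' N bases never belong to a repeat tract. Overlapping maximal tracts of
#' different periods at tract borders are all reported and can then be
#' flagged as compound.
#'
#' @param subject a \code{DNAStringSet}, a named character vector of
#'   uppercase sequences over A/C/G/T/N, or a path to a FASTA file.
#' @param minRepeats integer vector of length 6: minimum full repeat units
#'   for motif lengths 1..6; all values must be >= 2.
#' @param compoundGap maximum gap (bases) between two tracts for them to be
#'   flagged compound; see \code{\link{flagCompound}}.
#' @param flagCompounds logically, whether to flag compound loci.
#' @return a \code{GRanges} (1-based inclusive coordinates, forward strand)
#'   with metadata columns \code{motif}, \code{canonicalMotif},
#'   \code{motifLength}, \code{nRepeats}, \code{compound}.
#' @examples
#' scanSSRs(c(toy = paste0("GG", strrep("AT", 8), "C")))
#' @export
scanSSRs <- function(subject, minRepeats = defaultMinRepeats(),
                     compoundGap = 0L, flagCompounds = TRUE) {
  seqs <- .as_sequences(subject)
  minRepeats <- .check_min_repeats(minRepeats)
  per <- lapply(seq_along(seqs), function(i) {
    df <- .scan_one_sequence(seqs[[i]], minRepeats)
    if (nrow(df)) df$seq_id <- names(seqs)[i]
    df
  })
  per <- per[vapply(per, nrow, integer(1)) > 0L]
  if (!length(per)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(motif = character(0),
                           canonicalMotif = character(0),
                           motifLength = integer(0), nRepeats = integer(0),
                           compound = logical(0))
    return(gr)
  }
  df <- do.call(rbind, per)
  gr <- GRanges(df$seq_id, IRanges(df$start, df$end), strand = "+")
  mcols(gr) <- DataFrame(
    motif = df$motif,
    canonicalMotif = canonicalizeMotif(df$motif),
    motifLength = df$motif_length,
    nRepeats = df$n_repeats,
    compound = FALSE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (flagCompounds) gr <- flagCompound(gr, maxGap = compoundGap)
  gr
}

#' Flag compound microsatellite loci
#'
#' Two tracts on the same sequence whose gap (start2 - end1 - 1) is at most
#' \code{maxGap} are both marked compound; marking is symmetric and runs
#' transitively along chains of adjacent tracts. Overlapping tracts
#' (negative gap) are always compound.
#'
#' @param loci \code{GRanges} from \code{\link{scanSSRs}}.
#' @param maxGap maximum separating gap in bases (default 0: directly
#'   abutting or overlapping tracts).
#' @return the input with the \code{compound} column updated.
#' @export
flagCompound <- function(loci, maxGap = 0L) {
  stopifnot(is(loci, "GRanges"), maxGap >= 0L)
  if (!length(loci)) return(loci)
  hits <- findOverlaps(loci, loci, maxgap = as.integer(maxGap),
                       ignore.strand = TRUE)
  other <- queryHits(hits) != subjectHits(hits)
  mcols(loci)$compound <- seq_along(loci) %in% queryHits(hits)[other]
  loci
}

#' Summarize microsatellite class distributions
#'
#' Counts loci per motif-length class, per canonical motif, and per
#' (class, repeat-number) cell, with percentages of the grand total rounded
#' to two decimals.
#'
#' @param loci \code{GRanges} from \code{\link{scanSSRs}}, or a data.frame
#'   with a \code{motifLength} column (columns \code{canonicalMotif} and
#'   \code{nRepeats} optional).
#' @return list with elements \code{total}, \code{classes} (class, count,
#'   percent), \code{motifs} (class, canonicalMotif, count, percent,
#'   percentWithinClass) and \code{byRepeatCount} (class, nRepeats, count).
#' @export
summarizeClasses <- function(loci) {
  df <- .loci_frame(loci)
  total <- nrow(df)
  cls <- factor(.CLASS_NAMES[df$motifLength], levels = .CLASS_NAMES)
  counts <- as.integer(table(cls))
  classes <- data.frame(
    class = .CLASS_NAMES,
    count = counts,
    percent = .pct(counts, total))
  motifs <- NULL
  if (!is.null(df$canonicalMotif) && total > 0L) {
    tab <- as.data.frame(table(class = cls, canonicalMotif = df$canonicalMotif),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, ]
    clsTotal <- classes$count[match(tab$class, classes$class)]
    motifs <- data.frame(
      class = tab$class, canonicalMotif = tab$canonicalMotif,
      count = tab$Freq,
      percent = .pct(tab$Freq, total),
      percentWithinClass = .pct(tab$Freq, clsTotal))
    motifs <- motifs[order(match(motifs$class, .CLASS_NAMES),
                           -motifs$count, motifs$canonicalMotif), ]
    rownames(motifs) <- NULL
  }
  byRepeat <- NULL
  if (!is.null(df$nRepeats) && total > 0L) {
    byRepeat <- as.data.frame(table(class = cls, nRepeats = df$nRepeats),
                              stringsAsFactors = FALSE)
    byRepeat <- byRepeat[byRepeat$Freq > 0L, ]
    names(byRepeat)[3L] <- "count"
    byRepeat$nRepeats <- as.integer(byRepeat$nRepeats)
    byRepeat <- byRepeat[order(match(byRepeat$class, .CLASS_NAMES),
                               byRepeat$nRepeats), ]
    rownames(byRepeat) <- NULL
  }
  list(total = total, classes = classes, motifs = motifs,
       byRepeatCount = byRepeat)
}

#' Write / read an SSR table
#'
#' Tab-separated table with columns seq_id, start, end, motif,
#' canonical_motif, motif_length, n_repeats, compound.
#'
#' @param loci \code{GRanges} from \code{\link{scanSSRs}}.
#' @param path output (input) file path.
#' @return \code{writeSSRTable} returns \code{path} invisibly;
#'   \code{readSSRTable} returns a \code{GRanges}.
#' @export
writeSSRTable <- function(loci, path) {
  df <- data.frame(
    seq_id = as.character(seqnames(loci)),
    start = start(loci), end = end(loci),
    motif = mcols(loci)$motif,
    canonical_motif = mcols(loci)$canonicalMotif,
    motif_length = mcols(loci)$motifLength,
    n_repeats = mcols(loci)$nRepeats,
    compound = mcols(loci)$compound)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSSRTable
#' @export
readSSRTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gr <- GRanges(df$seq_id, IRanges(df$start, df$end), strand = "+")
  mcols(gr) <- DataFrame(motif = df$motif,
                         canonicalMotif = df$canonical_motif,
                         motifLength = df$motif_length,
                         nRepeats = df$n_repeats,
                         compound = df$compound)
  gr
}

## ---- internal helpers -------------------------------------------------

.pct <- function(count, total) {
  out <- round(100 * count / total, 2)
  out[!is.finite(out)] <- 0
  out
}

.as_sequences <- function(subject) {
  if (is.character(subject) && length(subject) == 1L &&
      !grepl("^[ACGTNacgtn]*$", subject) && file.exists(subject)) {
    subject <- readDNAStringSet(subject)
  }
  if (is(subject, "DNAStringSet") || is(subject, "DNAString")) {
    subject <- as.character(subject)
  }
  if (!is.character(subject)) {
    stop("subject must be a DNAStringSet, character vector or FASTA path")
  }
  subject <- toupper(subject)
  bad <- grepl("[^ACGTN]", subject)
  if (any(bad)) stop("sequences must use the A/C/G/T/N alphabet")
  if (is.null(names(subject))) {
    names(subject) <- paste0("seq", seq_along(subject))
  }
  as.list(subject)
}

.check_min_repeats <- function(minRepeats) {
  minRepeats <- as.integer(minRepeats)
  if (length(minRepeats) != 6L || any(is.na(minRepeats)) ||
      any(minRepeats < 2L)) {
    stop("minRepeats must be 6 integers (motif lengths 1..6), all >= 2")
  }
  minRepeats
}

.loci_frame <- function(loci) {
  if (is(loci, "GRanges")) {
    data.frame(motifLength = mcols(loci)$motifLength,
               canonicalMotif = mcols(loci)$canonicalMotif,
               nRepeats = mcols(loci)$nRepeats)
  } else if (is.data.frame(loci)) {
    stopifnot("motifLength" %in% names(loci))
    loci
  } else {
    stop("loci must be a GRanges or a data.frame")
  }
}
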