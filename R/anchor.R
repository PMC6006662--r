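#' Anchor scaffolds to linkage groups from a SNP genetic map
#'
#' A scaffold's genetic position is the arithmetic mean of the map
#' positions (cM) of its SNPs. Scaffolds whose SNPs all share one linkage
#' group are anchored (\code{single}); scaffolds spanning 2 to
#' \code{maxAmbiguous} linkage groups are \code{ambiguous} (the candidate
#' set is reported but no single group); scaffolds spanning more are
#' \code{unknown}.
#'
#' @param mapRecords data.frame with columns \code{snp_id},
#'   \code{scaffold}, \code{lg} (integer, 1..\code{nLinkageGroups}) and
#'   \code{cM} (>= 0).
#' @param maxAmbiguous most linkage groups a scaffold may span and still be
#'   reported as ambiguous (default 3).
#' @param nLinkageGroups number of linkage groups in the map (default 17).
#' @return data.frame with columns \code{scaffold}, \code{status}
#'   (\code{single}/\code{ambiguous}), \code{lg} (NA unless single),
#'   \code{lgSet} (comma-separated candidate groups), \code{cM} (mean SNP
#'   position, NA unless single) and \code{nSnps}. Scaffolds spanning more
#'   than \code{maxAmbiguous} groups appear with status \code{unknown}.
#' @export
computeScaffoldAnchors <- function(mapRecords, maxAmbiguous = 3L,
                                   nLinkageGroups = 17L) {
  req <- c("snp_id", "scaffold", "lg", "cM")
  stopifnot(is.data.frame(mapRecords), all(req %in% names(mapRecords)))
  lg <- mapRecords$lg
  if (any(is.na(lg)) || any(lg < 1L | lg > nLinkageGroups) ||
      any(lg != as.integer(lg))) {
    stop("lg must be an integer in 1..", nLinkageGroups)
  }
  if (any(is.na(mapRecords$cM)) || any(mapRecords$cM < 0)) {
    stop("cM positions must be >= 0")
  }
  split_ <- split(mapRecords, mapRecords$scaffold)
  out <- lapply(split_, function(d) {
    lgs <- sort(unique(as.integer(d$lg)))
    if (length(lgs) == 1L) {
      data.frame(scaffold = d$scaffold[1L], status = "single",
                 lg = lgs, lgSet = as.character(lgs),
                 cM = mean(d$cM), nSnps = nrow(d))
    } else if (length(lgs) <= maxAmbiguous) {
      data.frame(scaffold = d$scaffold[1L], status = "ambiguous",
                 lg = NA_integer_, lgSet = paste(lgs, collapse = ","),
                 cM = NA_real_, nSnps = nrow(d))
    } else {
      data.frame(scaffold = d$scaffold[1L], status = "unknown",
                 lg = NA_integer_, lgSet = "", cM = NA_real_,
                 nSnps = nrow(d))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read a SNP genetic-map table
#'
#' Tab-separated table with columns snp_id, scaffold, lg, cM.
#'
#' @param path file path.
#' @return data.frame suitable for \code{\link{computeScaffoldAnchors}}.
#' @export
readSnpMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "scaffold", "lg", "cM") %in% names(df)))
  df
}

#' Anchor microsatellite loci through their scaffolds
#'
#' Each locus inherits the anchor of the scaffold (sequence) it lies on;
#' loci on scaffolds absent from the anchor table are \code{unknown}.
#'
#' @param loci \code{GRanges} of SSR loci, or a data.frame with a
#'   \code{seq_id} column.
#' @param anchors data.frame from \code{\link{computeScaffoldAnchors}}.
#' @return data.frame of the loci with added columns \code{anchor_status},
#'   \code{lg}, \code{lgSet} and \code{cM}.
#' @export
anchorLoci <- function(loci, anchors) {
  df <- if (is(loci, "GRanges")) {
    data.frame(seq_id = as.character(seqnames(loci)),
               start = start(loci), end = end(loci),
               motif = mcols(loci)$motif,
               canonical_motif = mcols(loci)$canonicalMotif,
               motif_length = mcols(loci)$motifLength,
               n_repeats = mcols(loci)$nRepeats,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(loci), "seq_id" %in% names(loci))
    loci
  }
  i <- match(df$seq_id, anchors$scaffold)
  df$anchor_status <- ifelse(is.na(i), "unknown", anchors$status[i])
  df$lg <- ifelse(is.na(i), NA_integer_, anchors$lg[i])
  df$lgSet <- ifelse(is.na(i), "", anchors$lgSet[i])
  df$cM <- ifelse(is.na(i), NA_real_, anchors$cM[i])
  df
}

#' Anchoring bookkeeping
#'
#' Counts loci per anchoring status; \code{located} is the number of loci
#' placed on either a single linkage group or a small candidate set
#' (single + ambiguous).
#'
#' @param anchored data.frame from \code{\link{anchorLoci}}, or a named
#'   numeric vector/list with elements \code{single}, \code{ambiguous} and
#'   \code{unknown}.
#' @return data.frame with columns status, count, percent (of total).
#' @export
anchorSummary <- function(anchored) {
  if (is.data.frame(anchored)) {
    s <- anchored$anchor_status
    counts <- c(single = sum(s == "single"),
                ambiguous = sum(s == "ambiguous"),
                unknown = sum(s == "unknown"))
  } else {
    counts <- c(single = as.numeric(anchored[["single"]]),
                ambiguous = as.numeric(anchored[["ambiguous"]]),
                unknown = as.numeric(anchored[["unknown"]]))
  }
  total <- sum(counts)
  counts <- c(counts, located = counts[["single"]] + counts[["ambiguous"]],
              total = total)
  data.frame(status = names(counts), count = as.numeric(counts),
             percent = .pct(counts, total), row.names = NULL)
}

#' Compose a marker name
#'
#' Names follow the convention \code{"Pb"} (species prefix) + motif length
#' + \code{"L"} + linkage-group number (or \code{"U"} when unplaced) +
#' \code{"N"} + zero-padded serial, e.g. \code{Pb3L11N5758},
#' \code{Pb2LUN25693}, \code{Pb4L1N0014}.
#'
#' @param motifLength integer 1..6.
#' @param lg linkage-group number, or NA for unplaced markers.
#' @param serial non-negative serial number.
#' @param pad zero-padding width for the serial; serials wider than
#'   \code{pad} use their natural width.
#' @param prefix species prefix (default \code{"Pb"}).
#' @return character vector of marker names.
#' @export
markerName <- function(motifLength, lg, serial, pad = 4L, prefix = "Pb") {
  stopifnot(all(motifLength %in% 1:6), all(serial >= 0))
  lgPart <- ifelse(is.na(lg), "U", as.character(lg))
  serialPart <- formatC(serial, width = pad, flag = "0", format = "d")
  paste0(prefix, motifLength, "L", lgPart, "N", serialPart)
}

#' Parse a marker name back to its components
#'
#' @param name character vector of names produced by
#'   \code{\link{markerName}}.
#' @param prefix species prefix (default \code{"Pb"}).
#' @return data.frame with columns motif_length, lg (NA for "U") and
#'   serial.
#' @export
parseMarkerName <- function(name, prefix = "Pb") {
  pat <- paste0("^", prefix, "([1-6])L([0-9]+|U)N([0-9]+)$")
  if (any(!grepl(pat, name))) stop("malformed marker name")
  m <- regmatches(name, regexec(pat, name))
  data.frame(
    motif_length = as.integer(vapply(m, `[`, character(1), 2L)),
    lg = suppressWarnings(as.integer(vapply(m, `[`, character(1), 3L))),
    serial = as.integer(vapply(m, `[`, character(1), 4L)))
}

#' Assign names to anchored markers
#'
#' Serials run consecutively within each motif-length series, ordered by
#' linkage group, genetic position, then physical position (sequence id and
#' start), with unplaced markers last. The padding width is each series'
#' natural maximum width (at least \code{pad}).
#'
#' @param markers data.frame from \code{\link{anchorLoci}} (needs columns
#'   motif_length, lg, cM, seq_id, start).
#' @param pad minimum zero-padding width (default 4).
#' @param prefix species prefix (default \code{"Pb"}).
#' @return the input with a \code{name} column added, in the input row
#'   order.
#' @export
assignMarkerNames <- function(markers, pad = 4L, prefix = "Pb") {
  req <- c("motif_length", "lg", "cM", "seq_id", "start")
  stopifnot(is.data.frame(markers), all(req %in% names(markers)))
  markers$name <- NA_character_
  for (k in sort(unique(markers$motif_length))) {
    idx <- which(markers$motif_length == k)
    d <- markers[idx, ]
    ord <- order(is.na(d$lg), d$lg, d$cM, d$seq_id, d$start)
    serial <- integer(length(idx))
    serial[ord] <- seq_along(idx)
    width <- max(pad, nchar(as.character(length(idx))))
    markers$name[idx] <- markerName(k, d$lg, serial, pad = width,
                                    prefix = prefix)
  }
  markers
}
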