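#' Gene models for genomic-context classification
#'
#' Holds gene spans and their exon, CDS and UTR intervals, each as a
#' \code{GRanges} carrying a \code{geneId} metadata column. Validity
#' requires every sub-feature to lie within its gene's span.
#'
#' @slot genes,exons,cds,utr5,utr3 \code{GRanges} with a \code{geneId}
#'   metadata column.
#' @export
setClass("GeneModels", representation(
  genes = "GRanges", exons = "GRanges", cds = "GRanges",
  utr5 = "GRanges", utr3 = "GRanges"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  if (!length(g)) return(TRUE)
  if (is.null(mcols(g)$geneId)) return("genes must carry a geneId column")
  for (slotName in c("exons", "cds", "utr5", "utr3")) {
    f <- slot(object, slotName)
    if (!length(f)) next
    if (is.null(mcols(f)$geneId)) {
      return(sprintf("%s must carry a geneId column", slotName))
    }
    i <- match(mcols(f)$geneId, mcols(g)$geneId)
    if (anyNA(i)) return(sprintf("%s refers to unknown gene ids", slotName))
    ok <- as.character(seqnames(f)) == as.character(seqnames(g))[i] &
      start(f) >= start(g)[i] & end(f) <= end(g)[i]
    if (!all(ok)) {
      return(sprintf("%s intervals fall outside their gene span", slotName))
    }
  }
  TRUE
})

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels:", length(object@genes), "genes,",
      length(object@exons), "exons,", length(object@cds), "CDS,",
      length(object@utr5) + length(object@utr3), "UTR intervals\n")
})

#' Construct gene models from component ranges
#'
#' @param genes \code{GRanges} of gene spans with \code{geneId} metadata
#'   column (strand must be + or -).
#' @param exons,cds,utr5,utr3 \code{GRanges} of sub-features, each with a
#'   \code{geneId} column; may be empty.
#' @return a \code{GeneModels} object.
#' @export
GeneModels <- function(genes, exons = GRanges(), cds = GRanges(),
                       utr5 = GRanges(), utr3 = GRanges()) {
  fix <- function(gr, id = NULL) {
    if (!length(gr)) {
      gr <- GRanges()
      mcols(gr) <- DataFrame(geneId = character(0))
    }
    gr
  }
  new("GeneModels", genes = genes, exons = fix(exons), cds = fix(cds),
      utr5 = fix(utr5), utr3 = fix(utr3))
}

#' Read gene models from a GFF3 file
#'
#' Imports gene, mRNA, exon, CDS, five_prime_UTR and three_prime_UTR
#' features and resolves Parent chains (feature -> mRNA -> gene) to a flat
#' per-gene model.
#'
#' @param path GFF3 file path.
#' @return a \code{GeneModels} object.
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  ids <- as.character(gff$ID)
  parents <- vapply(as.list(gff$Parent), function(p) {
    if (length(p)) as.character(p)[1L] else NA_character_
  }, character(1))
  genes <- gff[type == "gene"]
  geneIds <- as.character(genes$ID)
  ## map any feature id to its owning gene id (at most two hops)
  toGene <- function(i) {
    p <- parents[i]
    for (hop in 1:3) {
      if (is.na(p)) return(NA_character_)
      if (p %in% geneIds) return(p)
      j <- match(p, ids)
      if (is.na(j)) return(NA_character_)
      p <- parents[j]
    }
    NA_character_
  }
  pick <- function(what) {
    sel <- which(type == what)
    gr <- gff[sel]
    gid <- vapply(sel, toGene, character(1))
    keep <- !is.na(gid)
    gr <- gr[keep]
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                   strand = strand(gr))
    mcols(out) <- DataFrame(geneId = gid[keep])
    out
  }
  g <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)),
               strand = strand(genes))
  mcols(g) <- DataFrame(geneId = geneIds)
  GeneModels(g, exons = pick("exon"), cds = pick("CDS"),
             utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"))
}

.CONTEXT_LEVELS <- c("exon", "five_prime_utr", "three_prime_utr", "intron",
                     "upstream_1kb", "downstream_1kb", "between_genes_1kb",
                     "intergenic")

#' Classify microsatellite loci by genomic context
#'
#' Assigns each locus exactly one context label relative to gene models,
#' by the priority coding exon > 5' UTR > 3' UTR > intron > flanking
#' categories > intergenic. A locus overlapping a feature by at least one
#' base belongs to it. Flank classification is strand-aware: upstream is
#' the \code{flank} bases 5' of the transcription start, downstream the
#' \code{flank} bases 3' of the transcription end; a locus upstream of one
#' gene and downstream of another is \code{between_genes_1kb}.
#'
#' @param loci \code{GRanges} of SSR loci.
#' @param models a \code{GeneModels} object.
#' @param flank flank width in bases (default 1000).
#' @return the loci with added metadata columns \code{context} (factor) and
#'   \code{geneIds} (comma-separated, empty iff intergenic).
#' @export
classifyContext <- function(loci, models, flank = 1000L) {
  stopifnot(is(loci, "GRanges"), is(models, "GeneModels"))
  validObject(models)
  n <- length(loci)
  context <- rep(NA_character_, n)
  geneIds <- rep("", n)
  assign_overlap <- function(feature, label) {
    if (!length(feature)) return()
    hits <- findOverlaps(loci, feature, ignore.strand = TRUE)
    q <- queryHits(hits)
    ids <- mcols(feature)$geneId[subjectHits(hits)]
    for (i in unique(q)) {
      if (!is.na(context[i])) next
      context[i] <<- label
      geneIds[i] <<- .join_ids(ids[q == i])
    }
  }
  ## coding exons first; exons of genes without any CDS annotation count too
  cds <- models@cds
  noCdsGenes <- setdiff(mcols(models@genes)$geneId, mcols(cds)$geneId)
  exonNoCds <- models@exons[mcols(models@exons)$geneId %in% noCdsGenes]
  assign_overlap(c(cds, exonNoCds), "exon")
  assign_overlap(models@utr5, "five_prime_utr")
  assign_overlap(models@utr3, "three_prime_utr")
  assign_overlap(models@genes, "intron")

  ## strand-aware flanks of the remaining loci
  g <- models@genes
  if (length(g)) {
    plus <- as.character(strand(g)) != "-"
    upWindow <- GRanges(seqnames(g), IRanges(
      ifelse(plus, pmax(1L, start(g) - flank), end(g) + 1L),
      ifelse(plus, start(g) - 1L, end(g) + flank)))
    mcols(upWindow) <- DataFrame(geneId = mcols(g)$geneId)
    downWindow <- GRanges(seqnames(g), IRanges(
      ifelse(plus, end(g) + 1L, pmax(1L, start(g) - flank)),
      ifelse(plus, end(g) + flank, start(g) - 1L)))
    mcols(downWindow) <- DataFrame(geneId = mcols(g)$geneId)
    upWindow <- upWindow[width(upWindow) > 0L & start(upWindow) <= end(upWindow)]
    downWindow <- downWindow[width(downWindow) > 0L]
    upHits <- findOverlaps(loci, upWindow, ignore.strand = TRUE)
    downHits <- findOverlaps(loci, downWindow, ignore.strand = TRUE)
    for (i in which(is.na(context))) {
      upIds <- mcols(upWindow)$geneId[subjectHits(upHits)[queryHits(upHits) == i]]
      downIds <- mcols(downWindow)$geneId[subjectHits(downHits)[queryHits(downHits) == i]]
      if (length(upIds) && length(downIds)) {
        context[i] <- "between_genes_1kb"
        geneIds[i] <- .join_ids(c(upIds, downIds))
      } else if (length(upIds)) {
        context[i] <- "upstream_1kb"
        geneIds[i] <- .join_ids(upIds)
      } else if (length(downIds)) {
        context[i] <- "downstream_1kb"
        geneIds[i] <- .join_ids(downIds)
      }
    }
  }
  context[is.na(context)] <- "intergenic"
  mcols(loci)$context <- factor(context, levels = .CONTEXT_LEVELS)
  mcols(loci)$geneIds <- geneIds
  loci
}

#' Summarize genomic-context categories
#'
#' @param annotated \code{GRanges} returned by \code{\link{classifyContext}},
#'   or a factor/character vector of context labels.
#' @return data.frame with context, count and percent (of total, 2 dp).
#' @export
summarizeContexts <- function(annotated) {
  ctx <- if (is(annotated, "GRanges")) mcols(annotated)$context else annotated
  ctx <- factor(as.character(ctx), levels = .CONTEXT_LEVELS)
  counts <- as.integer(table(ctx))
  data.frame(context = .CONTEXT_LEVELS, count = counts,
             percent = .pct(counts, length(ctx)))
}

.join_ids <- function(ids) paste(sort(unique(ids)), collapse = ",")
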