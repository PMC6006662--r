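#' Codominant diploid microsatellite genotypes
#'
#' A \code{SummarizedExperiment} subclass holding diploid codominant calls
#' as two integer assays, \code{allele1} and \code{allele2} (loci in rows,
#' individuals in columns; values are fragment sizes in bases). A cell is
#' either fully called (both alleles positive) or missing (both NA): there
#' are no half-calls. The allele pair is unordered; constructors store it
#' with \code{allele1 <= allele2}.
#'
#' @export
setClass("SSRGenotypes", contains = "SummarizedExperiment")

setValidity("SSRGenotypes", function(object) {
  if (!all(c("allele1", "allele2") %in% assayNames(object))) {
    return("assays 'allele1' and 'allele2' are required")
  }
  a1 <- assay(object, "allele1")
  a2 <- assay(object, "allele2")
  if (!identical(dim(a1), dim(a2))) return("assay dimensions differ")
  if (!identical(is.na(a1), is.na(a2))) {
    return("half-called cells: allele1 and allele2 must be missing together")
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE)) {
    return("allele sizes must be positive")
  }
  TRUE
})

#' Construct an SSRGenotypes object
#'
#' @param allele1,allele2 integer matrices (loci x individuals) of allele
#'   fragment sizes; NA marks a missing call (in both). The pair is
#'   unordered and is stored sorted within each cell.
#' @return an \code{SSRGenotypes} object.
#' @export
SSRGenotypes <- function(allele1, allele2) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  if (!identical(is.na(allele1), is.na(allele2))) {
    stop("half-called cells: allele1 and allele2 must be missing together")
  }
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  dimnames(lo) <- dimnames(hi) <- dimnames(allele1)
  if (is.null(rownames(lo))) {
    rownames(lo) <- rownames(hi) <- sprintf("locus%02d", seq_len(nrow(lo)))
  }
  if (is.null(colnames(lo))) {
    colnames(lo) <- colnames(hi) <- sprintf("ind%02d", seq_len(ncol(lo)))
  }
  new("SSRGenotypes",
      SummarizedExperiment(assays = list(allele1 = lo, allele2 = hi)))
}

setMethod("show", "SSRGenotypes", function(object) {
  a1 <- assay(object, "allele1")
  miss <- mean(is.na(a1))
  cat("SSRGenotypes:", nrow(object), "loci x", ncol(object),
      sprintf("individuals (%.1f%% missing)\n", 100 * miss))
})

#' Read / write genotype tables
#'
#' CSV layout: one row per individual (first column \code{id}), then two
#' columns per locus named \code{<locus>_1} and \code{<locus>_2}; 0, empty
#' or NA marks a missing call.
#'
#' @param path file path.
#' @param x an \code{SSRGenotypes} object.
#' @return \code{readGenotypes} returns an \code{SSRGenotypes};
#'   \code{writeGenotypes} returns \code{path} invisibly.
#' @export
readGenotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  cols <- names(df)
  loci <- unique(sub("_[12]$", "", cols))
  a1 <- sapply(loci, function(l) as.numeric(df[[paste0(l, "_1")]]))
  a2 <- sapply(loci, function(l) as.numeric(df[[paste0(l, "_2")]]))
  a1 <- t(as.matrix(a1)); a2 <- t(as.matrix(a2))
  a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
  ## missing is all-or-nothing per cell
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA
  rownames(a1) <- rownames(a2) <- loci
  colnames(a1) <- colnames(a2) <- ids
  SSRGenotypes(a1, a2)
}

#' @rdname readGenotypes
#' @export
writeGenotypes <- function(x, path) {
  a1 <- assay(x, "allele1"); a2 <- assay(x, "allele2")
  out <- data.frame(id = colnames(a1), check.names = FALSE)
  for (l in rownames(a1)) {
    out[[paste0(l, "_1")]] <- ifelse(is.na(a1[l, ]), 0L, a1[l, ])
    out[[paste0(l, "_2")]] <- ifelse(is.na(a2[l, ]), 0L, a2[l, ])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
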