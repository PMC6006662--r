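#' Per-locus diversity statistics for codominant markers
#'
#' For each locus, allele frequencies are computed from the non-missing
#' calls (two gene copies per individual) and the following statistics are
#' reported: number of alleles (Na), number of distinct genotypes (Ng),
#' major allele frequency, observed heterozygosity (Ho, fraction of
#' non-missing individuals that are heterozygous), expected heterozygosity
#' (He, Nei's gene diversity \eqn{1 - \sum p_i^2}, optionally with the
#' small-sample correction \eqn{2n/(2n-1)}), and the polymorphism
#' information content for codominant markers,
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2.}
#'
#' @param x an \code{SSRGenotypes} object.
#' @param unbiased apply the \eqn{2n/(2n-1)} correction to He
#'   (default FALSE).
#' @return a data.frame with one row per locus: locus, n (individuals
#'   scored), na, ng, major_freq, ho, he, pic.
#' @export
locusStats <- function(x, unbiased = FALSE) {
  stopifnot(is(x, "SSRGenotypes"))
  a1 <- assay(x, "allele1"); a2 <- assay(x, "allele2")
  out <- lapply(seq_len(nrow(a1)), function(l) {
    ok <- !is.na(a1[l, ])
    if (!any(ok)) stop("locus '", rownames(a1)[l], "' has no data")
    x1 <- a1[l, ok]; x2 <- a2[l, ok]
    p <- table(c(x1, x2)) / (2 * sum(ok))
    p <- as.numeric(p)
    he <- 1 - sum(p^2)
    if (unbiased) he <- he * 2 * sum(ok) / (2 * sum(ok) - 1)
    pic <- 1 - sum(p^2) - (sum(p^2)^2 - sum(p^4))
    data.frame(
      locus = rownames(a1)[l], n = sum(ok),
      na = length(p),
      ng = length(unique(paste(x1, x2))),
      major_freq = max(p),
      ho = mean(x1 != x2),
      he = he, pic = pic)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Band-based similarity between individuals
#'
#' Genotypes are expanded into binary allele-presence bands per locus
#' (a heterozygote shows two bands, a homozygote one) and individuals are
#' compared by the Dice coefficient \eqn{2a/(2a + b + c)} over shared (a)
#' and private (b, c) bands, or by simple matching
#' \eqn{(a + d)/(a + b + c + d)} against the universe of bands observed at
#' the jointly scored loci. Loci missing in either individual of a pair
#' are excluded pairwise.
#'
#' @param x an \code{SSRGenotypes} object with at least 2 individuals.
#' @param method \code{"dice"} (default) or \code{"simple"}.
#' @return symmetric numeric matrix with unit diagonal, one row/column per
#'   individual.
#' @export
similarityMatrix <- function(x, method = c("dice", "simple")) {
  stopifnot(is(x, "SSRGenotypes"))
  method <- match.arg(method)
  a1 <- assay(x, "allele1"); a2 <- assay(x, "allele2")
  n <- ncol(a1)
  if (n < 2L) stop("at least 2 individuals are required")
  shared <- matrix(0, n, n)      # a, accumulated over loci
  bandSum <- matrix(0, n, n)     # b_i + b_j (2a + b + c)
  universe <- matrix(0, n, n)    # a + b + c + d for simple matching
  jointly <- matrix(0L, n, n)
  for (l in seq_len(nrow(a1))) {
    present <- !is.na(a1[l, ])
    alleles <- sort(unique(c(a1[l, present], a2[l, present])))
    if (!length(alleles)) next
    B <- matrix(0L, n, length(alleles))
    B[cbind(seq_len(n)[present], match(a1[l, present], alleles))] <- 1L
    B[cbind(seq_len(n)[present], match(a2[l, present], alleles))] <- 1L
    bothPresent <- outer(present, present, "&")
    shared <- shared + (B %*% t(B)) * bothPresent
    nb <- rowSums(B)
    bandSum <- bandSum + outer(nb, nb, "+") * bothPresent
    universe <- universe + length(alleles) * bothPresent
    jointly <- jointly + bothPresent
  }
  if (any(jointly[upper.tri(jointly)] == 0L)) {
    stop("some pair of individuals shares no jointly scored locus")
  }
  sim <- if (method == "dice") {
    2 * shared / bandSum
  } else {
    ## matches = shared presences + shared absences within the universe
    (shared + (universe - bandSum + shared)) / universe
  }
  diag(sim) <- 1
  dimnames(sim) <- list(colnames(a1), colnames(a1))
  sim
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Agglomerates with unweighted pair-group averaging (new-cluster distances
#' are means weighted by cluster sizes) on the distance matrix
#' \eqn{d = 1 - s}. Tie-breaking is deterministic: among equally close
#' pairs the one with the smallest pair of cluster indices (in order of
#' cluster formation) is merged first. The result is ultrametric: all
#' leaves are equidistant from the root, and the cophenetic distance of
#' two leaves equals the distance at which their clusters merged.
#'
#' @param sim symmetric similarity matrix in [0, 1] with unit diagonal
#'   (e.g. from \code{\link{similarityMatrix}}), or a \code{dist} object of
#'   distances.
#' @return an \code{ape} \code{phylo} tree (rooted, binary, with branch
#'   lengths; leaf-to-root depth equals half the root merge distance).
#' @export
upgmaTree <- function(sim) {
  if (inherits(sim, "dist")) {
    d <- as.matrix(sim)
  } else {
    stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
    if (max(abs(sim - t(sim))) > 1e-8) stop("similarity matrix not symmetric")
    d <- 1 - sim
    diag(d) <- 0
  }
  n <- nrow(d)
  if (n < 2L) stop("at least 2 leaves are required")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  active <- seq_len(n)             # column indices into d of live clusters
  id <- -seq_len(n)                # hclust code: -leaf or +merge row
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    dm <- d[active, active, drop = FALSE]
    dm[lower.tri(dm, diag = TRUE)] <- Inf
    best <- which(dm == min(dm), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    height[step] <- dm[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))
    ai <- active[i]; aj <- active[j]
    newd <- (d[ai, active] * size[i] + d[aj, active] * size[j]) /
      (size[i] + size[j])
    d[ai, active] <- newd
    d[active, ai] <- newd
    d[ai, ai] <- 0
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- active[-j]
    id <- id[-j]
    size <- size[-j]
  }
  hc <- list(merge = merge, height = height,
             order = .hclust_order(merge), labels = labels,
             method = "average", call = match.call(),
             dist.method = "one-minus-similarity")
  class(hc) <- "hclust"
  ape::as.phylo(hc)
}

## leaf ordering compatible with the merge matrix (left-to-right traversal)
.hclust_order <- function(merge) {
  walk <- function(row) {
    unlist(lapply(merge[row, ], function(v) {
      if (v < 0) -v else walk(v)
    }))
  }
  walk(nrow(merge))
}
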