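#' Canonical form of a microsatellite motif
#'
#' Maps each repeat motif to the representative of its equivalence class
#' under cyclic rotation and reverse complement: the lexicographically
#' smallest string among all rotations of the motif and of its reverse
#' complement. All motifs that describe the same tandem repeat read in
#' either orientation (e.g. \code{AG}, \code{GA}, \code{CT}, \code{TC})
#' share one canonical form (\code{AG}).
#'
#' @param motif character vector of motifs, length 1--6, alphabet ACGT,
#'   primitive (not itself a tandem power of a shorter unit).
#' @return character vector of canonical motifs, same length as input.
#' @examples
#' canonicalizeMotif(c("CT", "T", "GAA"))  # "AG" "A" "AAG"
#' @export
canonicalizeMotif <- function(motif) {
  if (length(motif) == 0L) return(character(0))
  motif <- toupper(as.character(motif))
  bad <- !grepl("^[ACGT]{1,6}$", motif)
  if (any(bad)) {
    stop("invalid motif (must be 1-6 bases over ACGT): ",
         paste(unique(motif[bad]), collapse = ", "))
  }
  prim <- vapply(motif, isPrimitiveMotif, logical(1))
  if (any(!prim)) {
    stop("non-primitive motif (tandem power of a shorter unit): ",
         paste(unique(motif[!prim]), collapse = ", "))
  }
  vapply(motif, function(m) {
    k <- nchar(m)
    rots <- vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1, i - 1L))
    }, character(1))
    rc <- revcompChar(m)
    rcrots <- vapply(seq_len(k), function(i) {
      paste0(substr(rc, i, k), substr(rc, 1, i - 1L))
    }, character(1))
    min(c(rots, rcrots))
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate canonical motif classes of a given length
#'
#' Lists the distinct canonical motifs among all primitive motifs of length
#' \code{k}. For example there are 2 mononucleotide classes (A, C) and 4
#' dinucleotide classes (AC, AG, AT, CG).
#'
#' @param k motif length, 1--6.
#' @return sorted character vector of canonical motifs.
#' @export
motifClasses <- function(k) {
  stopifnot(length(k) == 1L, k >= 1, k <= 6)
  bases <- c("A", "C", "G", "T")
  all <- do.call(paste0, expand.grid(rep(list(bases), k),
                                     stringsAsFactors = FALSE))
  prim <- all[vapply(all, isPrimitiveMotif, logical(1))]
  sort(unique(canonicalizeMotif(prim)))
}

## reverse complement of a plain character motif (no Biostrings round trip
## for tiny strings in hot paths)
revcompChar <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## TRUE iff the motif is not a tandem power of a shorter unit
isPrimitiveMotif <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(TRUE)
  ch <- strsplit(m, "")[[1L]]
  for (p in seq_len(k - 1L)) {
    if (k %% p != 0L) next
    if (all(ch == ch[((seq_len(k) - 1L) %% p) + 1L])) return(FALSE)
  }
  TRUE
}
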