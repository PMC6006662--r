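# A toy locus landscape on one 20 kb scaffold:
# geneA (+): 5001-8000, exons 5001-5600 / 7401-8000, CDS 5201-5600 and
#   7401-7800, 5'UTR 5001-5200, 3'UTR 7801-8000
# geneB (-): 12001-14000, exon = CDS = full span
make_toy_models <- function() {
  g <- GRanges("sc1", IRanges(c(5001, 12001), c(8000, 14000)),
               strand = c("+", "-"))
  mcols(g) <- S4Vectors::DataFrame(geneId = c("geneA", "geneB"))
  ex <- GRanges("sc1", IRanges(c(5001, 7401, 12001),
                               c(5600, 8000, 14000)),
                strand = c("+", "+", "-"))
  mcols(ex) <- S4Vectors::DataFrame(geneId = c("geneA", "geneA", "geneB"))
  cds <- GRanges("sc1", IRanges(c(5201, 7401, 12001),
                                c(5600, 7800, 14000)),
                 strand = c("+", "+", "-"))
  mcols(cds) <- S4Vectors::DataFrame(geneId = c("geneA", "geneA", "geneB"))
  u5 <- GRanges("sc1", IRanges(5001, 5200), strand = "+")
  mcols(u5) <- S4Vectors::DataFrame(geneId = "geneA")
  u3 <- GRanges("sc1", IRanges(7801, 8000), strand = "+")
  mcols(u3) <- S4Vectors::DataFrame(geneId = "geneA")
  GeneModels(g, exons = ex, cds = cds, utr5 = u5, utr3 = u3)
}

locus_at <- function(start, end) {
  gr <- GRanges("sc1", IRanges(start, end), strand = "+")
  mcols(gr) <- S4Vectors::DataFrame(
    motif = "AG", canonicalMotif = "AG", motifLength = 2L,
    nRepeats = as.integer((end - start + 1) / 2), compound = FALSE)
  gr
}

test_that("context labels follow the feature priority", {
  models <- make_toy_models()
  lab <- function(s, e) {
    as.character(mcols(classifyContext(locus_at(s, e), models))$context)
  }
  expect_identical(lab(5301, 5320), "exon")            # CDS overlap
  expect_identical(lab(5101, 5120), "five_prime_utr")
  expect_identical(lab(7851, 7870), "three_prime_utr")
  expect_identical(lab(6001, 6020), "intron")          # between the exons
  expect_identical(lab(4501, 4520), "upstream_1kb")    # 500 bp 5' of geneA
  expect_identical(lab(8501, 8520), "downstream_1kb")  # 3' of geneA TTS
  expect_identical(lab(14501, 14520), "upstream_1kb")  # 5' of -strand geneB
  expect_identical(lab(11501, 11520), "downstream_1kb")
  expect_identical(lab(18001, 18020), "intergenic")
  # a feature overlap of a single base is enough
  expect_identical(lab(5600, 5650), "exon")
})

test_that("gene ids accompany every non-intergenic label", {
  models <- make_toy_models()
  ann <- classifyContext(locus_at(4501, 4520), models)
  expect_identical(mcols(ann)$geneIds, "geneA")
  far <- classifyContext(locus_at(18001, 18020), models)
  expect_identical(mcols(far)$geneIds, "")
})

test_that("a locus between two genes within both flanks is between_genes", {
  # two + genes 1500 bp apart; midpoint is downstream of A, upstream of B
  g <- GRanges("sc1", IRanges(c(1001, 4501), c(3000, 6000)),
               strand = c("+", "+"))
  mcols(g) <- S4Vectors::DataFrame(geneId = c("gA", "gB"))
  models <- GeneModels(g)
  ann <- classifyContext(locus_at(3701, 3720), models)
  expect_identical(as.character(mcols(ann)$context), "between_genes_1kb")
  expect_identical(mcols(ann)$geneIds, "gA,gB")
})

test_that("reverse-complementing the landscape swaps upstream/downstream", {
  L <- 20000L
  g <- GRanges("sc1", IRanges(5001, 8000), strand = "+")
  mcols(g) <- S4Vectors::DataFrame(geneId = "geneA")
  fwd <- GeneModels(g)
  # mirrored coordinates, flipped strand
  gm <- GRanges("sc1", IRanges(L - 8000 + 1, L - 5001 + 1), strand = "-")
  mcols(gm) <- S4Vectors::DataFrame(geneId = "geneA")
  rev <- GeneModels(gm)
  for (win in list(c(4501, 4520), c(8501, 8520))) {
    labF <- as.character(mcols(classifyContext(
      locus_at(win[1], win[2]), fwd))$context)
    labR <- as.character(mcols(classifyContext(
      locus_at(L - win[2] + 1, L - win[1] + 1), rev))$context)
    expect_identical(labF, labR)
  }
})

test_that("every locus gets exactly one label and counts are conserved", {
  models <- make_toy_models()
  set.seed(7)
  starts <- sample(1:19900, 200)
  loci <- do.call(c, lapply(starts, function(s) locus_at(s, s + 19)))
  ann <- classifyContext(loci, models)
  expect_false(anyNA(mcols(ann)$context))
  sm <- summarizeContexts(ann)
  expect_equal(sum(sm$count), length(loci))
  # gene ids empty iff intergenic
  inter <- as.character(mcols(ann)$context) == "intergenic"
  expect_identical(mcols(ann)$geneIds == "", inter)
})

test_that("malformed gene models are rejected", {
  g <- GRanges("sc1", IRanges(1001, 2000), strand = "+")
  mcols(g) <- S4Vectors::DataFrame(geneId = "gA")
  cds <- GRanges("sc1", IRanges(1500, 2500), strand = "+")  # exceeds span
  mcols(cds) <- S4Vectors::DataFrame(geneId = "gA")
  expect_error(GeneModels(g, cds = cds), "outside")
})

test_that("gene models load from GFF3 with Parent resolution", {
  rows <- rbind(
    toy_gene_row("sc1", "gene", 5001, 8000, "+", "geneA"),
    toy_gene_row("sc1", "mRNA", 5001, 8000, "+", "geneA.t1", "geneA"),
    toy_gene_row("sc1", "exon", 5001, 5600, "+", "geneA.e1", "geneA.t1"),
    toy_gene_row("sc1", "exon", 7401, 8000, "+", "geneA.e2", "geneA.t1"),
    toy_gene_row("sc1", "CDS", 5201, 5600, "+", "geneA.c1", "geneA.t1"),
    toy_gene_row("sc1", "CDS", 7401, 7800, "+", "geneA.c2", "geneA.t1"),
    toy_gene_row("sc1", "five_prime_UTR", 5001, 5200, "+", "geneA.u5",
                 "geneA.t1"),
    toy_gene_row("sc1", "three_prime_UTR", 7801, 8000, "+", "geneA.u3",
                 "geneA.t1"))
  path <- tempfile(fileext = ".gff3")
  write_toy_gff(path, rows)
  models <- readGeneModels(path)
  expect_length(models@genes, 1L)
  expect_length(models@cds, 2L)
  expect_identical(unique(mcols(models@exons)$geneId), "geneA")
  lab <- as.character(mcols(classifyContext(
    locus_at(6001, 6020), models))$context)
  expect_identical(lab, "intron")
})
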