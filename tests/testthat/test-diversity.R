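geno_from_calls <- function(calls) {
  # calls: list of length-2 vectors (or NA) for one locus
  a1 <- matrix(vapply(calls, function(x) x[1], numeric(1)), nrow = 1)
  a2 <- matrix(vapply(calls, function(x) x[2], numeric(1)), nrow = 1)
  SSRGenotypes(a1, a2)
}

test_that("locus statistics match hand-worked values", {
  g <- geno_from_calls(list(c(100, 100), c(100, 120), c(120, 120),
                            c(100, 120)))
  st <- locusStats(g)
  expect_equal(st$na, 2L)
  expect_equal(st$ng, 3L)
  expect_equal(st$major_freq, 0.5)
  expect_equal(st$ho, 0.5)
  expect_equal(st$he, 0.5)
  expect_equal(st$pic, 0.375)
  mono <- locusStats(geno_from_calls(list(c(100, 100), c(100, 100))))
  expect_equal(unlist(mono[, c("na", "ng", "ho", "he", "pic")]),
               c(na = 1, ng = 1, ho = 0, he = 0, pic = 0))
})

test_that("equifrequent alleles reach the closed-form He and PIC", {
  # 4 alleles, each at frequency 1/4 (8 copies from 4 individuals)
  g <- geno_from_calls(list(c(100, 102), c(104, 106), c(100, 102),
                            c(104, 106)))
  st <- locusStats(g)
  expect_equal(st$he, 0.75)
  expect_equal(st$pic, 0.703125)
  # general closed form: he = 1 - 1/k, pic = he - (k-1)/k^3 * ... via oracle
  for (k in 2:6) {
    p <- rep(1 / k, k)
    he <- 1 - sum(p^2)
    pic <- he - (sum(p^2)^2 - sum(p^4))
    expect_equal(pic, 1 - 1 / k - (k - 1) / k^3, tolerance = 1e-12)
  }
})

test_that("statistics equal brute-force enumeration on small matrices", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    nl <- sample(2:4, 1)
    a1 <- matrix(sample(c(100, 102, 104, 106), n * nl, replace = TRUE),
                 nl, n)
    a2 <- matrix(sample(c(100, 102, 104, 106), n * nl, replace = TRUE),
                 nl, n)
    # sprinkle missing cells, keeping every locus scored at least once
    miss <- matrix(runif(nl * n) < 0.15, nl, n)
    miss[, 1] <- FALSE
    a1[miss] <- NA; a2[miss] <- NA
    g <- SSRGenotypes(a1, a2)
    st <- locusStats(g)
    for (l in seq_len(nl)) {
      o <- oracle_locus_stats(assay(g, "allele1")[l, ],
                              assay(g, "allele2")[l, ])
      expect_equal(st$na[l], o$na)
      expect_equal(st$ng[l], o$ng)
      expect_equal(st$major_freq[l], o$major_freq)
      expect_equal(st$ho[l], o$ho)
      expect_equal(st$he[l], o$he)
      expect_equal(st$pic[l], o$pic)
    }
    # invariant chain: pic <= he <= 1 - 1/na
    expect_true(all(st$pic <= st$he + 1e-12))
    expect_true(all(st$he <= 1 - 1 / st$na + 1e-12))
    expect_true(all(st$ng <= st$na * (st$na + 1) / 2))
  }
})

test_that("Dice similarity matches explicit band counting", {
  # columns are individuals, rows loci (two loci, four individuals)
  a1 <- matrix(c(100, 200,  100, 202,  102, 200,  104, 204), 2, 4)
  a2 <- matrix(c(100, 202,  102, 204,  102, 206,  104, 204), 2, 4)
  g <- SSRGenotypes(a1, a2)
  sim <- similarityMatrix(g)
  expect_true(isSymmetric(sim))
  expect_true(all(diag(sim) == 1))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      gi <- lapply(1:2, function(l) c(a1[l, i], a2[l, i]))
      gj <- lapply(1:2, function(l) c(a1[l, j], a2[l, j]))
      expect_equal(sim[i, j], oracle_dice_pair(gi, gj))
    }
  }
  # identical rows and fully disjoint rows hit the bounds
  twin <- SSRGenotypes(a1[, c(1, 1)], a2[, c(1, 1)])
  expect_equal(similarityMatrix(twin)[1, 2], 1)
  disj <- SSRGenotypes(matrix(c(100, 200, 110, 210), 2, 2),
                       matrix(c(102, 202, 112, 212), 2, 2))
  expect_equal(similarityMatrix(disj)[1, 2], 0)
})

test_that("missing loci are excluded pairwise and empty overlap errors", {
  a1 <- matrix(c(100, NA, 100, 200, NA, 204), 3, 2)
  a2 <- matrix(c(102, NA, 100, 200, NA, 204), 3, 2)
  g <- SSRGenotypes(a1, a2)
  sim <- similarityMatrix(g)
  # only locus 1 and 3 jointly scored... locus2 missing in ind1, locus...
  expect_true(sim[1, 2] >= 0 && sim[1, 2] <= 1)
  allmiss <- SSRGenotypes(matrix(c(100, NA, NA, 102), 2, 2),
                          matrix(c(100, NA, NA, 104), 2, 2))
  expect_error(similarityMatrix(allmiss), "jointly")
})

test_that("UPGMA reproduces the hand agglomeration and two-taxon height", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- upgmaTree(as.dist(d))
  co <- ape::cophenetic.phylo(phy)
  expect_equal(co["A", "B"], 2)
  expect_equal(co["A", "C"], 4)
  expect_equal(co["B", "C"], 4)
  # branch lengths: ((A:1,B:1):1,C:2)
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(unname(depths[1:3]), c(2, 2, 2))  # ultrametric leaves
  two <- upgmaTree(as.dist(matrix(c(0, 3, 3, 0), 2, 2,
                                  dimnames = list(c("A", "B"),
                                                  c("A", "B")))))
  expect_equal(unname(ape::node.depth.edgelength(two)[1:2]), c(1.5, 1.5))
})

test_that("UPGMA agrees with hclust average linkage on random matrices", {
  set.seed(88)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("t", seq_len(n))
    d <- dist(x)
    phy <- upgmaTree(d)
    hc <- hclust(d, method = "average")
    expect_equal(as.matrix(ape::cophenetic.phylo(phy)),
                 as.matrix(cophenetic(hc))[phy$tip.label, phy$tip.label],
                 tolerance = 1e-10)
  }
})

test_that("ultrametric input is reproduced exactly by the cophenetic matrix", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    x <- matrix(rnorm(n * 2), n)
    rownames(x) <- paste0("t", seq_len(n))
    um <- cophenetic(hclust(dist(x), method = "average"))  # ultrametric
    phy <- upgmaTree(as.dist(as.matrix(um)))
    expect_equal(as.matrix(ape::cophenetic.phylo(phy))[labels(um), labels(um)],
                 as.matrix(um), tolerance = 1e-10)
    # three-point condition on the output
    co <- as.matrix(ape::cophenetic.phylo(phy))
    trip <- combn(rownames(co), 3)
    for (t3 in seq_len(min(20, ncol(trip)))) {
      dd <- sort(c(co[trip[1, t3], trip[2, t3]],
                   co[trip[1, t3], trip[3, t3]],
                   co[trip[2, t3], trip[3, t3]]))
      expect_lte(dd[3], dd[2] + 1e-9)
    }
  }
})

test_that("permuting labels yields an isomorphic tree", {
  set.seed(12)
  sim <- simulateGenotypes(nIndividuals = 12, nLoci = 8, seed = 30)
  sm <- similarityMatrix(sim$genotypes)
  phy1 <- upgmaTree(sm)
  perm <- sample(nrow(sm))
  phy2 <- upgmaTree(sm[perm, perm])
  expect_equal(as.matrix(ape::cophenetic.phylo(phy1))[phy1$tip.label,
                                                      phy1$tip.label],
               as.matrix(ape::cophenetic.phylo(phy2))[phy1$tip.label,
                                                      phy1$tip.label],
               tolerance = 1e-10)
})

test_that("genotype tables round-trip through CSV and enforce validity", {
  sim <- simulateGenotypes(nIndividuals = 10, nLoci = 4, seed = 77)
  path <- tempfile(fileext = ".csv")
  writeGenotypes(sim$genotypes, path)
  back <- readGenotypes(path)
  expect_equal(assay(back, "allele1"), assay(sim$genotypes, "allele1"))
  expect_equal(assay(back, "allele2"), assay(sim$genotypes, "allele2"))
  expect_error(SSRGenotypes(matrix(c(100, NA), 1), matrix(c(100, 104), 1)),
               "missing together")
  expect_error(SSRGenotypes(matrix(-1, 1, 1), matrix(100, 1, 1)),
               "positive")
})
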