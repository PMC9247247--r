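test_that("Poisson correction matches closed forms and a naive recount", {
  d0 <- aa_distance_poisson(c(a = "MKTAYIAK", b = "MKTAYIAK"))
  expect_equal(d0$d[1, 2], 0)
  # p = 0.5 -> ln 2
  d5 <- aa_distance_poisson(c(a = "AAAAAAAAAA", b = "AAAAARRRRR"))
  expect_equal(d5$d[1, 2], log(2), tolerance = 1e-12)
  withr::with_seed(41, {
    aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    seqs <- replicate(5, paste(sample(c(aas, "X", "-"), 60, TRUE,
                                      prob = c(rep(1, 20), .5, .5)),
                               collapse = ""))
    names(seqs) <- paste0("s", 1:5)
    got <- suppressWarnings(aa_distance_poisson(seqs))
    P <- naive_p_matrix(seqs, ambiguous = c("-", ".", "X", "*", "?"))
    expect_equal(unname(got$p), P, tolerance = 1e-12)
    d_exp <- ifelse(P >= 1, 10, -log(1 - P)); diag(d_exp) <- 0
    expect_equal(unname(got$d), d_exp, tolerance = 1e-9)
  })
})

test_that("nucleotide distances match closed forms and are monotone in p", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAATTT")  # p = 0.3
  expect_equal(nt_distance(aln, "p")$d[1, 2], 0.3)
  expect_equal(nt_distance(aln, "JC69")$d[1, 2], -0.75 * log(1 - 0.4),
               tolerance = 1e-12)
  # K80 with transversions only equals its closed form with P = 0
  k <- nt_distance(c(a = "AAAAAAAAAA", b = "CCAAAAAAAA"), "K80")
  expect_equal(k$d[1, 2], -0.5 * log((1 - 0.2) * sqrt(1 - 0.4)),
               tolerance = 1e-12)
  withr::with_seed(42, {
    for (i in 1:10) {
      s <- rand_dna(120)
      v <- strsplit(s, "")[[1]]
      k1 <- sample(5:40, 1)
      for (p in sample(120, k1)) v[p] <- sample(setdiff(c("A","C","G","T"), v[p]), 1)
      aln <- c(a = s, b = paste(v, collapse = ""))
      pd <- nt_distance(aln, "p")$d[1, 2]
      jc <- nt_distance(aln, "JC69")$d[1, 2]
      expect_gte(jc, pd)  # JC69 >= p pointwise
    }
  })
  w <- testthat::capture_warnings(nt_distance(c(a = "AAAA", b = "TTTT"), "JC69"))
  expect_true(any(grepl("saturated", w)))
})

test_that("neighbor joining is exact on additive matrices", {
  withr::with_seed(43, {
    for (i in 1:30) {
      n <- sample(4:12, 1)
      tr <- ape::rtree(n)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
      D <- ape::cophenetic.phylo(tr)
      est <- nj_tree(D)
      got <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
      expect_equal(got, D, tolerance = 1e-6)
      # independent cross-check of the topology against ape's NJ
      expect_equal(ape::dist.topo(ape::unroot(tr), est), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("three taxa solve the three-point equations; ties are deterministic", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(D)
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("x", "y", "z")]), c(1, 2, 3))
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  # fully tied matrix: repeated runs give identical trees
  E <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5])); diag(E) <- 0
  expect_identical(ape::write.tree(nj_tree(E)), ape::write.tree(nj_tree(E)))
})

support_for <- function(tree, tips) {
  sup <- attr(tree, "support")
  all_tips <- sort(tree$tip.label)
  for (k in names(sup)) {
    side <- strsplit(k, "|", fixed = TRUE)[[1]]
    if (setequal(side, tips) || setequal(side, setdiff(all_tips, tips))) {
      return(unname(sup[[k]]))
    }
  }
  NA_real_
}

test_that("bootstrap support behaves at its extremes and is reproducible", {
  aln <- c(a1 = "AAAAAAAAAACCCCC", a2 = "AAAAAAAAAACCCCG",
           b1 = "TTTTTTTTTTGGGGG", b2 = "TTTTTTTTTTGGGGA",
           out = "ACGTACGTAAGTACG")
  one <- bootstrap_support(aln, model = "p", replicates = 1, seed = 3)
  expect_true(all(attr(one, "support") %in% c(0, 100)))
  b1 <- bootstrap_support(aln, model = "p", replicates = 50, seed = 7)
  b2 <- bootstrap_support(aln, model = "p", replicates = 50, seed = 7)
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  # two well-separated clusters: the separating bipartition is near-certain
  expect_gte(support_for(b1, c("a1", "a2")), 95)
  expect_gte(support_for(b1, c("b1", "b2")), 95)
  # label permutation leaves the bipartition supports invariant
  perm <- c(3, 1, 5, 2, 4)
  bp <- bootstrap_support(aln[perm], model = "p", replicates = 50, seed = 7)
  expect_equal(support_for(bp, c("a1", "a2")), support_for(b1, c("a1", "a2")))
  expect_equal(support_for(bp, c("b1", "b2")), support_for(b1, c("b1", "b2")))
})

test_that("degenerate one-column alignments are flagged", {
  expect_warning(bootstrap_support(c(a = "A", b = "T", c = "A", d = "T"),
                                   model = "p", replicates = 5, seed = 1),
                 "degenerate")
})
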