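test_that("supermatrix concatenation pads missing taxa and tiles partitions", {
  a1 <- c(t1 = strrep("A", 100), t2 = strrep("C", 100))
  a2 <- c(t1 = strrep("G", 50), t2 = strrep("T", 50))
  sm <- concatenate_supermatrix(list(locA = a1, locB = a2))
  expect_equal(ncol(sm$alignment), 150L)
  expect_equal(sm$partitions$start, c(1L, 101L))
  expect_equal(sm$partitions$end, c(100L, 150L))

  # taxon present in locus 1 only: all-gap block in locus 2
  sm2 <- concatenate_supermatrix(list(locA = a1, locB = a2[1]))
  expect_true(all(sm2$alignment["t2", 101:150] == "-"))

  # counting oracle: non-gap columns per taxon = sum of its locus lengths
  set.seed(31)
  taxa <- paste0("x", 1:8)
  lens <- c(40, 25, 60, 15, 30)
  alns <- lapply(lens, function(L) {
    pick <- sample(taxa, sample(3:8, 1))
    setNames(vapply(pick, function(t) random_dna(L), character(1)), pick)
  })
  names(alns) <- paste0("loc", seq_along(alns))
  sm3 <- concatenate_supermatrix(alns)
  for (t in taxa) {
    expected <- sum(vapply(alns, function(a) {
      if (t %in% names(a)) nchar(a[[t]]) else 0L
    }, numeric(1)))
    got <- if (t %in% rownames(sm3$alignment)) {
      sum(sm3$alignment[t, ] != "-")
    } else 0
    expect_equal(got, expected)
  }

  expect_error(concatenate_supermatrix(list(l1 = c(t1 = "AC", t1 = "AG"))),
               "unique|duplicate")
})

test_that("neighbor joining recovers additive structure", {
  # additive 4-taxon matrix: ((a,b),(c,d)) with internal edge 3
  lab <- c("a", "b", "c", "d")
  D <- matrix(c(0, 2, 7, 8,
                2, 0, 7, 8,
                7, 7, 0, 3,
                8, 8, 3, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(D)
  pd <- patristic_matrix(tr)[lab, lab]
  expect_equal(pd, D, tolerance = 1e-9)  # additivity: NJ is exact here

  # three taxa: closed-form three-point solution
  D3 <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3, dimnames = list(lab[1:3], lab[1:3]))
  tr3 <- ape::nj(stats::as.dist(D3))
  el <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(unname(el["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(el["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(el["c"]), (4 + 5 - 3) / 2)

  # identical pair: zero-length cherry
  D0 <- matrix(c(0, 0, 4,
                 0, 0, 4,
                 4, 4, 0), 3, 3, dimnames = list(lab[1:3], lab[1:3]))
  tr0 <- nj_tree(D0)
  expect_equal(patristic_matrix(tr0)["a", "b"], 0)

  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(nj_tree(Dna), "missing")
  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")
})

test_that("patristic matrix equals brute-force path sums", {
  cherry <- ape::read.tree(text = "(a:1,b:2);")
  pdc <- patristic_matrix(cherry)
  expect_equal(pdc["a", "a"], 0)
  expect_equal(pdc["a", "b"], 3)

  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    tr <- ape::rtree(n)
    pd <- patristic_matrix(tr)
    expect_equal(pd, patristic_oracle(tr)[rownames(pd), colnames(pd)],
                 tolerance = 1e-12)
    expect_equal(pd, ape::cophenetic.phylo(tr)[rownames(pd), colnames(pd)],
                 tolerance = 1e-9)
  }

  # four-point condition holds on trees
  tr <- ape::rtree(8)
  pd <- patristic_matrix(tr)
  tips <- rownames(pd)
  for (k in 1:20) {
    q <- sample(tips, 4)
    s <- sort(c(pd[q[1], q[2]] + pd[q[3], q[4]],
                pd[q[1], q[3]] + pd[q[2], q[4]],
                pd[q[1], q[4]] + pd[q[2], q[3]]))
    expect_lt(abs(s[2] - s[3]), 1e-9)
  }
})

test_that("query assignment follows the monophyly and distance rules", {
  # query identical to a reference: zero-length terminal pair
  t1 <- ape::read.tree(
    text = "((q1:0,S1_r1:0):0.02,(S1_r2:0.01,(S2_r1:0.005,S2_r2:0.005):0.02):0.01);")
  map1 <- c(S1_r1 = "S1", S1_r2 = "S1", S2_r1 = "S2", S2_r2 = "S2")
  r1 <- assign_queries(t1, map1)
  expect_equal(r1$assigned, "S1")
  expect_equal(r1$nearest_dist, 0)
  expect_true(r1$monophyly_ok)

  # query attaching between two species' clades, too far from both
  t2 <- ape::read.tree(text = paste0(
    "(q2:0.08,((A_r1:0.001,A_r2:0.001):0.05,",
    "(B_r1:0.001,B_r2:0.001):0.05):0.01);"))
  map2 <- c(A_r1 = "A", A_r2 = "A", B_r1 = "B", B_r2 = "B")
  r2 <- assign_queries(t2, map2)
  expect_equal(r2$assigned, "unidentified")
  expect_false(r2$monophyly_ok)
  expect_false(r2$distance_ok)
  expect_match(r2$clade_species, "A/B")

  # invariance to leaf-order representation (ladderized newick)
  t1rot <- ape::read.tree(text = ape::write.tree(ape::ladderize(t1, right = FALSE)))
  r1b <- assign_queries(t1rot, map1)
  expect_equal(r1b$assigned, r1$assigned)
  expect_equal(r1b$nearest_dist, r1$nearest_dist)

  # query label colliding with a reference label is rejected
  tdup <- t1
  tdup$tip.label[1] <- "S1_r2"
  expect_error(assign_queries(tdup, map1), "unique")
})

test_that("per-group distance distributions partition all pairs", {
  set.seed(55)
  tr <- ape::rtree(12)
  pd <- patristic_matrix(tr)
  tips <- rownames(pd)
  spmap <- setNames(rep(paste0("sp", 1:6), each = 2), tips)
  genus <- setNames(rep(c("GenA", "GenB", "GenC"), each = 4), tips)

  dd <- intra_inter_density(pd, spmap, genus)
  expect_equal(nrow(dd), 3L)
  # union of group vectors = brute-force classification within groups
  for (g in dd$group) {
    mem <- names(genus)[genus == g]
    brute_intra <- brute_inter <- numeric(0)
    for (i in seq_along(mem)) for (j in seq_along(mem)) {
      if (i < j) {
        v <- pd[mem[i], mem[j]]
        if (spmap[mem[i]] == spmap[mem[j]]) brute_intra <- c(brute_intra, v)
        else brute_inter <- c(brute_inter, v)
      }
    }
    row <- dd[dd$group == g, ]
    expect_setequal(row$intra[[1]], brute_intra)
    expect_setequal(row$inter[[1]], brute_inter)
  }

  # one species, several samples: empty inter vector
  one <- intra_inter_density(pd, spmap,
                             setNames(rep("G1", 2), tips[1:2]))
  expect_equal(one$n_inter, 0L)

  # constructed separation: no overlap flag
  t3 <- ape::read.tree(text = "((a1:0.005,a2:0.005):0.025,(b1:0.005,b2:0.005):0.025);")
  pd3 <- patristic_matrix(t3)
  dd3 <- intra_inter_density(
    pd3, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
    setNames(rep("G", 4), rownames(pd3)))
  expect_false(dd3$overlap)
  expect_equal(dd3$max_intra, 0.01)
  expect_equal(dd3$min_inter, 0.06)
})

test_that("recovery statistics follow the Table-2 definitions", {
  full <- setNames(rep(100, 353), paste0("g", 1:353))
  r1 <- recovery_stats(full, full)
  expect_equal(r1$genes_assembled, 353L)
  expect_equal(r1$genes_at_50, 353L)
  expect_equal(r1$length_pct, 100)

  r2 <- recovery_stats(c(g1 = 100, g2 = 60, g3 = 40, g4 = 0),
                       c(g1 = 100, g2 = 100, g3 = 100, g4 = 100))
  expect_equal(r2$genes_assembled, 3L)
  expect_equal(r2$genes_at_50, 2L)
  expect_equal(r2$length_pct, 50)

  r3 <- recovery_stats(setNames(rep(0, 4), paste0("g", 1:4)),
                       setNames(rep(100, 4), paste0("g", 1:4)))
  expect_equal(r3$genes_assembled, 0L)
  expect_equal(r3$length_pct, 0)

  expect_warning(
    r4 <- recovery_stats(c(g1 = 150), c(g1 = 100)), "clamped")
  expect_equal(r4$length_pct, 100)
})
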