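test_that("haplotype collapsing removes exact duplicates only", {
  trio <- c(x1 = "ACGTAC", x2 = "ACGTAC", x3 = "ACGTAC")
  out <- collapse_haplotypes(trio)
  expect_equal(length(out$records), 1L)
  expect_equal(nrow(out$mapping), 3L)
  expect_true(all(out$mapping$haplotype_id == "x1"))

  # case-insensitive
  out2 <- collapse_haplotypes(c(a = "acgt", b = "ACGT", c = "ACGA"))
  expect_equal(length(out2$records), 2L)
  expect_equal(out2$mapping$haplotype_id, c("a", "a", "c"))

  # gap-column differences stay distinct
  out3 <- collapse_haplotypes(c(a = "AC-T", b = "ACGT"))
  expect_equal(length(out3$records), 2L)

  # hash-set oracle on random sequences with planted duplicates
  set.seed(10)
  base <- vapply(1:38, function(i) random_dna(40), character(1))
  seqs <- c(base, base[sample.int(38, 12)])
  names(seqs) <- paste0("s", seq_along(seqs))
  out4 <- collapse_haplotypes(seqs)
  expect_equal(length(out4$records), length(unique(toupper(seqs))))
  expect_setequal(out4$mapping$id, names(seqs))

  expect_error(collapse_haplotypes(c(a = "ACG", b = "AC")), "length")
})

test_that("tn93 matches the independently coded Tamura-Nei formula", {
  # identical sequences
  r0 <- tn93(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(r0$P1, 0); expect_equal(r0$P2, 0); expect_equal(r0$Q, 0)
  expect_equal(r0$d, 0)
  expect_false(r0$undefined)

  # constructed pair: equal base composition, exactly 40 A<->G differences
  a <- paste0(strrep("A", 100), strrep("C", 100), strrep("G", 100), strrep("T", 100))
  bv <- strsplit(a, "", fixed = TRUE)[[1]]
  bv[1:20] <- "G"          # 20 A -> G
  bv[201:220] <- "A"       # 20 G -> A (composition preserved)
  b <- paste(bv, collapse = "")
  r <- tn93(a, b)
  expect_equal(r$P1, 0.1)
  expect_equal(r$P2, 0)
  expect_equal(r$Q, 0)
  expect_equal(r$n_sites, 400L)
  expect_equal(r$d, tn93_oracle(a, b), tolerance = 1e-12)

  # random pairs vs the oracle and vs ape's implementation
  set.seed(77)
  for (i in 1:100) {
    pr <- random_pair(500, keep = 0.8 + 0.15 * runif(1))
    r <- tn93(pr$a, pr$b)
    ref <- tn93_oracle(pr$a, pr$b)
    if (is.na(ref)) {
      expect_true(r$undefined)
    } else {
      expect_equal(r$d, ref, tolerance = 1e-10)
    }
  }
  pr <- random_pair(2000, keep = 0.9, gaps = FALSE)
  r <- tn93(pr$a, pr$b)
  dape <- ape::dist.dna(ape::as.DNAbin(rbind(
    strsplit(tolower(pr$a), "")[[1]], strsplit(tolower(pr$b), "")[[1]])),
    model = "TN93", pairwise.deletion = TRUE)
  expect_equal(r$d, as.numeric(dape), tolerance = 1e-3)

  # zero comparable sites: undefined result, not an exception
  rz <- tn93("----", "NNNN")
  expect_true(rz$undefined)
  expect_equal(rz$n_sites, 0L)

  # saturated pair: flagged undefined
  rs <- tn93(strrep("A", 50), strrep("C", 50))
  expect_true(rs$undefined)
})

test_that("distance matrix equals pairwise tn93 cell by cell", {
  set.seed(5)
  seqs <- vapply(1:10, function(i) random_pair(300, keep = 0.9)$b, character(1))
  names(seqs) <- paste0("t", 1:10)
  D <- distance_matrix(seqs, "tn93")
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:9) for (j in (i + 1):10) {
    r <- tn93(seqs[i], seqs[j])
    if (r$undefined) expect_true(is.na(D[i, j]))
    else expect_equal(D[i, j], r$d, tolerance = 1e-12)
  }

  # identical pair: zero matrix
  D0 <- distance_matrix(c(a = "ACGTACGT", b = "ACGTACGT"), "tn93")
  expect_equal(unname(D0), matrix(0, 2, 2))

  # undefined pairs are missing, not zero
  Dna <- distance_matrix(c(a = strrep("A", 30), b = strrep("C", 30),
                           c = strrep("A", 30)), "tn93")
  expect_true(is.na(Dna["a", "b"]))
  expect_equal(Dna["a", "c"], 0)

  # correction never shrinks the raw distance; label permutation invariance
  P <- distance_matrix(seqs, "p")
  expect_true(all(D >= P - 1e-12, na.rm = TRUE))
  perm <- sample(names(seqs))
  D2 <- distance_matrix(seqs[perm], "tn93")
  expect_equal(D2[names(seqs), names(seqs)], D)

  expect_error(distance_matrix(c(a = "ACGT")), "at least 2")
})

test_that("barcode gap summary partitions pairs and flags shared haplotypes", {
  # two well-separated species
  seqs <- c(A1 = strrep("ACGT", 10), A2 = strrep("ACGT", 10),
            B1 = strrep("ACGA", 10), B2 = strrep("ACGA", 10))
  D <- distance_matrix(seqs, "p")
  rep1 <- barcode_gap_summary(D, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_true(all(rep1$per_species$discriminable))
  expect_equal(rep1$per_species$gap, rep(0.25, 2))

  # shared haplotype between species forces both to fail
  seqs2 <- c(A1 = strrep("ACGT", 10), A2 = strrep("ACGT", 10),
             B1 = strrep("ACGT", 10), B2 = strrep("ACGC", 10))
  D2 <- distance_matrix(seqs2, "p")
  rep2 <- barcode_gap_summary(D2, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_true(all(rep2$per_species$shared_haplotype))
  expect_false(any(rep2$per_species$discriminable))

  # counting oracle: intra + inter pair counts sum to n(n-1)/2
  set.seed(20)
  n <- 24
  seqs3 <- setNames(vapply(1:n, function(i) random_dna(120), character(1)),
                    paste0("q", 1:n))
  spmap <- setNames(sample(paste0("sp", 1:8), n, replace = TRUE), names(seqs3))
  D3 <- distance_matrix(seqs3, "p")
  rep3 <- barcode_gap_summary(D3, spmap)
  expect_equal(length(rep3$intra) + length(rep3$inter), n * (n - 1) / 2)

  expect_error(barcode_gap_summary(D3, spmap[-1]), "unmapped")
})

test_that("liberal tree-based identification scores the documented topologies", {
  # reciprocal monophyly: 100% success
  t1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  m1 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  r1 <- tree_identification_success(t1, m1)
  expect_equal(r1$overall, 1)

  # species C split into two clades, each sequence sister to a conspecific
  t2 <- ape::read.tree(
    text = "(((c1:1,c2:1):1,(b1:1,b2:1):1):1,(c3:1,c4:1):2);")
  m2 <- c(c1 = "C", c2 = "C", c3 = "C", c4 = "C", b1 = "B", b2 = "B")
  r2 <- tree_identification_success(t2, m2)
  expect_true(r2$per_species$success[r2$per_species$species == "C"])

  # singleton D nested inside E's clade: D distance-only, E fails
  t3 <- ape::read.tree(text = "((e1:1,d1:1):1,(e2:1,e3:1):1);")
  m3 <- c(e1 = "E", e2 = "E", e3 = "E", d1 = "D")
  r3 <- tree_identification_success(t3, m3)
  per <- r3$per_species
  expect_equal(per$category[per$species == "D"], "distance-only")
  expect_false(per$success[per$species == "E"])

  # unrooted tree without outgroup is rejected
  t4 <- ape::unroot(ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1,x:3);"))
  expect_error(tree_identification_success(t4, c(m1, x = "X")), "outgroup")
  r4 <- tree_identification_success(t4, c(m1, x = "X"), outgroup = "x")
  expect_equal(r4$overall, 1)
})
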