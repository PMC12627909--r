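test_that("seed-vote mapping places reads correctly and drops junk", {
  set.seed(61)
  ref <- setNames(random_dna(8000), "plast")

  # error-free reads from the reference itself: all at true positions
  rs <- simulate_reads(ref, coverage = 10, read_length = 150,
                       error_rate = 0, seed = 2)
  aln <- naive_map(rs, ref)
  expect_equal(nrow(aln), nrow(rs))
  expect_equal(aln$pos, rs$start[match(aln$read_id, rs$read_id)])
  expect_true(all(aln$mismatches == 0L))

  # reads from a 2%-divergent sequence: >= 95% at true positions
  refv <- strsplit(unname(ref), "", fixed = TRUE)[[1]]
  mut <- sample(length(refv), round(0.02 * length(refv)))
  refv[mut] <- vapply(refv[mut], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  variant <- setNames(paste(refv, collapse = ""), "variant")
  rsv <- simulate_reads(variant, coverage = 10, read_length = 150,
                        error_rate = 0, seed = 3)
  alnv <- naive_map(rsv, ref, k = 21)
  truth <- rsv$start[match(alnv$read_id, rsv$read_id)]
  expect_gte(sum(alnv$pos == truth) / nrow(rsv), 0.95)

  # unrelated read: no seed hit, discarded
  junk <- tibble::tibble(read_id = "junk",
                         seq = strrep("AC", 75))
  expect_equal(nrow(naive_map(junk, ref)), 0L)

  expect_error(naive_map(rs, ref, k = 500), "read length")
})

test_that("pileup counts bases and conserves the total", {
  ref <- "ACGTACGTACGTACGTACGT"
  one <- tibble::tibble(read_id = "r1", pos = 3L, seq = "GTACG")
  p1 <- pileup(one, ref)
  expect_equal(nrow(p1), 5L)
  expect_true(all(p1$depth == 1L))
  # error-free read: counts concentrated on the reference base
  for (i in seq_len(nrow(p1))) {
    expect_equal(p1[[p1$ref_base[i]]][i], 1L)
  }

  two <- tibble::tibble(read_id = c("r1", "r2"), pos = c(1L, 3L),
                        seq = c("ACA", "AG"))
  p2 <- pileup(two, ref)
  col3 <- p2[p2$position == 3L, ]
  expect_equal(col3$depth, 2L)
  expect_equal(col3$A, 2L)  # both reads put A at position 3

  # conservation oracle: counted bases = aligned ACGT bases
  set.seed(62)
  ref2 <- random_dna(2000)
  rds <- simulate_reads(setNames(ref2, "x"), coverage = 8, read_length = 100,
                        error_rate = 0.02, seed = 4)
  aln <- naive_map(rds, ref2)
  pp <- pileup(aln, ref2)
  expect_equal(sum(pp$A + pp$C + pp$G + pp$T), sum(nchar(aln$seq)))
  expect_equal(sum(pp$depth), sum(nchar(aln$seq)))

  bad <- tibble::tibble(read_id = "r", pos = 1999L, seq = "ACGT")
  expect_error(pileup(bad, ref2), "beyond")
})

test_that("SNP counting applies the allele-frequency and depth filters", {
  # no variation: zero SNPs
  ref <- random_dna(500)
  rds <- simulate_reads(setNames(ref, "x"), coverage = 20, read_length = 100,
                        error_rate = 0, seed = 7)
  pile0 <- pileup(naive_map(rds, ref), ref)
  expect_equal(count_snps(pile0, f = 0.2, min_depth = 10), 0L)

  # depth 40 with 6 alternate bases: frequency 0.15 passes f=0.10 only
  col <- tibble::tibble(position = 1L, ref_base = "A", depth = 40L,
                        A = 34L, C = 6L, G = 0L, T = 0L)
  expect_equal(count_snps(col, f = 0.10, min_depth = 10), 1L)
  expect_equal(count_snps(col, f = 0.20, min_depth = 10), 0L)

  # constructed truth: 5 substitutions in a variant copy
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  pos5 <- c(50, 150, 250, 350, 450)
  refv[pos5] <- vapply(refv[pos5], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  variant <- paste(refv, collapse = "")
  rdsv <- simulate_reads(setNames(variant, "v"), coverage = 30,
                         read_length = 100, error_rate = 0, seed = 8)
  pilev <- pileup(naive_map(rdsv, ref), ref)
  expect_equal(count_snps(pilev, f = 0.2, min_depth = 10), 5L)

  # monotone non-increasing in f and in min_depth
  rdse <- simulate_reads(setNames(variant, "v"), coverage = 30,
                         read_length = 100, error_rate = 0.01, seed = 9)
  pe <- pileup(naive_map(rdse, ref), ref)
  fs <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  counts_f <- vapply(fs, function(f) count_snps(pe, f, 5), integer(1))
  expect_true(all(diff(counts_f) <= 0))
  depths <- c(1, 5, 10, 20)
  counts_d <- vapply(depths, function(d) count_snps(pe, 0.1, d), integer(1))
  expect_true(all(diff(counts_d) <= 0))

  expect_error(count_snps(col, f = 0.6), "f")
  expect_equal(count_snps(col[0, ], f = 0.2), 0L)
})

test_that("snp_density is the exact quotient with guarded input", {
  expect_equal(snp_density(0, 1000), 0)
  expect_equal(snp_density(5, 1000), 0.005)
  expect_equal(snp_density(1000, 1000), 1)
  expect_error(snp_density(5, 0), "positive")
})

test_that("pool classification separates homogeneous pools from mixes", {
  rep1 <- tibble::tibble(pool_id = "p", reference = "A", f = 0.1,
                         min_depth = 10L, snp_count = 0L,
                         ref_length = 1000L, density = 0)
  v1 <- classify_pool(rep1)
  expect_true(v1$homogeneous)
  expect_equal(v1$best_reference, "A")

  reps <- dplyr::bind_rows(
    rep1,
    tibble::tibble(pool_id = "p", reference = "B", f = 0.1, min_depth = 10L,
                   snp_count = 12L, ref_length = 1000L, density = 0.012))
  v2 <- classify_pool(reps, gap_ratio = 3)
  expect_true(v2$homogeneous)
  expect_equal(v2$best_reference, "A")
  expect_equal(v2$margin, 0.012)

  mixed <- reps
  mixed$density <- c(0.010, 0.012)
  expect_false(classify_pool(mixed, gap_ratio = 3)$homogeneous)

  bad_f <- reps; bad_f$f <- c(0.1, 0.2)
  expect_error(classify_pool(bad_f), "inconsistent")
})

test_that("control panel reproduces the intraspecific/mixed density contrast", {
  cfg <- simulation_config(plastome_length = 6000L)
  cp <- simulate_control_pools(cfg, seed = 91)
  panel <- control_panel(cp$pools[c("pure_A", "mix11_AB", "mix19_AD")],
                         cp$references[c("taxonA", "taxonB", "taxonD")],
                         f_values = c(0.2, 0.1))
  # intraspecific pool density below every interspecific comparison
  own <- panel$density[panel$pool_id == "pure_A" & panel$reference == "taxonA"]
  foreign <- panel$density[panel$pool_id == "pure_A" & panel$reference != "taxonA"]
  expect_true(all(own < foreign))

  # f monotonicity on the same pool/reference
  for (pr in unique(paste(panel$pool_id, panel$reference))) {
    sub <- panel[paste(panel$pool_id, panel$reference) == pr, ]
    expect_lte(sub$snp_count[sub$f == 0.2], sub$snp_count[sub$f == 0.1])
  }

  # 1:9 mix against the major member's reference: minor-species sites near
  # 10% frequency are filtered at f = 0.2 but kept at f = 0.1
  d19 <- panel[panel$pool_id == "mix19_AD" & panel$reference == "taxonD", ]
  expect_lt(d19$density[d19$f == 0.2], d19$density[d19$f == 0.1])

  # verdicts at f = 0.1: pure homogeneous, mixes not
  v_pure <- classify_pool(panel[panel$pool_id == "pure_A" & panel$f == 0.1, ])
  expect_true(v_pure$homogeneous)
  expect_equal(v_pure$best_reference, "taxonA")
  v_mix <- classify_pool(panel[panel$pool_id == "mix11_AB" & panel$f == 0.1, ])
  expect_false(v_mix$homogeneous)

  # empty pool list: empty table
  expect_equal(nrow(control_panel(list(), cp$references)), 0L)
})

test_that("SAM ingestion keeps primary mapped records and clips correctly", {
  ref <- strrep("ACGT", 15)  # 60 bp
  sam <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:ref1\tLN:60",
    paste("r1", "0", "ref1", "3", "60", "10M", "*", "0", "0",
          substring(ref, 3, 12), "IIIIIIIIII", sep = "\t"),
    paste("r2", "0", "ref1", "5", "60", "2S8M", "*", "0", "0",
          paste0("TT", substring(ref, 5, 12)), "IIIIIIIIII", sep = "\t"),
    paste("r3", "4", "ref1", "1", "0", "*", "*", "0", "0",
          "ACGT", "IIII", sep = "\t"),
    paste("r4", "256", "ref1", "3", "60", "10M", "*", "0", "0",
          substring(ref, 3, 12), "IIIIIIIIII", sep = "\t"),
    paste("r5", "0", "ref1", "9", "10", "6M", "*", "0", "0",
          substring(ref, 9, 14), "IIIIII", sep = "\t")
  )
  sam_path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, sam_path)

  aln <- read_sam_alignments(sam_path)
  expect_setequal(aln$read_id, c("r1", "r2", "r5"))  # unmapped/secondary out
  r2 <- aln[aln$read_id == "r2", ]
  expect_equal(r2$pos, 5L)
  expect_equal(r2$seq, substring(ref, 5, 12))        # soft clip removed

  # mapping-quality threshold
  aln2 <- read_sam_alignments(sam_path, min_mapq = 30)
  expect_setequal(aln2$read_id, c("r1", "r2"))

  # clean records pile up onto the reference with no alternate alleles
  pp <- pileup(aln, ref)
  expect_equal(sum(pp$A + pp$C + pp$G + pp$T), sum(nchar(aln$seq)))
  expect_equal(count_snps(pp, f = 0.1, min_depth = 1), 0L)
})
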