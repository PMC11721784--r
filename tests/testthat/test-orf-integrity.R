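test_that("CDS extraction respects strand and interval order", {
  genome <- c(chr1 = "TTATGAAATGATT")
  m <- gene_model("g", "chr1", "+", data.frame(start = 2L, end = 11L))
  expect_equal(extract_cds(genome, m), "ATGAAATGA")

  # minus strand: genomic slice TCATTTCAT reverse-complements to ATGAAATGA
  genome2 <- c(chr1 = "GGTCATTTCATGG")
  m2 <- gene_model("g2", "chr1", "-", data.frame(start = 2L, end = 11L))
  expect_equal(extract_cds(genome2, m2), "ATGAAATGA")

  # two intervals concatenated; non-multiple-of-3 length warns at model build
  expect_warning(
    m3 <- gene_model("g3", "chr1", "+",
                     data.frame(start = c(0L, 7L), end = c(5L, 10L))),
    "multiple of 3")
  genome3 <- c(chr1 = "ATGAACCATGCC")
  expect_equal(extract_cds(genome3, m3), "ATGAAATG")

  m4 <- gene_model("g4", "chr1", "+", data.frame(start = 2L, end = 20L))
  expect_error(extract_cds(genome, m4), "out of bounds")
})

test_that("variant application follows half-open edit semantics", {
  expect_equal(apply_variants("ATGAAATGA",
                              data.frame(pos = 3L, ref = "A", alt = "T")),
               "ATGTAATGA")
  # 1-bp deletion via the half-open slice [4,5)
  expect_equal(apply_variants("ATGAAATGA",
                              data.frame(pos = 4L, ref = "A", alt = "")),
               "ATGAATGA")
  # VCF-style anchored deletion
  expect_equal(apply_variants("ATGAAATGA",
                              data.frame(pos = 3L, ref = "AA", alt = "A")),
               "ATGAATGA")
  expect_error(apply_variants("ATGAAATGA",
                              data.frame(pos = 0L, ref = "C", alt = "T")),
               "mismatch at position 0")
  expect_error(apply_variants("ATGAAATGA",
                              data.frame(pos = c(2L, 3L), ref = c("GA", "AA"),
                                         alt = c("G", "A"))),
               "overlapping")
})

test_that("variant application is order-invariant given non-overlap", {
  set.seed(42)
  for (rep in 1:25) {
    cds <- random_cds(30L)
    edits <- NULL
    while (is.null(edits)) edits <- random_edits(cds, sample(2:4, 1L))
    shuffled <- edits[sample(nrow(edits)), , drop = FALSE]
    expect_identical(apply_variants(cds, edits), apply_variants(cds, shuffled))
  }
})

test_that("ORF classification matches the stated decision rule", {
  expect_equal(classify_orf("ATGAAATGA", 2L), "FUNCTIONAL")
  expect_equal(classify_orf("ATGTAATGA", 2L), "PREMATURE_STOP")
  expect_equal(classify_orf("ATAAAATGA", 2L), "START_LOST")
  expect_equal(classify_orf("ATGAAAAAA", 2L), "STOP_LOST")
  # frameshifted sequence classified through its translated consequence
  expect_equal(classify_orf("ATGATGA", 2L), oracle_classify("ATGATGA", 2L))
})

test_that("synonymous substitutions never change the ORF status", {
  set.seed(7)
  syn_pairs <- list(c("GGA", "GGG"), c("CTA", "CTG"), c("TCA", "TCT"))
  for (rep in 1:50) {
    n <- sample(10:40, 1L)
    cds <- random_cds(n)
    pair <- syn_pairs[[sample.int(3, 1L)]]
    codon_i <- sample(2:(n - 1L), 1L)
    cds_mut <- cds
    substr(cds_mut, (codon_i - 1L) * 3L + 1L, codon_i * 3L) <- pair[1]
    edited <- apply_variants(cds_mut,
      data.frame(pos = (codon_i - 1L) * 3L + 2L,
                 ref = substr(pair[1], 3, 3), alt = substr(pair[2], 3, 3)))
    expect_equal(classify_orf(edited, n), classify_orf(cds_mut, n))
  }
})

test_that("presence calling applies the HET/MISSING policy", {
  genome <- c(chr1 = "TTATGAAATGATT")
  m <- gene_model("g", "chr1", "+", data.frame(start = 2L, end = 11L))
  variants <- data.frame(chrom = "chr1", pos = 6L, id = NA, ref = "A",
                         alt = "T")  # creates ATGTAATGA: premature stop
  calls <- matrix(c("REF", "ALT", "HET", "MISSING"), ncol = 1,
                  dimnames = list(c("w", "x", "y", "z"), NULL))
  gm <- genotype_matrix(c("w", "x", "y", "z"), variants, calls)

  strict <- call_presence(m, genome, gm, policy = "strict")
  expect_equal(strict$status, c("FUNCTIONAL", "PREMATURE_STOP",
                                "UNRESOLVED", "UNRESOLVED"))
  expect_equal(strict$present, c(TRUE, FALSE, FALSE, FALSE))

  anyf <- call_presence(m, genome, gm, policy = "any-functional")
  expect_equal(anyf$status, c("FUNCTIONAL", "PREMATURE_STOP",
                              "FUNCTIONAL", "FUNCTIONAL"))
  expect_error(call_presence(m, genome, gm, policy = "nonsense"))
})

test_that("zero applied variants reproduce the reference classification", {
  set.seed(11)
  g <- gen_catalog_variants(populations = c(p = 4L),
                            lof_freq = matrix(0, 2, 1,
                                              dimnames = list(NULL, "p")),
                            seed = 5)
  calls <- do.call(rbind, lapply(g$models, call_presence, genome = g$genome,
                                 genotypes = g$genotypes))
  expect_true(all(calls$status == "FUNCTIONAL"))
  expect_true(all(calls$present))
})
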