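quartet_aln <- function(ing1, ing2, outg, ref = "ingroup1") {
  ortholog_alignment(c(ingroup1 = ing1, ingroup2 = ing2, outgroup = outg),
                     reference_id = ref)
}
QTREE <- "((ingroup1,ingroup2),outgroup);"

test_that("parsimony ancestor follows outgroup rooting and tie-breaks", {
  # all identical
  a <- quartet_aln("ATGAAATAA", "ATGAAATAA", "ATGAAATAA")
  expect_equal(unname(reconstruct_ancestor_parsimony(a, QTREE, "outgroup")),
               "ATGAAATAA")
  # ingroup {A, A}, outgroup G at column 4: ancestor keeps A
  b <- quartet_aln("ATGAAATAA", "ATGAAATAA", "ATGGAATAA")
  expect_equal(unname(substr(reconstruct_ancestor_parsimony(b, QTREE, "outgroup"),
                             4, 4)), "A")
  # ingroup {A, G}, outgroup G: outgroup breaks the tie toward G
  d <- quartet_aln("ATGAAATAA", "ATGGAATAA", "ATGGAATAA")
  expect_equal(unname(substr(reconstruct_ancestor_parsimony(d, QTREE, "outgroup"),
                             4, 4)), "G")
  expect_error(
    reconstruct_ancestor_parsimony(b, "((ingroup1,missing),outgroup);",
                                   "outgroup"),
    "missing")
})

test_that("parsimony agrees with exhaustive minimum-change enumeration", {
  set.seed(19)
  states <- c("A", "C", "G", "T", "-")
  tree <- "(((a,b),(c,d)),outgroup);"
  for (rep in 1:200) {
    col <- sample(states, 5, replace = TRUE)
    names(col) <- c("a", "b", "c", "d", "outgroup")
    recs <- stats::setNames(paste0(c(col, "A"), "AA"), c(names(col), "ref"))
    aln <- ortholog_alignment(recs, reference_id = "ref")
    anc <- reconstruct_ancestor_parsimony(aln, "((((a,b),(c,d)),ref),outgroup);",
                                          "outgroup")
    anc1 <- substr(unname(anc), 1, 1)
    optimal <- oracle_parsimony_states(
      list(list(list(col[["a"]], col[["b"]]), list(col[["c"]], col[["d"]])),
           "A"))  # the reference leaf sits inside the ingroup
    expect_true(anc1 %in% optimal)
    if (col[["outgroup"]] %in% optimal)
      expect_equal(anc1, col[["outgroup"]])
  }
})

test_that("branch events classify substitutions in the parent codon background", {
  ref <- "ATGAAAGGGTGA"
  aln <- quartet_aln(ref, ref, ref)
  ev <- function(parent, child)
    annotate_branch_events(parent, child, aln)
  # third-position synonymous change in codon 1 (AAA -> AAG)
  e <- ev("ATGAAAGGGTGA", "ATGAAGGGGTGA")
  expect_equal(e$kind, "SYN")
  expect_equal(e$codon_index, 1L)
  # first-position nonsynonymous change (AAA -> GAA)
  e <- ev("ATGAAAGGGTGA", "ATGGAAGGGTGA")
  expect_equal(e$kind, "NONSYN")
  # TGG -> TGA gains a stop; TGA -> TGG loses one
  e <- ev("ATGAAATGGTGA", "ATGAAATGATGA")
  expect_equal(e$kind, "STOP_GAIN")
  e <- ev("ATGAAATGATGA", "ATGAAATGGTGA")
  expect_equal(e$kind, "STOP_LOSS")
  # destroying the start codon
  e <- ev("ATGAAAGGGTGA", "GTGAAAGGGTGA")
  expect_equal(e$kind, "START_LOST")
  # a gap-vs-base run is one indel event with a column span
  aln2 <- quartet_aln("AAACCCGGG", "AAACCCGGG", "AAACCCGGG")
  e <- annotate_branch_events("AAA---GGG", "AAACCCGGG", aln2)
  expect_equal(e$kind, "INS")
  expect_equal(c(e$col_start, e$col_end), c(4L, 6L))
  e <- annotate_branch_events("AAACCCGGG", "AAA---GGG", aln2)
  expect_equal(e$kind, "DEL")
})

test_that("identical sequences yield no events; stop kinds are exclusive", {
  set.seed(23)
  for (rep in 1:10) {
    s <- random_cds(20L)
    aln <- quartet_aln(s, s, s)
    expect_equal(nrow(annotate_branch_events(s, s, aln)), 0L)
  }
  # SYN+NONSYN count equals substituted in-frame columns minus stop events
  q <- gen_ortholog_quartet(
    n_codons = 40L,
    events = list("ancestor:ingroup1" = c(SYN = 3, NONSYN = 5, STOP_GAIN = 1)),
    seed = 41)
  ev <- annotate_branch_events(q$ancestor, q$alignment$records[["ingroup1"]],
                               q$alignment)
  p <- strsplit(unname(q$ancestor), "")[[1]]
  k <- strsplit(unname(q$alignment$records[["ingroup1"]]), "")[[1]]
  n_sub_cols <- sum(p != k & p != "-" & k != "-")
  expect_equal(sum(ev$kind %in% c("SYN", "NONSYN")),
               n_sub_cols - sum(ev$kind %in% c("STOP_GAIN", "STOP_LOSS")))
})

test_that("multi-hit codons are flagged per-site or merged per-codon", {
  ref <- "ATGAAAGGGTGA"
  aln <- quartet_aln(ref, ref, ref)
  # two hits in codon 1: AAA -> GAC
  per_site <- annotate_branch_events("ATGAAAGGGTGA", "ATGGACGGGTGA", aln)
  expect_equal(nrow(per_site), 2L)
  expect_true(all(per_site$multi_hit))
  per_codon <- annotate_branch_events("ATGAAAGGGTGA", "ATGGACGGGTGA", aln,
                                      multi_hit = "per-codon")
  expect_equal(nrow(per_codon), 1L)
  expect_equal(per_codon$detail, "AAA->GAC")
})

test_that("TSD scan reports 1-based distances upstream of the start codon", {
  motif <- "CATGGC"
  # plant the motif so its 3' end sits 167 bp upstream of the ATG
  set.seed(5)
  bases <- sample(c("A", "C", "T"), 400, replace = TRUE)  # no G: no chance hits
  start_codon_pos <- 301L
  flank <- paste(bases, collapse = "")
  insert_at <- function(s, end3, motif) {
    # place motif so that its last base is at position start_codon_pos - end3
    e <- start_codon_pos - end3
    paste0(substr(s, 1, e - nchar(motif)), motif,
           substr(s, e + 1, nchar(s)))
  }
  flank <- insert_at(flank, 167L, motif)
  flank <- insert_at(flank, 232L, motif)
  hits <- scan_tsd(flank, motif, start_codon_pos)
  expect_equal(hits$distance_upstream, c(232L, 167L))  # 5' to 3' order
  expect_equal(nrow(scan_tsd(paste(rep("A", 50), collapse = ""), motif, 10L)),
               0L)
  # a motif ending immediately before the ATG has distance 1
  adj <- paste0(strrep("A", 10), motif, "ATGAAA")
  expect_equal(scan_tsd(adj, motif, 17L)$distance_upstream, 1L)
})

test_that("homology-hit filtering applies inclusive thresholds", {
  hits <- data.frame(
    query_id = "q", subject_id = letters[1:4],
    pct_identity = c(59.9, 60.0, 95, 80),
    align_len = c(80, 70, 90, 75),
    evalue = c(1e-10, 1e-5, 1e-4, 1e-8),
    qcov = c(80, 70, 90, 75))
  kept <- filter_homology_hits(hits)
  expect_equal(kept$subject_id, c("b", "d"))  # identity<60 and E>1e-5 removed

  # qcov derived from align_len and query length
  hits2 <- hits[, setdiff(names(hits), "qcov")]
  kept2 <- filter_homology_hits(hits2, query_lengths = c(q = 100))
  expect_equal(kept2$subject_id, c("b", "d"))

  hits$evalue[1] <- NA
  expect_warning(filter_homology_hits(hits), "rejected")
})
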