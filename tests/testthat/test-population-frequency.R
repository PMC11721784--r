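make_calls <- function(n_present, n_absent, n_unresolved = 0L,
                       gene = "g1", pop = "popA", prefix = pop) {
  n <- n_present + n_absent + n_unresolved
  acc <- sprintf("%s_%03d", prefix, seq_len(n))
  status <- c(rep("FUNCTIONAL", n_present), rep("PREMATURE_STOP", n_absent),
              rep("UNRESOLVED", n_unresolved))
  list(calls = data.frame(accession = acc, gene_id = gene, status = status,
                          present = status == "FUNCTIONAL", events = "",
                          stringsAsFactors = FALSE),
       pops = data.frame(accession = acc, population = pop,
                         stringsAsFactors = FALSE))
}

test_that("frequencies come out of counts with UNRESOLVED excluded", {
  x <- make_calls(55L, 5L)
  fr <- compute_frequency(x$calls, x$pops)
  expect_equal(fr$n_called, 60L)
  expect_equal(fr$n_present, 55L)
  expect_equal(round(fr$freq_pct, 1), 91.7)

  y <- make_calls(10L, 0L)
  expect_equal(compute_frequency(y$calls, y$pops)$freq_pct, 100)
  z <- make_calls(0L, 8L)
  expect_equal(compute_frequency(z$calls, z$pops)$freq_pct, 0)

  u <- make_calls(6L, 2L, n_unresolved = 2L)
  fu <- compute_frequency(u$calls, u$pops)
  expect_equal(fu$n_called, 8L)
  expect_equal(fu$freq_pct, 75)

  all_un <- make_calls(0L, 0L, n_unresolved = 3L)
  expect_warning(out <- compute_frequency(all_un$calls, all_un$pops),
                 "zero called")
  expect_equal(nrow(out), 0L)

  bad <- make_calls(2L, 0L)
  bad$pops <- bad$pops[-1L, ]
  expect_error(compute_frequency(bad$calls, bad$pops), "missing from")
})

test_that("spectrum binning follows the caption rule", {
  expect_equal(bin_frequency(c(0, 100)), c("0", "100"))
  expect_equal(bin_frequency(c(7, 10)), c("5", "15"))
  expect_equal(bin_frequency(99.9), "95")
  expect_error(bin_frequency(101), "0, 100")
  expect_error(bin_frequency(-1), "0, 100")
})

test_that("bin counts sum to the number of frequency records", {
  set.seed(3)
  freqs <- c(0, 100, runif(50, 0, 100))
  bins <- bin_frequency(freqs)
  expect_equal(sum(table(bins)), length(freqs))
})

test_that("population summary applies strict thresholds", {
  rec <- data.frame(gene_id = sprintf("g%02d", 1:20), population = "p",
                    freq_pct = c(90, 100, 5, rep(95, 17)))
  s <- summarize_population(rec)
  # the gene at exactly 90% is NOT nearly fixed under the strict ">" rule
  expect_equal(s$nearly_fixed_frac, 18 / 20)
  expect_equal(s$low_frac, 1 / 20)
  s2 <- summarize_population(rec, strict = FALSE)
  expect_equal(s2$nearly_fixed_frac, 19 / 20)

  all_fixed <- data.frame(gene_id = c("a", "b"), population = "p",
                          freq_pct = c(100, 100))
  expect_equal(summarize_population(all_fixed)$nearly_fixed_frac, 1)
})

test_that("feature contrasts use exact Wilcoxon with BH adjustment", {
  feats <- data.frame(gene_id = c("a", "b", "c", "d"),
                      pi = c(1, 2, 3, 4),
                      cds_length = c(10, 10, 10, 10),
                      gc_content = c(0.3, 0.4, 0.35, 0.45))
  out <- compare_features(feats, low_set = c("a", "b"),
                          high_set = c("c", "d"))
  expect_equal(out$p[out$feature == "pi"], 1 / 3, tolerance = 1e-12)
  # constant feature in both groups: p = 1, zero direction
  expect_equal(out$p[out$feature == "cds_length"], 1)
  expect_equal(out$direction[out$feature == "cds_length"], 0)
  expect_equal(out$p_adj, pmin(1, stats::p.adjust(out$p, "BH")))

  # identical groups give p = 1 for every feature
  same <- compare_features(feats, low_set = c("a", "b"),
                           high_set = c("a", "b"))
  expect_true(all(same$p == 1))

  feats$methylation <- c(NA, NA, 0.1, 0.2)
  expect_warning(compare_features(feats, c("a", "b"), c("c", "d")),
                 "methylation")
})

test_that("GC content excludes N from the denominator", {
  expect_equal(compute_gc(c("ATGC", "AAAA")), c(0.5, 0))
  expect_equal(compute_gc("ANGC"), 2 / 3)
  expect_warning(gc <- compute_gc("NNN"), "NA")
  expect_true(is.na(gc))
})

test_that("CDS length sums the model intervals", {
  m <- gene_model("g", "chr1", "+",
                  data.frame(start = c(0L, 10L), end = c(6L, 16L)))
  expect_equal(compute_cds_length(m), 12L)
})

test_that("evidence tiers follow the strict TPM threshold", {
  ev <- data.frame(translated = c(FALSE, FALSE, TRUE, TRUE, FALSE),
                   polya = c(FALSE, FALSE, TRUE, FALSE, TRUE),
                   max_tpm = c(0.9, 1.0, 0.1, 5, 2))
  expect_equal(classify_evidence(ev), c("TN", "TN", "TLplus", "TLminus", "TC"))
  # per-tissue columns: expression = any tissue TPM > 1
  ev2 <- data.frame(translated = FALSE, polya = FALSE,
                    tpm_root = 0.2, tpm_flower = 1.4)
  expect_equal(classify_evidence(ev2), "TC")
})
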