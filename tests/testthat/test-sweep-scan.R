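block_hap <- function(cols, positions, ...) {
  haplotype_matrix(do.call(cbind, cols), positions, ...)
}

test_that("r-squared matches complete association, independence and the table oracle", {
  h <- block_hap(list(c(1, 1, 0, 0), c(1, 1, 0, 0)), c(10, 20))
  expect_equal(r_squared(h, 1, 2), 1)
  h2 <- block_hap(list(c(1, 1, 0, 0), c(1, 0, 1, 0)), c(10, 20))
  expect_equal(r_squared(h2, 1, 2), 0)
  h3 <- block_hap(list(c(1, 1, 1, 0), c(1, 1, 0, 0)), c(10, 20))
  expect_equal(r_squared(h3, 1, 2),
               oracle_r2_table(h3$haplotypes[, 1], h3$haplotypes[, 2]))
  # monomorphic in the pairwise-complete subset: undefined
  m <- cbind(c(1, 1, 0, NA), c(0, 0, 0, 1))
  h4 <- haplotype_matrix(m, c(10, 20), drop_monomorphic = FALSE)
  expect_true(is.na(r_squared(h4, 1, 2)))
})

test_that("omega is 1 for uniform LD and capped for zero cross-flank LD", {
  # identical columns everywhere: every pairwise r2 is 1, omega = 1
  col <- c(rep(1, 5), rep(0, 5))
  h <- block_hap(rep(list(col), 12),
                 c(1000, 3000, 5000, 7000, 8000, 9000,
                   11000, 12000, 13000, 15000, 17000, 19000))
  o <- omega_at(h, 10000, minwin = 10000, maxwin = 10000)
  expect_equal(o$omega, 1)

  # perfect within-flank LD, exactly zero cross-flank LD: cap sentinel
  left <- c(1, 1, 0, 0)
  right <- c(1, 0, 1, 0)  # orthogonal: D = 0
  h2 <- block_hap(list(left, left, right, right), c(6000, 8000, 12000, 14000))
  o2 <- omega_at(h2, 10000, minwin = 10000, maxwin = 10000)
  expect_equal(o2$omega, 1e6)
})

test_that("omega equals exhaustive pair summation on a 6-site toy", {
  set.seed(77)
  m <- matrix(rbinom(20 * 6, 1, 0.5), nrow = 20)
  h <- haplotype_matrix(m, c(2000, 5000, 9000, 11000, 15000, 18000))
  stopifnot(ncol(h$haplotypes) == 6L)
  o <- omega_at(h, 10000, minwin = 10000, maxwin = 10000)
  L <- which(h$positions < 10000)
  R <- which(h$positions >= 10000)
  sum_within <- 0; n_within <- 0
  for (idx in list(L, R))
    for (i in idx) for (j in idx) if (i < j) {
      sum_within <- sum_within + oracle_r2_table(m[, i], m[, j])
      n_within <- n_within + 1
    }
  sum_cross <- 0
  for (i in L) for (j in R)
    sum_cross <- sum_cross + oracle_r2_table(m[, i], m[, j])
  expected <- (sum_within / n_within) / (sum_cross / (length(L) * length(R)))
  expect_equal(o$omega, expected, tolerance = 1e-12)
  expect_equal(o$n_left, length(L))
  expect_equal(o$n_right, length(R))
})

test_that("omega is invariant to relabeling alleles at any site", {
  set.seed(13)
  for (rep in 1:20) {
    m <- matrix(rbinom(16 * 8, 1, 0.5), nrow = 16)
    h <- haplotype_matrix(m, sort(sample(1000:19000, 8)))
    if (ncol(h$haplotypes) < 4) next
    flip <- sample(ncol(h$haplotypes), 2)
    m2 <- h$haplotypes
    m2[, flip] <- 1 - m2[, flip]
    h2 <- haplotype_matrix(m2, h$positions)
    expect_equal(omega_at(h, 10000)$omega, omega_at(h2, 10000)$omega)
  }
})

test_that("the scan grid covers interior multiples of the step", {
  set.seed(2)
  m <- matrix(rbinom(30 * 40, 1, 0.4), nrow = 30)
  h <- haplotype_matrix(m, sort(sample(1:99999, 40)))
  res <- scan_omega(h)
  expect_equal(res$center, seq(10000, 90000, by = 10000))
  expect_error(scan_omega(block_hap(list(c(0, 1), c(1, 0)), c(100, 200))),
               "shorter than")
})

test_that("selected-region calling takes the top fraction and merges neighbours", {
  res <- data.frame(chrom = "chr1", population = "p",
                    center = seq(10000, 1000000, by = 10000),
                    omega = seq_len(100))
  reg <- call_selected(res, top_frac = 0.05, merge = FALSE)
  expect_equal(nrow(reg), 5L)  # distinct values: exactly 5 of 100
  merged <- call_selected(res, top_frac = 0.05)
  expect_equal(nrow(merged), 1L)  # the top 5 centers are adjacent
  expect_equal(merged$start, 955000)
  expect_equal(merged$end, 1005000)
  # ties straddling the cut are all included
  res$omega <- c(rep(1, 90), rep(9, 10))
  regt <- call_selected(res, top_frac = 0.05, merge = FALSE)
  expect_equal(nrow(regt), 10L)
  resna <- data.frame(chrom = "chr1", population = "p",
                      center = c(10000, 20000), omega = c(NA, NA))
  expect_warning(empty <- call_selected(resna), "no finite")
  expect_equal(nrow(empty), 0L)
})

test_that("gene overlap uses half-open intervals and counts sharing", {
  regions <- data.frame(chrom = "chr1",
                        start = c(5000, 25000, 5000),
                        end = c(15000, 35000, 15000),
                        population = c("p1", "p1", "p2"))
  genes <- data.frame(chrom = "chr1",
                      start = c(7000, 15000, 40000),
                      end = c(8000, 16000, 41000),
                      name = c("inside", "abutting", "outside"))
  ov <- overlap_genes(regions, genes)
  expect_equal(ov$per_gene$n_populations, c(2L, 0L, 0L))
  expect_equal(ov$n_selected_union, 1L)
  expect_equal(ov$pct_union, 100 / 3)
  expect_equal(ov$shared_by_k$n_genes[ov$shared_by_k$k == 2], 1L)
})

test_that("nucleotide diversity matches the pairwise oracle", {
  h <- block_hap(list(c(0, 0), c(0, 0)), c(1, 2), drop_monomorphic = FALSE)
  expect_equal(compute_pi(h), 0)
  # 2 haplotypes differing at 1 of 10 sites
  m <- matrix(0, nrow = 2, ncol = 1)
  m[1, 1] <- 1
  h2 <- haplotype_matrix(m, 5, drop_monomorphic = FALSE)
  expect_equal(compute_pi(h2, n_sites = 10), 0.1)
  expect_error(compute_pi(haplotype_matrix(matrix(1, 1, 1), 1,
                                           drop_monomorphic = FALSE)),
               "two haplotypes")
})
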