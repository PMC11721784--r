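# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# ORF status via Biostrings translation of the trimmed sequence
oracle_classify <- function(seq, ref_protein_len) {
  if (nchar(seq) < 3L || substr(seq, 1L, 3L) != "ATG") return("START_LOST")
  k <- nchar(seq) %/% 3L
  aa <- strsplit(as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, 3L * k))))),
    "")[[1]]
  stops <- which(aa == "*")
  if (length(stops) == 0L) return("STOP_LOST")
  if (stops[1L] - 1L < ref_protein_len) "PREMATURE_STOP" else "FUNCTIONAL"
}

# random well-formed reference CDS: ATG + non-stop codons + TAA
random_cds <- function(n_codons) {
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(non_stop, n_codons - 1L, replace = TRUE), "TAA"),
        collapse = "")
}

# random SNP/insertion/deletion edits on a sequence, non-overlapping
random_edits <- function(seq, n_edits) {
  len <- nchar(seq)
  pos <- sort(sample(0:(len - 3L), n_edits))
  if (n_edits > 1L && any(diff(pos) < 3L)) return(NULL)  # caller retries
  rows <- lapply(pos, function(p) {
    type <- sample(c("snp", "del", "ins"), 1L)
    refb <- substr(seq, p + 1L, p + 1L)
    if (type == "snp") {
      data.frame(pos = p, ref = refb,
                 alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1L))
    } else if (type == "del") {
      w <- sample(1:2, 1L)
      data.frame(pos = p, ref = substr(seq, p + 1L, p + 1L + w), alt = refb)
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L),
                          replace = TRUE), collapse = "")
      data.frame(pos = p, ref = refb, alt = paste0(refb, ins))
    }
  })
  do.call(rbind, rows)
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all group
# assignments (no ties assumed)
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  w_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - k * (k + 1) / 2
  }
  obs <- w_of(seq_len(k))
  all_w <- apply(utils::combn(n, k), 2, w_of)
  p_lo <- mean(all_w <= obs)
  p_hi <- mean(all_w >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# r-squared from the 2x2 haplotype count table
oracle_r2_table <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  p <- (n11 + n10) / n; q <- (n11 + n01) / n
  if (p %in% c(0, 1) || q %in% c(0, 1)) return(NA_real_)
  D <- n11 / n - p * q
  D^2 / (p * (1 - p) * q * (1 - q))
}

# nucleotide diversity as the mean over all haplotype pairs of per-site
# Hamming distance (complete data)
oracle_pi_pairs <- function(m, n_sites = ncol(m)) {
  n <- nrow(m)
  if (ncol(m) == 0L) return(0)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ]) / n_sites
    np <- np + 1
  }
  tot / np
}

# minimum-change ancestral state at the root by exhaustive enumeration over
# all internal-node assignments of a rooted tree given as nested lists of
# leaf states (single column)
oracle_parsimony_states <- function(tree, states = c("A", "C", "G", "T", "-")) {
  # tree: leaf state (length-1 character) or list of child trees
  score <- function(node, state) {
    if (!is.list(node)) return(if (node == state) 0 else 1)
    sum(vapply(node, function(ch)
      min(vapply(states, function(s)
        score(ch, s) + (s != state), numeric(1))), numeric(1)))
  }
  root_scores <- vapply(states, function(s) score(tree, s), numeric(1))
  states[root_scores == min(root_scores)]
}
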