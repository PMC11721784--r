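# Linkage-disequilibrium contrast (omega statistic) sweep scan on haplotype
# matrices, selected-region calling, gene overlap, and nucleotide diversity.

OMEGA_CAP <- 1e6

#' Construct a haplotype matrix object
#'
#' @param haplotypes integer/numeric matrix (haplotypes x sites) of 0/1
#'   allele states; `NA` for missing.
#' @param positions strictly increasing bp coordinates, one per site.
#' @param chrom chromosome name.
#' @param population population label.
#' @param drop_monomorphic drop sites with no variation among non-missing
#'   haplotypes (default TRUE; the object invariant requires polymorphic
#'   columns).
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(haplotypes, positions, chrom = "chr1",
                             population = "pop1", drop_monomorphic = TRUE) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(ncol(haplotypes) == length(positions))
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (!all(haplotypes %in% c(0, 1, NA)))
    stop("haplotype states must be 0, 1 or NA")
  if (drop_monomorphic) {
    poly <- apply(haplotypes, 2, function(v) {
      v <- v[!is.na(v)]
      length(v) >= 2L && any(v != v[1])
    })
    haplotypes <- haplotypes[, poly, drop = FALSE]
    positions <- positions[poly]
  }
  structure(list(haplotypes = haplotypes, positions = positions,
                 chrom = chrom, population = population),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix: ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " polymorphic sites on ", x$chrom,
      " (", x$population, ")\n", sep = "")
  invisible(x)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' `r^2 = D^2 / (p (1 - p) q (1 - q))` with `D = p_AB - p q`, computed over
#' the haplotypes non-missing at both sites. Returns `NA` when either site is
#' monomorphic in the pairwise-complete subset.
#'
#' @param hap a [haplotype_matrix()] or plain 0/1 matrix.
#' @param i,j site (column) indices.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
r_squared <- function(hap, i, j) {
  m <- if (inherits(hap, "haplotype_matrix")) hap$haplotypes else as.matrix(hap)
  x <- m[, i]
  y <- m[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  p <- mean(x)
  q <- mean(y)
  if (p %in% c(0, 1) || q %in% c(0, 1)) return(NA_real_)
  d <- mean(x * y) - p * q
  d^2 / (p * (1 - p) * q * (1 - q))
}

# full site-by-site r^2 matrix (squared Pearson correlation of allele
# states, identical to the frequency formula; pairwise-complete)
r2_matrix <- function(hap) {
  suppressWarnings(stats::cor(hap$haplotypes, use = "pairwise.complete.obs")^2)
}

# omega for a fixed left/right site index split, given the r2 matrix
omega_of_split <- function(r2, left, right, cap = OMEGA_CAP) {
  l <- length(left)
  r <- length(right)
  if (l < 2L || r < 2L) return(NA_real_)
  sum_pairs <- function(idx) {
    s <- r2[idx, idx, drop = FALSE]
    vals <- s[upper.tri(s)]
    c(sum(vals, na.rm = TRUE), sum(!is.na(vals)))
  }
  wl <- sum_pairs(left)
  wr <- sum_pairs(right)
  cr <- r2[left, right, drop = FALSE]
  cross_sum <- sum(cr, na.rm = TRUE)
  cross_n <- sum(!is.na(cr))
  within_n <- wl[2] + wr[2]
  if (within_n == 0L || cross_n == 0L) return(NA_real_)
  num <- (wl[1] + wr[1]) / within_n
  den <- cross_sum / cross_n
  if (den == 0) {
    if (num > 0) return(cap)
    return(0)
  }
  num / den
}

#' Omega statistic at one grid center
#'
#' For each of `n_windows` symmetric window extents on a geometric ladder
#' from `minwin` to `maxwin`, the sites within the window are split at the
#' center into a left and a right flank and
#' `omega = [ (C(l,2)+C(r,2))^-1 (sum r^2 within L + sum r^2 within R) ] /
#' [ (l r)^-1 sum r^2 between L and R ]` is evaluated; the maximum over the
#' ladder is returned with its window extent. When the cross-flank sum is
#' exactly zero but the within-flank sum is positive, the documented cap
#' sentinel (`1e6`) is emitted to keep quantile machinery finite.
#'
#' @param hap a [haplotype_matrix()].
#' @param center grid center in bp.
#' @param minwin,maxwin smallest/largest one-sided window extent in bp.
#' @param n_windows number of ladder extents.
#' @param r2 optional precomputed r-squared matrix (internal use).
#' @param cap sentinel value for a zero cross-flank LD sum.
#' @return one-row data.frame: `chrom`, `population`, `center`, `omega`,
#'   `best_window`, `n_left`, `n_right` (`omega = NA` when either flank has
#'   fewer than two usable sites at every ladder extent).
#' @export
omega_at <- function(hap, center, minwin = 10000, maxwin = 100000,
                     n_windows = 10L, r2 = NULL, cap = OMEGA_CAP) {
  stopifnot(inherits(hap, "haplotype_matrix"), minwin > 0, maxwin >= minwin)
  if (is.null(r2)) r2 <- r2_matrix(hap)
  pos <- hap$positions
  ladder <- unique(round(exp(seq(log(minwin), log(maxwin), length.out = n_windows))))
  best <- c(omega = NA_real_, win = NA_real_, nl = NA_real_, nr = NA_real_)
  for (w in ladder) {
    left <- which(pos >= center - w & pos < center)
    right <- which(pos >= center & pos < center + w)
    om <- omega_of_split(r2, left, right, cap = cap)
    if (!is.na(om) && (is.na(best["omega"]) || om > best["omega"]))
      best <- c(omega = om, win = w, nl = length(left), nr = length(right))
  }
  data.frame(chrom = hap$chrom, population = hap$population, center = center,
             omega = unname(best["omega"]), best_window = unname(best["win"]),
             n_left = unname(best["nl"]), n_right = unname(best["nr"]),
             stringsAsFactors = FALSE)
}

#' Omega scan along a chromosome
#'
#' Evaluates [omega_at()] on a regular grid: every multiple of `grid_step`
#' strictly between the first and last polymorphic site.
#'
#' @param hap a [haplotype_matrix()].
#' @param grid_step grid interval in bp.
#' @param minwin,maxwin window ladder bounds in bp.
#' @param n_windows number of ladder extents.
#' @param cap sentinel value for a zero cross-flank LD sum.
#' @return data.frame of per-center results, one row per grid center.
#' @export
scan_omega <- function(hap, grid_step = 10000, minwin = 10000,
                       maxwin = 100000, n_windows = 10L, cap = OMEGA_CAP) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  pos <- hap$positions
  if (length(pos) == 0L || diff(range(pos)) < grid_step)
    stop("chromosome span is shorter than the grid step")
  k <- seq.int(floor(min(pos) / grid_step) + 1L, ceiling(max(pos) / grid_step) - 1L)
  centers <- k[k * grid_step > min(pos) & k * grid_step < max(pos)] * grid_step
  r2 <- r2_matrix(hap)
  out <- lapply(centers, function(ct)
    omega_at(hap, ct, minwin = minwin, maxwin = maxwin,
             n_windows = n_windows, r2 = r2, cap = cap))
  do.call(rbind, out)
}

#' Call selected regions from an omega scan
#'
#' The threshold is the `(1 - top_frac)` quantile of the finite omega values
#' of each population, genome-wide; grid points with `omega >= threshold`
#' (ties at the cut are included) become regions
#' `[center - step/2, center + step/2)` and adjacent regions are merged
#' unless `merge = FALSE`.
#'
#' @param results scan results from [scan_omega()] (several populations may
#'   be row-bound).
#' @param top_frac upper tail fraction called selected.
#' @param grid_step grid interval in bp; inferred from the centers when NULL.
#' @param merge merge book-ended regions (default TRUE).
#' @return data.frame of regions: `chrom`, `start`, `end` (0-based
#'   half-open), `population`. Empty (with a warning) when the scan has no
#'   finite values.
#' @export
call_selected <- function(results, top_frac = 0.05, grid_step = NULL,
                          merge = TRUE) {
  stopifnot(all(c("chrom", "population", "center", "omega") %in% names(results)))
  out <- list()
  for (popn in unique(results$population)) {
    res <- results[results$population == popn, , drop = FALSE]
    fin <- res[!is.na(res$omega), , drop = FALSE]
    if (nrow(fin) == 0L) {
      warning("population '", popn, "': no finite omega values; no regions called")
      next
    }
    if (nrow(fin) < 20L)
      warning("population '", popn, "': fewer than 20 finite omega values; ",
              "the top-", top_frac * 100, "% cut is coarse")
    step <- grid_step
    if (is.null(step)) {
      step <- if (nrow(res) > 1L) min(diff(sort(unique(res$center)))) else 10000
    }
    thr <- stats::quantile(fin$omega, 1 - top_frac, names = FALSE)
    sel <- fin[fin$omega >= thr, , drop = FALSE]
    sel <- sel[order(sel$chrom, sel$center), , drop = FALSE]
    reg <- data.frame(chrom = sel$chrom,
                      start = sel$center - step / 2,
                      end = sel$center + step / 2,
                      population = popn, stringsAsFactors = FALSE)
    if (merge && nrow(reg) > 1L) {
      keep <- list(reg[1, ])
      for (i in 2:nrow(reg)) {
        last <- keep[[length(keep)]]
        if (reg$chrom[i] == last$chrom && reg$start[i] <= last$end) {
          keep[[length(keep)]]$end <- max(last$end, reg$end[i])
        } else {
          keep[[length(keep) + 1L]] <- reg[i, ]
        }
      }
      reg <- do.call(rbind, keep)
    }
    out[[popn]] <- reg
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), population = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap genes with selected regions
#'
#' A gene is selected in a population iff its interval overlaps any selected
#' region of that population by at least 1 bp (both sides 0-based
#' half-open, so a gene abutting a region end does not overlap).
#'
#' @param regions selected regions from [call_selected()].
#' @param genes data.frame of gene intervals (`chrom`, `start`, `end`,
#'   `name`; 0-based half-open) — the full gene catalog.
#' @return list with `per_gene` (gene x population selection flags, one row
#'   per gene: `populations` is a comma-joined list, `n_populations` the
#'   count), `per_population` (selected-gene counts), `n_selected_union`,
#'   `pct_union` (percentage of the catalog selected in at least one
#'   population), and `shared_by_k` (number of genes selected in exactly k
#'   populations).
#' @export
overlap_genes <- function(regions, genes) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  pops <- unique(regions$population)
  hit <- matrix(FALSE, nrow = nrow(genes), ncol = length(pops),
                dimnames = list(genes$name, pops))
  for (p in pops) {
    reg <- regions[regions$population == p, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      hit[i, p] <- any(reg$chrom == genes$chrom[i] &
                         reg$start < genes$end[i] &
                         genes$start[i] < reg$end)
    }
  }
  n_pop <- rowSums(hit)
  per_gene <- data.frame(
    gene_id = genes$name,
    populations = apply(hit, 1, function(v) paste(pops[v], collapse = ",")),
    n_populations = n_pop, row.names = NULL, stringsAsFactors = FALSE)
  per_population <- data.frame(population = pops, n_selected = colSums(hit),
                               row.names = NULL, stringsAsFactors = FALSE)
  shared <- table(factor(n_pop[n_pop > 0], levels = seq_len(max(1, length(pops)))))
  list(per_gene = per_gene, per_population = per_population,
       n_selected_union = sum(n_pop > 0),
       pct_union = 100 * sum(n_pop > 0) / nrow(genes),
       shared_by_k = data.frame(k = as.integer(names(shared)),
                                n_genes = as.integer(shared)))
}

#' Nucleotide diversity of a haplotype matrix
#'
#' Average pairwise difference per site:
#' `pi = sum_sites 2 p (1 - p) n / (n - 1) / L` with the per-site
#' non-missing haplotype count `n`. Equals the mean per-site Hamming
#' distance over all haplotype pairs when no data are missing.
#'
#' @param hap a [haplotype_matrix()].
#' @param n_sites number of sites `L` to average over; defaults to the
#'   number of (polymorphic) columns in the matrix. Pass the full sequence
#'   length to express diversity per surveyed bp.
#' @return numeric nucleotide diversity.
#' @export
compute_pi <- function(hap, n_sites = NULL) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  m <- hap$haplotypes
  if (nrow(m) < 2L) stop("need at least two haplotypes")
  if (is.null(n_sites)) n_sites <- ncol(m)
  if (ncol(m) == 0L) return(0)
  n <- colSums(!is.na(m))
  p <- colMeans(m, na.rm = TRUE)
  ok <- n >= 2L
  sum(2 * p[ok] * (1 - p[ok]) * n[ok] / (n[ok] - 1)) / n_sites
}
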