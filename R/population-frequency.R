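# Per-population presence frequencies, spectrum bins, frequency-class
# summaries and feature contrasts.

#' Compute per-gene, per-population presence frequencies
#'
#' `UNRESOLVED` calls are excluded from the denominator. Populations with no
#' called accession for a gene are omitted with a warning.
#'
#' @param calls data.frame of presence calls as returned by
#'   [call_presence()] (possibly for several genes row-bound together).
#' @param pop_map data.frame mapping `accession` to `population`.
#' @return data.frame with columns `gene_id`, `population`, `n_called`,
#'   `n_present`, `freq_pct` (0-100, unrounded).
#' @export
compute_frequency <- function(calls, pop_map) {
  stopifnot(all(c("accession", "gene_id", "status", "present") %in% names(calls)),
            all(c("accession", "population") %in% names(pop_map)))
  unknown <- setdiff(calls$accession, pop_map$accession)
  if (length(unknown))
    stop("accession(s) missing from the population map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  pop <- pop_map$population[match(calls$accession, pop_map$accession)]
  called <- calls$status != "UNRESOLVED"
  grp <- interaction(calls$gene_id, pop, drop = FALSE, sep = "\r")
  n_called <- tapply(called, grp, sum)
  n_present <- tapply(calls$present & called, grp, sum)
  keys <- do.call(rbind, strsplit(names(n_called), "\r", fixed = TRUE))
  out <- data.frame(gene_id = keys[, 1], population = keys[, 2],
                    n_called = as.integer(n_called),
                    n_present = as.integer(n_present),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$n_called), , drop = FALSE]
  empty <- out$n_called == 0L
  if (any(empty)) {
    warning("omitting ", sum(empty),
            " gene x population record(s) with zero called accessions")
    out <- out[!empty, , drop = FALSE]
  }
  out$freq_pct <- 100 * out$n_present / out$n_called
  rownames(out) <- NULL
  out[order(out$gene_id, out$population), , drop = FALSE]
}

#' Bin a presence frequency into a spectrum label
#'
#' Exact 0 maps to `"0"` and exact 100 to `"100"`; anything in between falls
#' into decade bins labelled by their midpoints: `"5"` for (0, 10), `"15"`
#' for \[10, 20), and so on up to `"95"` for \[90, 100).
#'
#' @param freq_pct numeric vector of frequencies in \[0, 100\].
#' @return character vector of bin labels.
#' @export
bin_frequency <- function(freq_pct) {
  if (any(is.na(freq_pct)) || any(freq_pct < 0) || any(freq_pct > 100))
    stop("frequencies must lie in [0, 100]")
  out <- as.character(10L * pmin(floor(freq_pct / 10), 9) + 5L)
  out[freq_pct == 0] <- "0"
  out[freq_pct == 100] <- "100"
  out
}

#' Summarize nearly-fixed and low-frequency fractions per population
#'
#' @param records frequency records from [compute_frequency()].
#' @param nearly_fixed_threshold percent threshold for the nearly-fixed class.
#' @param low_threshold percent threshold for the low-frequency class.
#' @param strict when `TRUE` (default) the nearly-fixed rule is a strict
#'   `freq > threshold`; when `FALSE` it is `freq >= threshold`. The
#'   low-frequency rule is always a strict `freq < low_threshold`.
#' @return data.frame with one row per population: `population`, `n_genes`,
#'   `nearly_fixed_frac`, `low_frac`.
#' @export
summarize_population <- function(records, nearly_fixed_threshold = 90,
                                 low_threshold = 10, strict = TRUE) {
  stopifnot(nrow(records) >= 1L)
  f <- function(df) {
    nf <- if (strict) df$freq_pct > nearly_fixed_threshold
          else df$freq_pct >= nearly_fixed_threshold
    data.frame(population = df$population[1], n_genes = nrow(df),
               nearly_fixed_frac = mean(nf),
               low_frac = mean(df$freq_pct < low_threshold),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(records, records$population), f))
  rownames(out) <- NULL
  out
}

#' Contrast gene features between two frequency classes
#'
#' Two-sided Wilcoxon rank-sum test per feature (exact when sample sizes
#' allow and no ties are present, as in [stats::wilcox.test()]), with
#' Benjamini-Hochberg adjustment across the feature list.
#'
#' @param features data.frame with a `gene_id` column plus numeric feature
#'   columns (e.g. `pi`, `cds_length`, `gc_content`, ...).
#' @param low_set,high_set character vectors of gene ids in the two classes.
#' @return data.frame with one row per feature: group sizes, group medians,
#'   `median_diff` (high minus low), `direction` (its sign), `p`, `p_adj`.
#'   Features entirely missing in one class are skipped with a warning.
#' @export
compare_features <- function(features, low_set, high_set) {
  stopifnot("gene_id" %in% names(features),
            length(low_set) > 0L, length(high_set) > 0L)
  feat_cols <- setdiff(names(features), "gene_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  lo <- features[features$gene_id %in% low_set, , drop = FALSE]
  hi <- features[features$gene_id %in% high_set, , drop = FALSE]
  rows <- list()
  for (fc in feat_cols) {
    x <- lo[[fc]][!is.na(lo[[fc]])]
    y <- hi[[fc]][!is.na(hi[[fc]])]
    if (length(x) == 0L || length(y) == 0L) {
      warning("feature '", fc, "' entirely missing in one class; skipped")
      next
    }
    p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
    if (is.nan(p)) p <- 1  # both groups constant and identical
    md <- stats::median(y) - stats::median(x)
    rows[[fc]] <- data.frame(feature = fc, n_low = length(x), n_high = length(y),
                             median_low = stats::median(x), median_high = stats::median(y),
                             median_diff = md, direction = sign(md), p = p,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable features")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' GC content of sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the denominator.
#' All-N sequences yield `NA` with a warning.
#'
#' @param seq character vector of DNA sequences.
#' @return numeric vector of fractions in \[0, 1\] (or `NA`).
#' @export
compute_gc <- function(seq) {
  stopifnot(all(nchar(seq) > 0L))
  count <- function(s, chars) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% chars)
  }
  gc <- vapply(seq, count, numeric(1), chars = c("G", "C"))
  acgt <- vapply(seq, count, numeric(1), chars = c("A", "C", "G", "T"))
  if (any(acgt == 0L)) warning("sequence(s) with no unambiguous base: GC content is NA")
  unname(ifelse(acgt == 0L, NA_real_, gc / acgt))
}

#' Coding length of a gene model in bp
#'
#' @param model a [gene_model()].
#' @return integer CDS length.
#' @export
compute_cds_length <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  as.integer(sum(model$cds$end - model$cds$start))
}

#' Classify transcription/translation evidence tiers
#'
#' `TLplus` for translated genes with a poly(A) tail, `TLminus` for translated
#' genes without one, `TC` for untranslated genes expressed (TPM strictly
#' greater than the threshold) in at least one tissue, `TN` otherwise.
#'
#' @param evidence data.frame with logical columns `translated` and `polya`
#'   plus either a numeric `max_tpm` column or per-tissue columns prefixed
#'   `tpm_`.
#' @param tpm_threshold expression threshold (strict `>`).
#' @return character vector of tiers, one per row.
#' @export
classify_evidence <- function(evidence, tpm_threshold = 1) {
  stopifnot(all(c("translated", "polya") %in% names(evidence)))
  if ("max_tpm" %in% names(evidence)) {
    max_tpm <- evidence$max_tpm
  } else {
    tpm_cols <- grep("^tpm_", names(evidence), value = TRUE)
    if (length(tpm_cols) == 0L) stop("no max_tpm or tpm_* columns in evidence table")
    max_tpm <- do.call(pmax, c(evidence[tpm_cols], na.rm = TRUE))
  }
  ifelse(evidence$translated & evidence$polya, "TLplus",
    ifelse(evidence$translated, "TLminus",
      ifelse(max_tpm > tpm_threshold, "TC", "TN")))
}
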