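# Presence calling: apply an accession's variants to the reference CDS and
# classify the resulting open reading frame.

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds data.frame of CDS intervals with columns `start`, `end`
#'   (0-based half-open genomic coordinates), non-overlapping.
#' @return an object of class `gene_model`. A warning is raised (and a
#'   `malformed` flag set) when the concatenated CDS length is not a multiple
#'   of three.
#' @export
gene_model <- function(gene_id, chrom, strand = c("+", "-"), cds) {
  strand <- match.arg(strand)
  stopifnot(is.data.frame(cds), all(c("start", "end") %in% names(cds)))
  if (any(cds$start >= cds$end)) stop("CDS interval with start >= end in gene ", gene_id)
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  if (nrow(cds) > 1L && any(cds$start[-1L] < cds$end[-nrow(cds)]))
    stop("overlapping CDS intervals in gene ", gene_id)
  malformed <- FALSE
  if (sum(cds$end - cds$start) %% 3L != 0L) {
    warning("CDS length of gene ", gene_id, " is not a multiple of 3")
    malformed <- TRUE
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, malformed = malformed),
            class = "gene_model")
}

#' Build gene models from an interval table
#'
#' @param intervals data.frame as returned by [read_intervals()] (0-based
#'   half-open), one group of CDS rows per gene `name`.
#' @return named list of [gene_model()] objects.
#' @export
gene_models_from_intervals <- function(intervals) {
  out <- lapply(split(intervals, intervals$name), function(df) {
    strand <- unique(df$strand)
    if (length(strand) != 1L) stop("inconsistent strand for gene ", df$name[1])
    if (strand == ".") strand <- "+"
    gene_model(df$name[1], unique(df$chrom), strand, df[, c("start", "end")])
  })
  out[unique(intervals$name)]
}

#' Extract the coding sequence of a gene model from a genome
#'
#' Concatenates the CDS intervals in coding orientation (reverse complement
#' for minus-strand genes). Warns when the reference CDS does not start with
#' ATG or end with a stop codon.
#'
#' @param genome named character vector of chromosome sequences.
#' @param model a [gene_model()].
#' @return the CDS as a single uppercase string.
#' @export
extract_cds <- function(genome, model) {
  stopifnot(inherits(model, "gene_model"))
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " not present in the genome")
  chrom_seq <- genome[[model$chrom]]
  if (any(model$cds$end > nchar(chrom_seq)))
    stop("CDS interval out of bounds on ", model$chrom, " for gene ", model$gene_id)
  pieces <- substring(chrom_seq, model$cds$start + 1L, model$cds$end)
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  if (nchar(cds) >= 3L && substr(cds, 1L, 3L) != "ATG")
    warning("reference CDS of ", model$gene_id, " does not start with ATG")
  if (nchar(cds) %% 3L == 0L &&
      !substr(cds, nchar(cds) - 2L, nchar(cds)) %in% STOP_CODONS)
    warning("reference CDS of ", model$gene_id, " does not end with a stop codon")
  cds
}

#' Apply variants to a coding sequence
#'
#' Each variant `(pos, ref, alt)` replaces the half-open slice
#' `[pos, pos + nchar(ref))` of the sequence with `alt` (VCF-style
#' left-anchored indels, `pos` 0-based within the sequence). Variants are
#' applied in descending coordinate order so that earlier edits never shift
#' later coordinates; any application order therefore yields the same result.
#'
#' @param cds sequence string.
#' @param variants data.frame with columns `pos` (0-based), `ref`, `alt`.
#' @return the edited sequence string.
#' @export
apply_variants <- function(cds, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(cds)
  stopifnot(all(c("pos", "ref", "alt") %in% names(variants)))
  v <- variants[order(variants$pos, decreasing = TRUE), , drop = FALSE]
  ends <- v$pos + nchar(v$ref)  # half-open ends, descending pos
  if (nrow(v) > 1L && any(ends[-1L] > v$pos[-nrow(v)]))
    stop("overlapping variants")
  for (i in seq_len(nrow(v))) {
    pos <- v$pos[i]
    ref <- v$ref[i]
    have <- substr(cds, pos + 1L, pos + nchar(ref))
    if (have != ref)
      stop("reference mismatch at position ", pos, ": expected '", ref,
           "', found '", have, "'")
    cds <- paste0(substr(cds, 1L, pos), v$alt[i],
                  substr(cds, pos + nchar(ref) + 1L, nchar(cds)))
  }
  cds
}

#' Classify an edited open reading frame
#'
#' Codon-by-codon classification against the reference frame:
#' `START_LOST` when the sequence does not begin with ATG; `PREMATURE_STOP`
#' when the first in-frame stop codon falls before the reference terminal
#' codon position (any truncation counts, with no near-terminal exemption);
#' `STOP_LOST` when no stop codon is reached by the end of the sequence;
#' `FUNCTIONAL` otherwise. Frameshifting indels need no special casing: their
#' translated consequence surfaces as one of the above.
#'
#' @param seq edited CDS string.
#' @param reference_protein_len reference protein length in amino acids
#'   (i.e. the reference terminal stop sits at 0-based codon index
#'   `reference_protein_len`).
#' @return one of `"FUNCTIONAL"`, `"START_LOST"`, `"PREMATURE_STOP"`,
#'   `"STOP_LOST"`.
#' @export
classify_orf <- function(seq, reference_protein_len) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  if (nchar(seq) < 3L || substr(seq, 1L, 3L) != "ATG") return("START_LOST")
  codons <- split_codons(seq)
  stop_idx <- which(codons %in% STOP_CODONS)
  if (length(stop_idx) == 0L) return("STOP_LOST")
  first <- stop_idx[1L] - 1L  # 0-based codon index of first stop
  if (first < reference_protein_len) "PREMATURE_STOP" else "FUNCTIONAL"
}

#' Call per-accession presence of a gene
#'
#' For each accession, the homozygous-alternate variants falling inside the
#' gene's CDS footprint are applied to the reference CDS and the result is
#' classified with [classify_orf()]. The gene is present iff the ORF is
#' `FUNCTIONAL`. Under the `"strict"` policy any heterozygous or missing call
#' at a gene variant leaves the accession `UNRESOLVED` (excluded from
#' downstream frequency denominators); under `"any-functional"` such sites
#' are ignored, since the reference-allele haplotype remains intact.
#'
#' @param model a [gene_model()].
#' @param genome named character vector of chromosome sequences.
#' @param genotypes a [genotype_matrix()].
#' @param policy `"strict"` or `"any-functional"`.
#' @return data.frame with one row per accession: `accession`, `gene_id`,
#'   `status`, `present`, `events` (semicolon-joined variant descriptions).
#' @export
call_presence <- function(model, genome, genotypes, policy = c("strict", "any-functional")) {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "gene_model"), inherits(genotypes, "genotype_matrix"))
  ref_cds <- extract_cds(genome, model)
  ref_protein_len <- nchar(ref_cds) %/% 3L - 1L

  # variants inside the CDS footprint, with gene-local 0-based coordinates on
  # the plus strand (minus-strand genes are edited on the plus-strand slice
  # and reverse-complemented afterwards, so VCF alleles apply directly)
  v <- genotypes$variants
  pos0 <- v$pos - 1L
  offs <- cumsum(c(0L, (model$cds$end - model$cds$start)[-nrow(model$cds)]))
  hit <- rep(NA_integer_, nrow(v))
  for (k in seq_len(nrow(model$cds))) {
    inside <- v$chrom == model$chrom &
      pos0 >= model$cds$start[k] &
      (pos0 + nchar(v$ref)) <= model$cds$end[k]
    hit[inside] <- k
  }
  idx <- which(!is.na(hit))
  local <- data.frame(
    col = idx,
    pos = pos0[idx] - model$cds$start[hit[idx]] + offs[hit[idx]],
    ref = v$ref[idx], alt = v$alt[idx],
    label = sprintf("%s:%d%s>%s", v$chrom[idx], v$pos[idx], v$ref[idx], v$alt[idx]),
    stringsAsFactors = FALSE)

  plus_slice <- paste(substring(genome[[model$chrom]], model$cds$start + 1L,
                                model$cds$end), collapse = "")
  out <- data.frame(accession = genotypes$accessions,
                    gene_id = model$gene_id,
                    status = "FUNCTIONAL", present = TRUE, events = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(genotypes$accessions)) {
    calls <- genotypes$calls[i, local$col]
    if (policy == "strict" && any(calls %in% c("HET", "MISSING"))) {
      out$status[i] <- "UNRESOLVED"
      out$present[i] <- FALSE
      out$events[i] <- paste(local$label[calls %in% c("HET", "MISSING")],
                             collapse = ";")
      next
    }
    sel <- calls == "ALT"
    if (!any(sel)) next
    edited <- apply_variants(plus_slice, local[sel, c("pos", "ref", "alt")])
    if (model$strand == "-") edited <- revcomp(edited)
    status <- classify_orf(edited, ref_protein_len)
    out$status[i] <- status
    out$present[i] <- status == "FUNCTIONAL"
    if (status != "FUNCTIONAL") out$events[i] <- paste(local$label[sel], collapse = ";")
  }
  out
}
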