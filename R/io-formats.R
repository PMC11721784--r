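# Format readers and writers. Internally every genomic interval is 0-based
# half-open; conversion to the 1-based conventions of FASTA/VCF/GFF3 happens
# only inside these functions.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. Gap characters
#' (`-`) are accepted so that alignment FASTA files can be read with the same
#' function.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, names are record ids, in file
#'   order.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA file '", path, "' has a record with an empty id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sequence id(s) in '", path, "': ", paste(dup, collapse = ", "))
  seqs <- chartr("u", "U", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("non-DNA characters in record(s): ", paste(ids[bad], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a genotype matrix object
#'
#' @param accessions character vector of accession ids.
#' @param variants data.frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `id`, `ref`, `alt`; one row per biallelic variant.
#' @param calls character matrix (accession x variant) over
#'   `REF`, `ALT`, `HET`, `MISSING`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(accessions, variants, calls) {
  stopifnot(is.character(accessions), is.data.frame(variants), is.matrix(calls))
  need <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(calls) != length(accessions) || ncol(calls) != nrow(variants))
    stop("calls matrix dimensions do not match accession/variant lists")
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1 (1-based VCF convention)")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)))
    stop("ref and alt alleles must be non-empty")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  bad <- setdiff(unique(as.vector(calls)), c("REF", "ALT", "HET", "MISSING"))
  if (length(bad)) stop("invalid call state(s): ", paste(bad, collapse = ", "))
  dimnames(calls) <- list(accessions, NULL)
  structure(list(accessions = accessions, variants = variants, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$accessions), " accessions x ",
      nrow(x$variants), " biallelic variants\n", sep = "")
  invisible(x)
}

#' Read a VCF into a genotype matrix
#'
#' Multi-allelic records are split into biallelic records; for the record of
#' alternate allele *a*, a diploid genotype maps by its count of allele *a*
#' (2 to `ALT`, 1 to `HET`, 0 to `REF`) and any genotype containing `.` maps
#' to `MISSING`. Phasing is ignored. Star (`*`) alleles are dropped with a
#' warning.
#'
#' @param path path to a VCF (v4.x) file with a GT FORMAT field.
#' @return a [genotype_matrix()].
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (!"GT" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF '", path, "' has no GT genotype field")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(VariantAnnotation::alt(vcf))
  ref <- as.character(VariantAnnotation::ref(vcf))
  # allele index of each expanded row within its original record
  keep <- alt != "*"
  if (any(!keep)) warning(sum(!keep), " star-allele record(s) dropped")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(alt))
  accessions <- colnames(gt)
  # which ALT index each expanded row is: recover by counting within (chrom,pos,ref)
  key <- paste(as.character(GenomicRanges::seqnames(rr)), GenomicRanges::start(rr), ref)
  aidx <- stats::ave(seq_along(key), key, FUN = seq_along)
  map_call <- function(g, a) {
    if (grepl("\\.", g)) return("MISSING")
    alleles <- strsplit(g, "[/|]")[[1]]
    n <- sum(alleles == as.character(a))
    if (n >= 2L) "ALT" else if (n == 1L) "HET" else "REF"
  }
  calls <- matrix("MISSING", nrow = length(accessions), ncol = sum(keep))
  rows <- which(keep)
  for (j in seq_along(rows)) {
    i <- rows[j]
    calls[, j] <- vapply(gt[i, ], map_call, character(1), a = aidx[i])
  }
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    id = names(rr)[keep] %||% NA_character_,
    ref = ref[keep], alt = alt[keep],
    stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  genotype_matrix(accessions, variants, calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genotype matrix as VCF
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param contig_lengths optional named integer vector of contig lengths for
#'   the header.
#' @return `path`, invisibly.
#' @export
write_variants <- function(gm, path, contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  chroms <- unique(gm$variants$chrom)
  for (ch in chroms) {
    len <- if (!is.null(contig_lengths) && ch %in% names(contig_lengths))
      contig_lengths[[ch]]
    else max(gm$variants$pos[gm$variants$chrom == ch]) + 1000L
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, as.integer(len)), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$accessions), collapse = "\t"), con)
  code <- c(REF = "0/0", ALT = "1/1", HET = "0/1", MISSING = "./.")
  for (j in seq_len(nrow(gm$variants))) {
    v <- gm$variants[j, ]
    writeLines(paste(c(v$chrom, v$pos, ifelse(is.na(v$id), ".", v$id), v$ref,
                       v$alt, ".", ".", ".", "GT", code[gm$calls[, j]]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genomic intervals from BED or GFF3
#'
#' All intervals are returned 0-based half-open regardless of the input
#' dialect. For GFF3, only `CDS` features are returned, named by their
#' `Parent` (falling back to `ID`) attribute and sorted by coordinate within
#' each gene.
#'
#' @param path input path.
#' @param dialect `"bed"` (0-based half-open) or `"gff3"` (1-based closed).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`
#'   (0-based half-open).
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interval file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3"),
    error = function(e) stop("malformed ", toupper(dialect), " '", path, "': ",
                             conditionMessage(e)))
  if (dialect == "gff3") {
    gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
    parent <- vapply(as.list(S4Vectors::mcols(gr)$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    nm <- ifelse(is.na(parent), S4Vectors::mcols(gr)$ID, parent)
  } else {
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    name = nm,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  if (any(out$start >= out$end))
    stop("interval with start >= end after normalization in '", path, "'")
  out[order(out$name, out$chrom, out$start), , drop = FALSE]
}

#' Write 0-based half-open intervals as BED
#'
#' @param intervals data.frame as returned by [read_intervals()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) stop("interval with start >= end")
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  st <- if ("strand" %in% names(intervals)) intervals$strand else "."
  utils::write.table(
    data.frame(intervals$chrom, intervals$start, intervals$end, nm, 0L, st),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV table with a required-column schema
#'
#' @param path path to a tab-separated file with a header line.
#' @param required character vector of column names that must be present.
#' @return data.frame; unknown extra columns are preserved, row order kept.
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("table '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Write a data.frame as TSV
#'
#' @param tab data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
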