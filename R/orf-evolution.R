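# Codon-aware evolutionary history of an ORF: outgroup-rooted parsimony
# ancestor, per-branch substitution/indel/stop events in the reference
# reading frame, TSD motif scan, homology-hit filtering.

ALN_STATES <- c("A", "C", "G", "T", "-")

#' Construct an ortholog alignment object
#'
#' @param records named character vector of equal-length aligned sequences
#'   over `A`, `C`, `G`, `T`, `N`, `-`.
#' @param reference_id id of the record whose reading frame anchors all codon
#'   indexing (the reference must have a whole number of codons after gap
#'   removal).
#' @param frame_offset 1-based alignment column of the reference's first CDS
#'   base.
#' @return an object of class `ortholog_alignment`.
#' @export
ortholog_alignment <- function(records, reference_id, frame_offset = 1L) {
  stopifnot(is.character(records), !is.null(names(records)))
  if (length(unique(nchar(records))) != 1L)
    stop("aligned records must all have the same length")
  if (!reference_id %in% names(records))
    stop("reference id '", reference_id, "' not among the records")
  ref_len <- sum(strsplit(substring(records[[reference_id]], frame_offset),
                          "")[[1]] != "-")
  if (ref_len %% 3L != 0L)
    warning("reference has ", ref_len, " non-gap bases after the frame offset; ",
            "not a whole number of codons")
  structure(list(records = records, reference_id = reference_id,
                 frame_offset = as.integer(frame_offset)),
            class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("ortholog_alignment: ", length(x$records), " records x ",
      nchar(x$records[[1]]), " columns (reference ", x$reference_id, ")\n", sep = "")
  invisible(x)
}

# 0-based reference codon index per alignment column (NA where the reference
# is gapped or before the frame offset), plus the columns of each codon.
ref_codon_map <- function(aln) {
  ref <- strsplit(aln$records[[aln$reference_id]], "")[[1]]
  idx <- rep(NA_integer_, length(ref))
  coding <- which(seq_along(ref) >= aln$frame_offset & ref != "-")
  idx[coding] <- (seq_along(coding) - 1L) %/% 3L
  cols <- split(coding, idx[coding])
  list(index = idx, codon_cols = cols)
}

#' Reconstruct the ingroup ancestor by outgroup-rooted Fitch parsimony
#'
#' Column-wise Fitch parsimony over the ingroup leaves (gap treated as a
#' fifth state), with the outgroup used to root the tree and to break ties:
#' when the ingroup root state set has more than one member, the outgroup
#' state is chosen if it belongs to the set; ties the outgroup cannot break
#' fall back to the reference state, and finally to a fixed
#' `A < C < G < T < -` order. Multifurcating nodes use the generalized
#' (majority-count) Fitch rule.
#'
#' @param aln an [ortholog_alignment()].
#' @param tree an `ape::phylo` object or a Newick string whose tip labels are
#'   record ids in `aln`.
#' @param outgroup tip label of the outgroup leaf.
#' @return the ancestral sequence as a single named character string
#'   (aligned, may contain gaps).
#' @export
reconstruct_ancestor_parsimony <- function(aln, tree, outgroup) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick string")
  if (!outgroup %in% tree$tip.label) stop("outgroup '", outgroup, "' is not a tip of the tree")
  miss <- setdiff(tree$tip.label, names(aln$records))
  if (length(miss))
    stop("tree leaf/leaves missing from the alignment: ", paste(miss, collapse = ", "))
  if (length(tree$tip.label) < 3L) stop("tree must have at least 3 leaves")

  ingroup_tips <- setdiff(tree$tip.label, outgroup)
  chars <- lapply(aln$records, function(s) strsplit(s, "")[[1]])
  ncol_aln <- length(chars[[1]])
  # state-set bitmask per column, per taxon (N = any base)
  bit <- stats::setNames(c(1L, 2L, 4L, 8L, 16L), ALN_STATES)
  mask_of <- function(v) {
    m <- unname(bit[v])
    m[v == "N"] <- 15L
    m
  }

  if (length(ingroup_tips) == 1L) {
    root_mask <- mask_of(chars[[ingroup_tips]])
  } else {
    sub <- ape::keep.tip(tree, ingroup_tips)
    sub <- stats::reorder(sub, "postorder")
    ntip <- length(sub$tip.label)
    nnode <- sub$Nnode
    masks <- matrix(0L, nrow = ntip + nnode, ncol = ncol_aln)
    for (i in seq_len(ntip)) masks[i, ] <- mask_of(chars[[sub$tip.label[i]]])
    for (node in unique(sub$edge[, 1])) {
      children <- sub$edge[sub$edge[, 1] == node, 2]
      # generalized Fitch: keep states present in the maximal number of
      # child state sets
      counts <- matrix(0L, nrow = 5L, ncol = ncol_aln)
      for (ch in children)
        for (b in seq_len(5L))
          counts[b, ] <- counts[b, ] + bitwAnd(masks[ch, ], bit[b]) %/% bit[b]
      maxc <- apply(counts, 2, max)
      m <- integer(ncol_aln)
      for (b in seq_len(5L)) m <- m + bit[b] * (counts[b, ] == maxc)
      masks[node, ] <- m
    }
    root_mask <- masks[ntip + 1L, ]  # ape root node
  }

  out_mask <- mask_of(chars[[outgroup]])
  ref_mask <- mask_of(chars[[aln$reference_id]])
  pick_first <- function(mask) ALN_STATES[match(TRUE, bitwAnd(mask, bit) > 0L)]
  anc <- character(ncol_aln)
  single <- root_mask %in% bit  # exactly one state
  for (j in seq_len(ncol_aln)) {
    m <- root_mask[j]
    anc[j] <- if (single[j]) pick_first(m)
      else if (bitwAnd(m, out_mask[j]) > 0L && out_mask[j] %in% bit)
        pick_first(bitwAnd(m, out_mask[j]))
      else if (bitwAnd(m, ref_mask[j]) > 0L && ref_mask[j] %in% bit)
        pick_first(bitwAnd(m, ref_mask[j]))
      else pick_first(m)
  }
  stats::setNames(paste(anc, collapse = ""), "ancestor")
}

#' Annotate the events along one tree branch
#'
#' Compares an aligned parent sequence with an aligned child sequence.
#' Maximal runs of gap-versus-base columns become single `INS` or `DEL`
#' events. Each substituted column is classified in the reference-frame codon
#' by substituting that site alone while holding the other two codon
#' positions at the parent (ancestral) state: a parent stop codon turning
#' non-stop is `STOP_LOSS`, a new stop is `STOP_GAIN`, destruction of the
#' reference start codon is `START_LOST`, otherwise `SYN` when the encoded
#' amino acids agree and `NONSYN` when they differ. Stop and start events
#' take precedence over the SYN/NONSYN label. Codons hit by more than one
#' substitution are flagged `multi_hit`; with `multi_hit = "per-codon"` such
#' codons are instead emitted as a single event comparing the full parent and
#' child codons. Indels never shift the reading frame: codon indexing always
#' stays on the reference columns. Events at columns where the reference is
#' gapped carry `codon_index = NA` (and no SYN/NONSYN call for
#' substitutions).
#'
#' @param parent,child aligned sequence strings of equal length.
#' @param aln an [ortholog_alignment()] providing the reference frame.
#' @param labels length-2 character vector naming the branch ends.
#' @param multi_hit `"per-site"` (default) or `"per-codon"`.
#' @return data.frame with columns `parent`, `child`, `kind`, `codon_index`
#'   (0-based), `col_start`, `col_end` (1-based alignment columns), `detail`,
#'   `multi_hit`. Zero rows when the sequences are identical.
#' @export
annotate_branch_events <- function(parent, child, aln,
                                   labels = c("parent", "child"),
                                   multi_hit = c("per-site", "per-codon")) {
  multi_hit <- match.arg(multi_hit)
  stopifnot(inherits(aln, "ortholog_alignment"),
            nchar(parent) == nchar(child))
  p <- strsplit(parent, "")[[1]]
  c_ <- strsplit(child, "")[[1]]
  map <- ref_codon_map(aln)
  empty <- data.frame(parent = character(0), child = character(0),
                      kind = character(0), codon_index = integer(0),
                      col_start = integer(0), col_end = integer(0),
                      detail = character(0), multi_hit = logical(0),
                      stringsAsFactors = FALSE)
  rows <- list()
  mk <- function(kind, ci, cs, ce, detail, mh = FALSE) {
    data.frame(parent = labels[1], child = labels[2], kind = kind,
               codon_index = ci, col_start = cs, col_end = ce,
               detail = detail, multi_hit = mh, stringsAsFactors = FALSE)
  }

  # indel runs
  state <- integer(length(p))
  state[p == "-" & c_ != "-"] <- 1L  # insertion on this branch
  state[p != "-" & c_ == "-"] <- 2L  # deletion on this branch
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values > 0L)) {
    cs <- starts[k]; ce <- ends[k]
    kind <- if (r$values[k] == 1L) "INS" else "DEL"
    span_idx <- map$index[cs:ce]
    ci <- if (all(is.na(span_idx))) NA_integer_ else min(span_idx, na.rm = TRUE)
    detail <- if (kind == "INS")
      paste0("-(", ce - cs + 1L, ")->", paste(c_[cs:ce], collapse = ""))
    else paste0(paste(p[cs:ce], collapse = ""), "->-(", ce - cs + 1L, ")")
    rows[[length(rows) + 1L]] <- mk(kind, ci, cs, ce, detail)
  }

  # substitutions
  sub_cols <- which(p != "-" & c_ != "-" & p != c_)
  if (length(sub_cols)) {
    sub_ci <- map$index[sub_cols]
    hits_per_codon <- table(sub_ci[!is.na(sub_ci)])
    classify_one <- function(pcod, ccod, ci) {
      if (!is.na(ci) && ci == 0L && paste(ccod, collapse = "") != "ATG")
        return("START_LOST")
      ps <- paste(pcod, collapse = "") %in% STOP_CODONS
      cs <- paste(ccod, collapse = "") %in% STOP_CODONS
      if (ps && !cs) return("STOP_LOSS")
      if (cs && !ps) return("STOP_GAIN")
      if (identical(translate_codon(paste(pcod, collapse = "")),
                    translate_codon(paste(ccod, collapse = "")))) "SYN" else "NONSYN"
    }
    done_codons <- integer(0)
    for (i in seq_along(sub_cols)) {
      col <- sub_cols[i]; ci <- sub_ci[i]
      if (is.na(ci)) {
        rows[[length(rows) + 1L]] <- mk(NA_character_, NA_integer_, col, col,
                                        paste0(p[col], "->", c_[col]))
        next
      }
      cols3 <- map$codon_cols[[as.character(ci)]]
      mh <- hits_per_codon[[as.character(ci)]] > 1L
      if (multi_hit == "per-codon" && mh) {
        if (ci %in% done_codons) next
        done_codons <- c(done_codons, ci)
        pcod <- p[cols3]; ccod <- c_[cols3]
        if (any(pcod == "-") || any(ccod == "-")) next  # covered by indel events
        kind <- classify_one(pcod, ccod, ci)
        chg <- cols3[pcod != ccod]
        rows[[length(rows) + 1L]] <- mk(kind, ci, min(chg), max(chg),
          paste0(paste(pcod, collapse = ""), "->", paste(ccod, collapse = "")), TRUE)
        next
      }
      pcod <- p[cols3]
      if (any(pcod == "-")) {  # parent codon not formable: record base change
        rows[[length(rows) + 1L]] <- mk(NA_character_, ci, col, col,
                                        paste0(p[col], "->", c_[col]), mh)
        next
      }
      ccod <- pcod
      ccod[match(col, cols3)] <- c_[col]
      kind <- classify_one(pcod, ccod, ci)
      rows[[length(rows) + 1L]] <- mk(kind, ci, col, col,
        paste0(paste(pcod, collapse = ""), "->", paste(ccod, collapse = "")), mh)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$col_start), , drop = FALSE]
}

#' Scan a flanking sequence for a target-site-duplication motif
#'
#' Reports every occurrence of the motif (optionally with mismatches) with
#' its absolute coordinates and its distance in bp upstream of the start
#' codon, measured 1-based from the motif's 3' end to the base immediately
#' 5' of the first base of ATG (a motif ending directly before the start
#' codon has distance 1).
#'
#' @param flank flanking sequence string.
#' @param motif motif string, e.g. `"CATGGC"`.
#' @param start_codon_pos 1-based position of the first base of the start
#'   codon within `flank`.
#' @param max_mismatch mismatch tolerance (default 0 = exact).
#' @return data.frame with columns `start`, `end` (1-based, inclusive) and
#'   `distance_upstream`; zero rows when the motif is absent. Hits are in
#'   5'-to-3' order.
#' @export
scan_tsd <- function(flank, motif, start_codon_pos, max_mismatch = 0L) {
  stopifnot(nchar(motif) > 0L, start_codon_pos >= 1L,
            start_codon_pos <= nchar(flank))
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(flank),
                                max.mismatch = max_mismatch)
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
             distance_upstream = start_codon_pos - BiocGenerics::end(m))
}

#' Filter tabular homology hits
#'
#' Retains hits with `evalue <= max_evalue`, `pct_identity >= min_identity`
#' and query coverage `>= min_qcov` (all bounds inclusive). Query coverage is
#' taken from a `qcov` column when present, otherwise derived as
#' `100 * align_len / query_length`.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `align_len`, `evalue` and optionally `qcov`.
#' @param query_lengths named numeric vector of query lengths (required when
#'   `hits` has no `qcov` column).
#' @param max_evalue,min_identity,min_qcov filter thresholds.
#' @return the retained rows of `hits`, with a `qcov` column. Rows with
#'   missing or negative fields are rejected with a warning.
#' @export
filter_homology_hits <- function(hits, query_lengths = NULL,
                                 max_evalue = 1e-5, min_identity = 60,
                                 min_qcov = 70) {
  need <- c("query_id", "subject_id", "pct_identity", "align_len", "evalue")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hits table missing column(s): ", paste(miss, collapse = ", "))
  if (!"qcov" %in% names(hits)) {
    if (is.null(query_lengths))
      stop("hits table has no qcov column and no query_lengths were supplied")
    qlen <- query_lengths[hits$query_id]
    hits$qcov <- 100 * hits$align_len / as.numeric(qlen)
  }
  bad <- is.na(hits$pct_identity) | is.na(hits$evalue) | is.na(hits$qcov) |
    hits$pct_identity < 0 | hits$evalue < 0 | hits$qcov < 0
  if (any(bad)) {
    warning(sum(bad), " hit(s) with missing or negative fields rejected")
    hits <- hits[!bad, , drop = FALSE]
  }
  hits[hits$evalue <= max_evalue & hits$pct_identity >= min_identity &
         hits$qcov >= min_qcov, , drop = FALSE]
}
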