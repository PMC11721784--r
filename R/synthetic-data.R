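# Synthetic inputs with planted ground truth for every analysis stage. The
# generators are deterministic given (scenario parameters, seed) and their
# truth is serialized alongside the data when a directory is given.

SAFE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

# one-substitution (parent, child) codon pairs per planted event kind
EVENT_CODONS <- list(
  SYN = list(c("GGA", "GGG"), c("CTA", "CTG"), c("GTT", "GTC"), c("TCA", "TCT")),
  NONSYN = list(c("GAA", "GTA"), c("AAA", "GAA"), c("TTC", "TCC"), c("CGT", "CAT")),
  STOP_GAIN = list(c("CAA", "TAA"), c("TGG", "TGA"), c("CAG", "TAG")),
  STOP_LOSS = list(c("TAA", "CAA"), c("TGA", "TGG"), c("TAG", "CAG")))

random_codons <- function(n) sample(SAFE_CODONS, n, replace = TRUE)

#' Generate a gene catalog with planted loss-of-function variants
#'
#' Builds a synthetic chromosome carrying `nrow(lof_freq)` well-formed genes
#' (ATG ... stop), a VCF-style genotype matrix over all accessions, and a
#' population map. Gene absence is created by planting exactly one
#' loss-of-function variant per gene, drawn uniformly from premature-stop
#' SNP, start-loss SNP, stop-loss SNP and 1-bp frameshift deletion; the
#' number of absent accessions per population is the exact census count
#' `round(freq * n)` (not binomially sampled), so a full-census frequency
#' computation recovers the planted frequencies exactly.
#'
#' @param populations named integer vector, population name to size.
#' @param lof_freq numeric matrix of planted absence frequencies in \[0, 1\],
#'   genes x populations (`colnames` must match `names(populations)`;
#'   `rownames` are gene ids, generated when absent).
#' @param n_codons protein length of each reference gene in codons
#'   (excluding the terminal stop).
#' @param intergenic intergenic spacer length in bp.
#' @param seed integer seed.
#' @param dir optional output directory for `genome.fasta`, `genes.gff3`,
#'   `variants.vcf`, `pops.tsv`, `truth.json`.
#' @return list with `genome`, `models`, `genotypes`, `pops`, `truth`
#'   (data.frame of realized per-gene, per-population absence counts and the
#'   planted LoF type) and, when `dir` is given, `paths`.
#' @export
gen_catalog_variants <- function(populations, lof_freq, n_codons = 50L,
                                 intergenic = 500L, seed = NULL, dir = NULL) {
  stopifnot(is.numeric(populations), !is.null(names(populations)),
            is.matrix(lof_freq), all(lof_freq >= 0), all(lof_freq <= 1))
  if (is.null(colnames(lof_freq))) colnames(lof_freq) <- names(populations)
  stopifnot(setequal(colnames(lof_freq), names(populations)))
  if (is.null(rownames(lof_freq)))
    rownames(lof_freq) <- sprintf("gene%02d", seq_len(nrow(lof_freq)))
  genes <- rownames(lof_freq)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "catalog"), {
    accessions <- unlist(lapply(names(populations), function(p)
      sprintf("%s_acc%03d", p, seq_len(populations[[p]]))), use.names = FALSE)
    pops <- data.frame(accession = accessions,
                       population = rep(names(populations), populations),
                       stringsAsFactors = FALSE)

    lof_types <- sample(c("premature_stop", "start_loss", "stop_loss",
                          "frameshift_del"), length(genes), replace = TRUE)
    chrom <- "chr1"
    pieces <- character(0)
    cursor <- 0L  # 0-based genome cursor
    models <- list()
    var_rows <- list()
    for (gi in seq_along(genes)) {
      spacer <- paste(sample(c("A", "C", "G", "T"), intergenic, replace = TRUE),
                      collapse = "")
      gene_start <- cursor + intergenic  # 0-based
      codons <- c("ATG", random_codons(n_codons - 1L), "TAA")
      type <- lof_types[gi]
      target_codon <- sample(2:(n_codons - 1L), 1L)  # interior, 1-based codon
      if (type == "premature_stop") codons[target_codon] <- "TAC"
      cds <- paste(codons, collapse = "")
      v <- switch(type,
        premature_stop = list(off = (target_codon - 1L) * 3L + 2L,
                              ref = "C", alt = "A"),
        start_loss = list(off = 0L, ref = "A", alt = "G"),
        stop_loss = list(off = n_codons * 3L, ref = "T", alt = "C"),
        frameshift_del = {
          off <- (target_codon - 1L) * 3L
          list(off = off, ref = substr(cds, off + 1L, off + 2L),
               alt = substr(cds, off + 1L, off + 1L))
        })
      var_rows[[gi]] <- data.frame(
        chrom = chrom, pos = gene_start + v$off + 1L,  # to 1-based VCF
        id = paste0(genes[gi], "_lof"), ref = v$ref, alt = v$alt,
        stringsAsFactors = FALSE)
      models[[genes[gi]]] <- gene_model(
        genes[gi], chrom, "+",
        data.frame(start = gene_start, end = gene_start + nchar(cds)))
      pieces <- c(pieces, spacer, cds)
      cursor <- gene_start + nchar(cds)
    }
    tail_spacer <- paste(sample(c("A", "C", "G", "T"), intergenic,
                                replace = TRUE), collapse = "")
    genome <- stats::setNames(paste(c(pieces, tail_spacer), collapse = ""), chrom)
    variants <- do.call(rbind, var_rows)

    calls <- matrix("REF", nrow = length(accessions), ncol = length(genes),
                    dimnames = list(accessions, NULL))
    truth_rows <- list()
    for (gi in seq_along(genes)) {
      for (p in names(populations)) {
        members <- pops$accession[pops$population == p]
        n_abs <- as.integer(round(lof_freq[genes[gi], p] * length(members)))
        if (n_abs > 0L) {
          absent <- sample(members, n_abs)
          calls[absent, gi] <- "ALT"
        }
        truth_rows[[paste(genes[gi], p)]] <- data.frame(
          gene_id = genes[gi], population = p, lof_type = lof_types[gi],
          n = length(members), n_absent = n_abs,
          freq_pct = 100 * (length(members) - n_abs) / length(members),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    gm <- genotype_matrix(accessions, variants, calls)
    out <- list(genome = genome, models = models, genotypes = gm, pops = pops,
                truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(genome = file.path(dir, "genome.fasta"),
                    gff = file.path(dir, "genes.gff3"),
                    vcf = file.path(dir, "variants.vcf"),
                    pops = file.path(dir, "pops.tsv"),
                    truth = file.path(dir, "truth.json"))
      write_sequences(genome, paths$genome)
      gff <- c("##gff-version 3")
      for (m in models) {
        gff <- c(gff,
          sprintf("%s\tdenovopop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  m$chrom, min(m$cds$start) + 1L, max(m$cds$end), m$strand,
                  m$gene_id),
          sprintf("%s\tdenovopop\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                  m$chrom, m$cds$start + 1L, m$cds$end, m$strand, m$gene_id,
                  m$gene_id))
      }
      writeLines(gff, paths$gff)
      write_variants(gm, paths$vcf,
                     contig_lengths = stats::setNames(nchar(genome), names(genome)))
      write_tsv(pops, paths$pops)
      jsonlite::write_json(truth, paths$truth, digits = NA)
      out$paths <- paths
    }
    out
  })
}

#' Generate haplotypes with a planted sweep LD signature
#'
#' Background sites are independent Bernoulli columns (expected r-squared
#' near 0). Inside the sweep, every haplotype is independently assigned one
#' of `n_haplogroups` left-flank block patterns and, independently, one
#' right-flank pattern, yielding within-flank r-squared of 1 and cross-flank
#' r-squared near 0 -- the configuration that maximizes the omega statistic
#' at the sweep center. With `n_haplogroups = 1` the flank sites are
#' monomorphic and dropped, leaving no evaluable signal at the center.
#'
#' @param n_hap number of haplotypes.
#' @param region_len chromosome span in bp.
#' @param site_density expected polymorphic sites per bp.
#' @param sweep_center planted sweep position in bp.
#' @param flank_width one-sided width of each sweep flank in bp.
#' @param n_haplogroups number of haplotype blocks per flank.
#' @param maf_range background minor-allele-frequency range.
#' @param sweep plant the sweep (`FALSE` gives a pure null data set).
#' @param population population label.
#' @param seed integer seed.
#' @param dir optional output directory for `haplotypes.tsv`, `truth.json`.
#' @return list with `hap` (a [haplotype_matrix()]) and `truth`.
#' @export
gen_sweep_haplotypes <- function(n_hap = 100L, region_len = 200000L,
                                 site_density = 2e-3, sweep_center = 100000L,
                                 flank_width = 10000L, n_haplogroups = 2L,
                                 maf_range = c(0.1, 0.5), sweep = TRUE,
                                 population = "pop1", seed = NULL, dir = NULL) {
  stopifnot(sweep_center - flank_width > 0,
            sweep_center + flank_width < region_len)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "sweep"), {
    left_rng <- c(sweep_center - flank_width, sweep_center - 1L)
    right_rng <- c(sweep_center, sweep_center + flank_width - 1L)
    in_sweep <- function(p) sweep && p >= left_rng[1] && p <= right_rng[2]
    all_pos <- seq_len(region_len)
    bg_pool <- if (sweep)
      all_pos[all_pos < left_rng[1] | all_pos > right_rng[2]] else all_pos
    n_bg <- round(site_density * length(bg_pool))
    bg_pos <- sort(sample(bg_pool, n_bg))
    cols <- list()
    positions <- integer(0)
    for (p in bg_pos) {
      maf <- stats::runif(1, maf_range[1], maf_range[2])
      cols[[length(cols) + 1L]] <- stats::rbinom(n_hap, 1L, maf)
      positions <- c(positions, p)
    }
    if (sweep) {
      n_fl <- max(2L, round(site_density * flank_width))
      for (side in c("left", "right")) {
        rng <- if (side == "left") left_rng else right_rng
        fl_pos <- sort(sample(seq(rng[1], rng[2]), n_fl))
        group <- sample.int(n_haplogroups, n_hap, replace = TRUE)
        for (p in fl_pos) {
          states <- if (n_haplogroups == 1L) 0L else {
            # per-site group states, at least one 0 and one 1 so that the
            # site is polymorphic whenever both groups are represented
            s <- stats::rbinom(n_haplogroups, 1L, 0.5)
            if (all(s == s[1])) s[sample.int(n_haplogroups, 1L)] <- 1L - s[1]
            s
          }
          cols[[length(cols) + 1L]] <- states[group]
          positions <- c(positions, p)
        }
      }
    }
    ord <- order(positions)
    m <- do.call(cbind, cols)[, ord, drop = FALSE]
    hap <- haplotype_matrix(m, positions[ord], chrom = "chr1",
                            population = population)
    truth <- list(sweep = sweep,
                  sweep_center = if (sweep) sweep_center else NA,
                  flank_width = flank_width, n_haplogroups = n_haplogroups,
                  n_hap = n_hap, region_len = region_len)
    out <- list(hap = hap, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      tab <- data.frame(position = hap$positions, t(hap$haplotypes))
      paths <- list(hap = file.path(dir, "haplotypes.tsv"),
                    truth = file.path(dir, "truth.json"))
      write_tsv(tab, paths$hap)
      jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
      out$paths <- paths
    }
    out
  })
}

#' Generate a two-group environmental table with a planted mean shift
#'
#' Nineteen climate factors are drawn as independent standard normals
#' (scaled by `sd`); the focal factor carries a planted mean shift in the
#' absent group.
#'
#' @param n_present,n_absent group sizes (`n_absent` must be >= 1).
#' @param effect mean shift added to the focal factor of the absent group
#'   (in the same units as `sd`).
#' @param sd common standard deviation of every factor.
#' @param focal name of the shifted factor.
#' @param seed integer seed.
#' @param dir optional output directory for `env.tsv`, `present.txt`,
#'   `absent.txt`, `truth.json`.
#' @return list with `env` (data.frame `accession`, `bio1`..`bio19`),
#'   `present`, `absent` (id vectors) and `truth`.
#' @export
gen_env <- function(n_present = 55L, n_absent = 5L, effect = 0, sd = 1,
                    focal = "bio17", seed = NULL, dir = NULL) {
  if (n_absent < 1L) stop("n_absent must be at least 1")
  if (n_present <= n_absent) stop("n_present must exceed n_absent")
  stopifnot(sd > 0)
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "env"), {
    ids <- c(sprintf("present%03d", seq_len(n_present)),
             sprintf("absent%03d", seq_len(n_absent)))
    env <- data.frame(accession = ids, stringsAsFactors = FALSE)
    for (f in sprintf("bio%d", 1:19))
      env[[f]] <- stats::rnorm(n_present + n_absent, 0, sd)
    env[[focal]][(n_present + 1):(n_present + n_absent)] <-
      env[[focal]][(n_present + 1):(n_present + n_absent)] + effect
    present <- ids[seq_len(n_present)]
    absent <- ids[(n_present + 1):(n_present + n_absent)]
    truth <- list(effect = effect, sd = sd, focal = focal,
                  n_present = n_present, n_absent = n_absent)
    out <- list(env = env, present = present, absent = absent, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(env = file.path(dir, "env.tsv"),
                    present = file.path(dir, "present.txt"),
                    absent = file.path(dir, "absent.txt"),
                    truth = file.path(dir, "truth.json"))
      write_tsv(env, paths$env)
      writeLines(present, paths$present)
      writeLines(absent, paths$absent)
      jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
      out$paths <- paths
    }
    out
  })
}

#' Generate an ortholog quartet alignment with planted branch events
#'
#' Builds an ancestral ORF (ATG, non-stop codons, terminal stop), derives two
#' ingroup leaves and one outgroup on the fixed topology
#' `((ingroup1, ingroup2), outgroup)`, and plants the requested events on the
#' requested branches at distinct codons (so no codon is multi-hit).
#' Substitution events change exactly one base; insertions and deletions are
#' whole codons, so the reference (`ingroup1`) reading frame always holds a
#' whole number of codons. Events named on the `outgroup:ancestor` branch
#' (e.g. the stop-codon losses that extend an ORF) place the parent state in
#' the outgroup and the child state in the ancestor and both ingroup leaves.
#'
#' @param n_codons reference protein length in codons (excluding the
#'   terminal stop).
#' @param events named list of per-branch event counts; names among
#'   `"outgroup:ancestor"`, `"ancestor:ingroup1"`, `"ancestor:ingroup2"`,
#'   each a named integer vector over
#'   `SYN`, `NONSYN`, `STOP_GAIN`, `STOP_LOSS`, `INS`, `DEL`.
#' @param seed integer seed.
#' @param dir optional output directory for `aln.fasta`, `tree.nwk`,
#'   `truth.json`.
#' @return list with `alignment` (an [ortholog_alignment()] of the three
#'   observable taxa), `tree` (Newick string), `ancestor` (the true aligned
#'   ancestral sequence) and `truth` (data.frame of planted events).
#' @export
gen_ortholog_quartet <- function(n_codons = 70L, events = list(), seed = NULL,
                                 dir = NULL) {
  branches <- c("outgroup:ancestor", "ancestor:ingroup1", "ancestor:ingroup2")
  kinds <- c("SYN", "NONSYN", "STOP_GAIN", "STOP_LOSS", "INS", "DEL")
  bad <- setdiff(names(events), branches)
  if (length(bad)) stop("unknown branch(es): ", paste(bad, collapse = ", "))
  for (ev in events)
    if (length(setdiff(names(ev), kinds)))
      stop("unknown event kind(s): ",
           paste(setdiff(names(ev), kinds), collapse = ", "))
  below_of <- list("outgroup:ancestor" = c("ancestor", "ingroup1", "ingroup2"),
                   "ancestor:ingroup1" = "ingroup1",
                   "ancestor:ingroup2" = "ingroup2")
  taxa <- c("outgroup", "ancestor", "ingroup1", "ingroup2")

  n_slot_events <- sum(vapply(events, function(ev)
    sum(ev[setdiff(names(ev), "INS")]), numeric(1)))
  if (n_slot_events > n_codons - 2L)
    stop("requested events do not fit in ", n_codons,
         " codons without collisions")

  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "quartet"), {
    base <- c("ATG", random_codons(n_codons - 1L), "TAA")
    n_slots <- n_codons + 1L
    M <- matrix(rep(base, each = length(taxa)), nrow = length(taxa),
                dimnames = list(taxa, NULL))
    free_slots <- sample(2:(n_codons - 1L))  # interior codons, shuffled
    inserts <- list()
    truth_rows <- list()
    used_anchors <- integer(0)  # insertion anchors are globally unique so
                                # that same-branch insertions never merge
    del_slots <- list()         # per-branch deleted slots kept non-adjacent
    for (br in names(events)) {
      below <- below_of[[br]]
      above <- setdiff(taxa, below)
      for (kind in names(events[[br]])) {
        for (rep_i in seq_len(events[[br]][[kind]])) {
          if (kind == "INS") {
            avail <- setdiff(seq_len(n_codons - 1L), used_anchors)
            if (length(avail) == 0L)
              stop("requested events do not fit in ", n_codons, " codons")
            after <- if (length(avail) == 1L) avail else sample(avail, 1L)
            used_anchors <- c(used_anchors, after)
            inserts[[length(inserts) + 1L]] <-
              list(after = after, codon = random_codons(1L), below = below)
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
              branch = br, kind = kind, slot = NA_integer_,
              stringsAsFactors = FALSE)
            next
          }
          if (kind == "DEL") {
            ds <- del_slots[[br]]
            ok <- which(!(free_slots %in% c(ds - 1L, ds + 1L)))
            if (length(ok) == 0L)
              stop("requested events do not fit in ", n_codons, " codons")
            slot <- free_slots[ok[1L]]
            free_slots <- setdiff(free_slots, slot)
            del_slots[[br]] <- c(ds, slot)
            M[below, slot] <- "---"
          } else {
            slot <- free_slots[1L]
            free_slots <- free_slots[-1L]
            pair <- EVENT_CODONS[[kind]][[
              sample.int(length(EVENT_CODONS[[kind]]), 1L)]]
            M[above, slot] <- pair[1L]
            M[below, slot] <- pair[2L]
          }
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            branch = br, kind = kind, slot = slot, stringsAsFactors = FALSE)
        }
      }
    }
    # assemble: base slots in order, insertion slots after their anchor
    seq_of <- function(taxon) {
      parts <- character(0)
      for (s in seq_len(n_slots)) {
        parts <- c(parts, M[taxon, s])
        for (ins in inserts)
          if (ins$after == s)
            parts <- c(parts,
                       if (taxon %in% ins$below) ins$codon else "---")
      }
      paste(parts, collapse = "")
    }
    records <- stats::setNames(vapply(taxa, seq_of, character(1)), taxa)
    aln <- ortholog_alignment(records[c("ingroup1", "ingroup2", "outgroup")],
                              reference_id = "ingroup1")
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(branch = character(0), kind = character(0),
                 slot = integer(0), stringsAsFactors = FALSE)
    tree <- "((ingroup1,ingroup2),outgroup);"
    out <- list(alignment = aln, tree = tree,
                ancestor = stats::setNames(records[["ancestor"]], "ancestor"),
                truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(aln = file.path(dir, "aln.fasta"),
                    tree = file.path(dir, "tree.nwk"),
                    truth = file.path(dir, "truth.json"))
      write_sequences(aln$records, paths$aln)
      writeLines(tree, paths$tree)
      jsonlite::write_json(truth, paths$truth, digits = NA)
      out$paths <- paths
    }
    out
  })
}
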