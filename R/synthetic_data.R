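# Synthetic-data module: generates every input the pipeline consumes, with
# planted ground truth (which genes are venom genes, which carry signal
# peptides, which have peptide evidence, and the true Venn structure of the
# venom set), so all downstream stages are testable with no download.
#
# The emulated world is a two-library venom-gland / carcass design: a de novo
# transcriptome in which a small set of venom genes is strongly enriched in
# the venom gland, carries a textbook signal peptide, and leaves peptide
# evidence in the venom proteome.

# reverse genetic code: amino acid -> codons (stops under "*")
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))
})

#' Simulation configuration
#'
#' Defaults describe a desk-scale version of a two-library venom-gland
#' study: a few hundred transcripts, ~4% venom genes with eight-fold
#' venom-gland enrichment, background signal-peptide prevalence near the
#' ~7% seen in whole-transcriptome annotation transfer, and a planted
#' three-set Venn design proportional to a 70-protein venom set.
#'
#' @param n_transcripts Number of transcripts.
#' @param n_venom Number of planted venom genes (<= `n_transcripts`).
#' @param fold_change_venom Expected venom-gland : carcass FPKM ratio of
#'   venom genes.
#' @param library_size_vg,library_size_carcass Nominal sequencing depths
#'   (reads) used to convert planted FPKM to expected counts; defaults are
#'   the tissue read totals of the emulated two-library design. Realized
#'   library sizes are the count column sums.
#' @param dispersion Negative-binomial overdispersion (0 = deterministic
#'   rounded expectations).
#' @param sp_fraction_background Probability that a background transcript
#'   carries a signal-peptide-like ORF.
#' @param psm_depth Mean passing PSMs per venom protein (each supported
#'   protein gets at least one).
#' @param venn_design Integer vector of 4 counts (unique, nv_only, oep_only,
#'   both) summing to `n_venom`.
#' @param n_nv Size of the first reference venom set (used only for the
#'   reference-vs-reference homology table).
#' @param seed Integer seed; identical configs reproduce identical outputs.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 500L, n_venom = 20L,
                              fold_change_venom = 8,
                              library_size_vg = 29540102,
                              library_size_carcass = 28109926,
                              dispersion = 0.1,
                              sp_fraction_background = 0.07,
                              psm_depth = 3,
                              venn_design = NULL,
                              n_nv = 79L,
                              seed = 1L) {
  if (is.null(venn_design)) {
    # proportional to a (14, 25, 13, 18)/70 partition, fixed remainders
    venn_design <- round(n_venom * c(14, 25, 13, 18) / 70)
    venn_design[4] <- n_venom - sum(venn_design[1:3])
  }
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              n_venom = as.integer(n_venom),
              fold_change_venom = fold_change_venom,
              library_size_vg = library_size_vg,
              library_size_carcass = library_size_carcass,
              dispersion = dispersion,
              sp_fraction_background = sp_fraction_background,
              psm_depth = psm_depth,
              venn_design = as.integer(venn_design),
              n_nv = as.integer(n_nv),
              seed = as.integer(seed))
  for (f in c("n_transcripts", "fold_change_venom", "library_size_vg",
              "library_size_carcass", "psm_depth")) {
    if (cfg[[f]] <= 0) stop("invalid config: '", f, "' must be positive")
  }
  if (cfg$n_venom < 0 || cfg$n_venom > cfg$n_transcripts) {
    stop("invalid config: 'n_venom' must lie in [0, n_transcripts]")
  }
  if (cfg$dispersion < 0) stop("invalid config: 'dispersion' must be >= 0")
  if (cfg$sp_fraction_background < 0 || cfg$sp_fraction_background > 1) {
    stop("invalid config: 'sp_fraction_background' must lie in [0, 1]")
  }
  if (length(cfg$venn_design) != 4L || any(cfg$venn_design < 0) ||
      sum(cfg$venn_design) != cfg$n_venom) {
    stop("invalid config: 'venn_design' must be 4 non-negative counts ",
         "summing to n_venom")
  }
  structure(cfg, class = "simulation_config")
}

# random amino-acid string (uniform over the 20 standard residues)
.random_protein <- function(n) {
  paste(sample(setdiff(names(.kd), "X"), n, replace = TRUE), collapse = "")
}

# reverse-translate a protein with uniformly sampled synonymous codons
.reverse_translate <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(res, function(a) {
    cods <- .codons_by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# a textbook signal peptide: positive n-region (MKK), hydrophobic h-region
# (10 x L), small residues at the -3/-1 positions; cleavage after residue 16
.planted_signal <- function() "MKKLLLLLLLLLLALA"

# build a transcript around a planted ORF: short 5' UTR ending in an
# in-frame stop, the ORF (start codon ... stop codon), short 3' UTR
.orf_transcript <- function(protein) {
  utr5 <- paste(sample(c("A", "C", "G", "T"),
                       3L * sample.int(8L, 1L), replace = TRUE),
                collapse = "")
  utr3 <- paste(sample(c("A", "C", "G", "T"), sample.int(60L, 1L),
                       replace = TRUE), collapse = "")
  paste0(utr5, "TAA", .reverse_translate(protein), "TAA", utr3)
}

#' Generate a synthetic transcriptome with planted venom genes
#'
#' Planted venom transcripts (and a `sp_fraction_background` share of
#' background transcripts) encode an open reading frame whose N-terminus is
#' a signal-peptide-like segment (positive n-region, hydrophobic h-region,
#' small residues at -3/-1). Remaining background transcripts encode ORFs
#' without a signal, plus a share of plain non-coding sequence.
#'
#' @param config A [simulation_config()].
#' @return List with `transcripts` (named character vector of nucleotide
#'   sequences) and `truth`, a `ground_truth` list carrying `venom_ids`,
#'   `sp_ids`, `psm_supported_ids`, `venn_labels`, plus the planted
#'   `proteins`, `cleavage_pos` and `effective_length` used by the other
#'   generators.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  ids <- sprintf("tx%05d", seq_len(n))
  venom_idx <- if (config$n_venom > 0) {
    sort(sample.int(n, config$n_venom))
  } else integer(0)
  is_venom <- seq_len(n) %in% venom_idx
  sp_bg <- !is_venom &
    stats::runif(n) < config$sp_fraction_background
  transcripts <- character(n)
  proteins <- rep(NA_character_, n)
  cleavage <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is_venom[i] || sp_bg[i]) {
      sig <- .planted_signal()
      mature <- .random_protein(sample(80:200, 1L))
      prot <- paste0(sig, mature)
      cleavage[i] <- nchar(sig)
      # resample codon/UTR choices until the planted ORF is the dominant
      # six-frame ORF, so the planted protein is what translation recovers
      for (attempt in 1:50) {
        tx <- .orf_transcript(prot)
        rec <- transcript_record(ids[i], tx)
        if (identical(predict_orf(rec), prot)) break
      }
      proteins[i] <- prot
      transcripts[i] <- tx
      next
    }
    if (stats::runif(1) < 0.8) {
      # coding background: ORF without a secretion signal; acidic start
      # keeps the n-region rule from firing spuriously
      prot <- paste0("MDE", .random_protein(sample(80:200, 1L)))
    } else {
      # non-coding background
      transcripts[i] <- paste(sample(c("A", "C", "G", "T"),
                                     sample(300:900, 1L), replace = TRUE),
                              collapse = "")
      next
    }
    proteins[i] <- prot
    transcripts[i] <- .orf_transcript(prot)
  }
  names(transcripts) <- ids
  names(proteins) <- ids
  names(cleavage) <- ids
  venom_ids <- ids[venom_idx]
  labels <- rep(c("unique", "a_only", "b_only", "both"),
                times = config$venn_design)
  names(labels) <- venom_ids
  truth <- structure(list(
    venom_ids = venom_ids,
    sp_ids = ids[is_venom | sp_bg],
    psm_supported_ids = venom_ids,
    venn_labels = labels,
    proteins = proteins,
    cleavage_pos = cleavage,
    effective_length = setNames(nchar(transcripts), ids)),
    class = "ground_truth")
  list(transcripts = transcripts, truth = truth)
}

#' Generate a two-library counts table
#'
#' Counts are drawn from a negative-binomial model around planted expected
#' FPKM levels: background genes have equal expected FPKM in both tissues;
#' venom genes have an expected venom-gland : carcass FPKM ratio of
#' `fold_change_venom` and expected venom-gland FPKM of at least 50.
#' `dispersion = 0` yields the rounded expectations exactly.
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth from [generate_transcriptome()].
#' @return data.frame with columns `id`, `count_vg`, `count_carcass`,
#'   `effective_length`, and attributes `libsize_vg` / `libsize_carcass`
#'   (the realized column sums).
#' @export
generate_counts <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  ids <- names(truth$effective_length)
  n <- length(ids)
  len <- unname(truth$effective_length)
  is_venom <- ids %in% truth$venom_ids
  base_fpkm <- stats::rlnorm(n, meanlog = log(20), sdlog = 1)
  # venom-gland expected FPKM >= 50 at the configured fold change
  base_fpkm[is_venom] <- pmax(base_fpkm[is_venom],
                              50 / config$fold_change_venom)
  fpkm_vg <- base_fpkm * ifelse(is_venom, config$fold_change_venom, 1)
  fpkm_ca <- base_fpkm
  mu_vg <- fpkm_vg * len * config$library_size_vg / 1e9
  mu_ca <- fpkm_ca * len * config$library_size_carcass / 1e9
  draw <- function(mu) {
    if (config$dispersion == 0) round(mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  out <- data.frame(id = ids, count_vg = draw(mu_vg),
                    count_carcass = draw(mu_ca),
                    effective_length = len, stringsAsFactors = FALSE)
  attr(out, "libsize_vg") <- sum(out$count_vg)
  attr(out, "libsize_carcass") <- sum(out$count_carcass)
  out
}

#' Generate a PSM table with passing venom evidence and failing decoys
#'
#' Every PSM-supported protein receives at least one PSM whose peptide is an
#' exact tryptic fragment and whose (charge, Xcorr, DeltaCn) passes the
#' default thresholds. Decoy PSMs (random peptides with sub-threshold
#' DeltaCn or Xcorr) are interleaved. Proteins with no tryptic peptide of
#' length >= 6 are skipped with a warning.
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth from [generate_transcriptome()].
#' @param proteins Named character vector of translated proteins (defaults
#'   to the planted ones in `truth`).
#' @return data.frame with columns `peptide`, `charge`, `xcorr`, `delta_cn`,
#'   `slice`.
#' @export
generate_psm_table <- function(config, truth, proteins = truth$proteins) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$seed + 2L)
  xcorr_min <- c(1.9, 2.2, 3.75)
  rows <- list()
  for (id in truth$psm_supported_ids) {
    prot <- proteins[[id]]
    if (is.na(prot)) next
    peps <- tryptic_digest(prot, missed_cleavages = 0L, min_len = 6L)
    # the mature secreted protein has its signal cleaved off: peptides
    # overlapping the signal region are never observed in the reservoir
    cp <- truth$cleavage_pos[[id]]
    if (!is.na(cp)) {
      starts <- c(1L, .tryptic_cuts(prot) + 1L)
      full <- tryptic_digest(prot, missed_cleavages = 0L, min_len = 1L)
      keep_tail <- starts > cp
      peps <- full[keep_tail & nchar(full) >= 6L]
    }
    if (length(peps) == 0L) {
      warning("protein ", id, " has no tryptic peptide of length >= 6; ",
              "skipped")
      next
    }
    k <- 1L + stats::rpois(1L, max(0, config$psm_depth - 1))
    pep <- sample(peps, k, replace = TRUE)
    charge <- sample.int(3L, k, replace = TRUE)
    rows[[id]] <- data.frame(
      peptide = pep, charge = charge,
      xcorr = xcorr_min[charge] + stats::runif(k, 0, 1.5),
      delta_cn = stats::runif(k, 0.1, 0.45),
      slice = sample.int(21L, k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  n_decoy <- max(1L, round(0.5 * sum(vapply(rows, nrow, integer(1)))))
  decoy_pep <- vapply(seq_len(n_decoy),
                      function(i) .random_protein(sample(8:14, 1L)),
                      character(1))
  decoy_charge <- sample.int(3L, n_decoy, replace = TRUE)
  low_dcn <- stats::runif(n_decoy) < 0.5
  rows[["decoys"]] <- data.frame(
    peptide = decoy_pep, charge = decoy_charge,
    xcorr = ifelse(low_dcn,
                   xcorr_min[decoy_charge] + stats::runif(n_decoy, 0, 1),
                   pmax(0.2, xcorr_min[decoy_charge] -
                          stats::runif(n_decoy, 0.3, 1.5))),
    delta_cn = ifelse(low_dcn, stats::runif(n_decoy, 0.01, 0.099),
                      stats::runif(n_decoy, 0.1, 0.45)),
    slice = sample.int(21L, n_decoy, replace = TRUE),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# one outfmt-6 row with plausible filler columns
.hit_row <- function(query, subject, bitscore) {
  len <- sample(80:300, 1L)
  data.frame(qseqid = query, sseqid = subject,
             pident = round(stats::runif(1, 30, 95), 2),
             length = len,
             mismatch = sample.int(50L, 1L), gapopen = sample.int(5L, 1L),
             qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = 10^(-bitscore / 10), bitscore = round(bitscore, 1),
             stringsAsFactors = FALSE)
}

#' Generate three homology tables realizing the planted Venn design
#'
#' Emits 12-column rows such that applying [paired_scores()] +
#' [venn_partition()] at the default cutoffs (e-value <= 1e-5, bit score
#' >= 50) recovers `truth$venn_labels` exactly: shared pairs carry bit
#' scores uniform on [55, 300], unshared pairs uniform on [20, 45], with
#' e-values derived as `10^(-bitscore/10)`. A reference-vs-reference table
#' (first reference set vs second) is also emitted for enrichment-style
#' contrasts.
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth from [generate_transcriptome()].
#' @param oep_share Fraction of reference-set-1 proteins sharing homology
#'   with reference set 2 in the third table (default 0.05).
#' @return List of data.frames `pp_vs_nv`, `pp_vs_oep`, `nv_vs_oep` in
#'   12-column format.
#' @export
generate_homology_tables <- function(config, truth, oep_share = 0.05) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$seed + 3L)
  shared_bs <- function() stats::runif(1, 55, 300)
  unshared_bs <- function() stats::runif(1, 20, 45)
  nv_rows <- list(); oep_rows <- list()
  for (id in names(truth$venn_labels)) {
    lab <- truth$venn_labels[[id]]
    nv_sub <- sprintf("NV%04d", sample.int(config$n_nv, 1L))
    oep_sub <- sprintf("OEP%04d", sample.int(200L, 1L))
    if (lab %in% c("a_only", "both")) {
      nv_rows[[id]] <- .hit_row(id, nv_sub, shared_bs())
    } else if (stats::runif(1) < 0.5) {
      nv_rows[[id]] <- .hit_row(id, nv_sub, unshared_bs())
    }
    if (lab %in% c("b_only", "both")) {
      oep_rows[[id]] <- .hit_row(id, oep_sub, shared_bs())
    } else if (stats::runif(1) < 0.5) {
      oep_rows[[id]] <- .hit_row(id, oep_sub, unshared_bs())
    }
  }
  nv_ids <- sprintf("NV%04d", seq_len(config$n_nv))
  nv_oep <- lapply(nv_ids, function(id) {
    bs <- if (stats::runif(1) < oep_share) shared_bs() else unshared_bs()
    .hit_row(id, sprintf("OEP%04d", sample.int(200L, 1L)), bs)
  })
  bindrows <- function(lst) {
    if (length(lst) == 0L) {
      return(read_outfmt6(tempfile()))  # empty 12-column frame
    }
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  list(pp_vs_nv = bindrows(nv_rows), pp_vs_oep = bindrows(oep_rows),
       nv_vs_oep = bindrows(nv_oep))
}

#' Write all synthetic inputs to a directory
#'
#' Writes `transcripts.fasta` (wrapped at 60 columns), `counts.tsv`,
#' `psms.tsv`, the three homology tables (`pp_vs_nv.tsv`, `pp_vs_oep.tsv`,
#' `nv_vs_oep.tsv`), and `truth.json`.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_inputs <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tg <- generate_transcriptome(config)
  counts <- generate_counts(config, tg$truth)
  psms <- generate_psm_table(config, tg$truth)
  hom <- generate_homology_tables(config, tg$truth)
  write_fasta(tg$transcripts, file.path(outdir, "transcripts.fasta"))
  utils::write.table(counts, file.path(outdir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(psms, file.path(outdir, "psms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(hom)) {
    utils::write.table(hom[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  truth <- tg$truth
  jsonlite::write_json(
    list(venom_ids = truth$venom_ids, sp_ids = truth$sp_ids,
         psm_supported_ids = truth$psm_supported_ids,
         venn_labels = as.list(truth$venn_labels)),
    file.path(outdir, "truth.json"), auto_unbox = TRUE)
  invisible(list(config = config, transcripts = tg$transcripts,
                 truth = truth, counts = counts, psms = psms,
                 homology = hom))
}
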