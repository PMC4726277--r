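# Evidence integration: intersects differential expression, signal-peptide
# and proteomic-confirmation evidence into the putative venom set, assigns
# rule-based functional categories, and orchestrates the full pipeline.

#' Intersect the three evidence streams
#'
#' A transcript is a venom candidate iff it is DE-flagged, has a determinate
#' positive signal-peptide call (undetermined calls are exclusions), and is
#' in the proteomically confirmed set. Candidates are sorted by descending
#' venom-gland FPKM, ties broken by id.
#'
#' @param expr Expression table ([expression_table()] output).
#' @param sp data.frame of signal calls ([call_signal_peptides()] output).
#' @param confirmed Character vector of confirmed transcript ids.
#' @param annotations Optional named character vector id -> annotation text;
#'   drives [categorize()].
#' @return data.frame: `transcript_id`, `fpkm_vg`, `de_flag`, `has_sp`,
#'   `proteomic_confirmed`, `category`, `annotation` — one row per candidate
#'   (all three evidence flags `TRUE` by construction).
#' @export
identify_venom_candidates <- function(expr, sp, confirmed,
                                      annotations = NULL) {
  has_sp <- sp$has_sp[match(expr$id, sp$transcript_id)]
  keep <- expr$de_flag & !is.na(has_sp) & has_sp &
    expr$id %in% confirmed
  n <- sum(keep)
  out <- data.frame(transcript_id = expr$id[keep],
                    fpkm_vg = expr$fpkm_vg[keep],
                    de_flag = rep(TRUE, n), has_sp = rep(TRUE, n),
                    proteomic_confirmed = rep(TRUE, n),
                    stringsAsFactors = FALSE)
  out$annotation <- if (is.null(annotations)) rep(NA_character_, n) else
    unname(annotations[out$transcript_id])
  out$category <- vapply(out$annotation, categorize, character(1))
  out <- out[order(-out$fpkm_vg, out$transcript_id), ]
  rownames(out) <- NULL
  out
}

# ordered keyword rules; first match wins. Inhibitor domains take precedence
# over enzyme words so "protease inhibitor" is not classed as an enzyme.
.category_rules <- list(
  protease_inhibitors = c("kazal", "serpin", "pacifastin", "cystatin",
                          "protease inhibitor", "peptidase inhibitor"),
  enzymes = c("protease", "proteinase", "peptidase", "lipase", "esterase",
              "phosphatase", "nuclease", "hydrolase", "deaminase",
              "transaminase", "amylase", "dehydrogenase", "transpeptidase",
              "reductase", "sulfatase", "isomerase", "kinase",
              "chymotrypsin", "trypsin", "oxidase", "transferase",
              "glucosidase", "glycosidase", "znmc"),
  recognition_binding = c("binding protein", "receptor", "gobp", "lectin",
                          "odorant-binding", "binding-protein"))

#' Rule-based functional categorization of an annotation string
#'
#' Ordered keyword rules approximating manual curation: protease-inhibitor
#' domain terms first, then enzyme terms, then recognition/binding terms.
#' Hypothetical proteins, single-letter venom proteins and empty
#' annotations are `unknown`; any other informative annotation is `others`.
#'
#' @param annotation Free-text best-hit annotation (or `NA`).
#' @return One of `"enzymes"`, `"protease_inhibitors"`,
#'   `"recognition_binding"`, `"others"`, `"unknown"`.
#' @export
#' @examples
#' categorize("serine protease 22 precursor")   # enzymes
#' categorize("venom protein U precursor")      # unknown
categorize <- function(annotation) {
  if (is.na(annotation) || !nzchar(trimws(annotation))) return("unknown")
  a <- tolower(annotation)
  for (cat in names(.category_rules)) {
    if (any(vapply(.category_rules[[cat]],
                   function(kw) grepl(kw, a, fixed = TRUE), logical(1)))) {
      return(cat)
    }
  }
  if (grepl("hypothetical", a, fixed = TRUE) ||
      grepl("venom protein [a-z]\\b", a) ||
      grepl("uncharacterized", a, fixed = TRUE)) {
    return("unknown")
  }
  "others"
}

#' Run the full identification pipeline on files in a directory
#'
#' Expects the file layout written by [simulate_inputs()]:
#' `transcripts.fasta`, `counts.tsv`, `psms.tsv`, and optionally
#' `pp_vs_nv.tsv` / `pp_vs_oep.tsv` for the comparative stage. Executes
#' expression -> signal peptide -> proteomics -> integration (-> compare),
#' writes per-stage TSVs plus a `summary.json` with the evidence counts and
#' thresholds used.
#'
#' @param indir Input directory.
#' @param outdir Output directory (default `indir`).
#' @param fpkm_min,log2_min,q_max DE thresholds (defaults 10, 1, 0.001).
#' @param min_peptides Proteomic confirmation threshold (default 1).
#' @return List with `expression`, `signal_calls`, `evidence`, `confirmed`,
#'   `candidates`, `summary`, and (when homology tables are present)
#'   `venn`.
#' @export
run_pipeline <- function(indir, outdir = indir, fpkm_min = 10,
                         log2_min = 1, q_max = 0.001, min_peptides = 1L) {
  need <- file.path(indir, c("transcripts.fasta", "counts.tsv", "psms.tsv"))
  for (f in need) if (!file.exists(f)) stop("missing input file: ", f)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  transcripts <- read_fasta(file.path(indir, "transcripts.fasta"))
  counts <- utils::read.delim(file.path(indir, "counts.tsv"),
                              stringsAsFactors = FALSE)
  psms <- read_psm_table(file.path(indir, "psms.tsv"))

  expr <- expression_table(counts, fpkm_min = fpkm_min,
                           log2_min = log2_min, q_max = q_max)
  records <- lapply(names(transcripts), function(id) {
    transcript_record(id, transcripts[[id]])
  })
  names(records) <- names(transcripts)
  proteins <- vapply(records, predict_orf, character(1))
  sp <- call_signal_peptides(records, proteins)
  passing <- filter_psms(psms)
  evidence <- map_peptides(passing$peptide, proteins)
  confirmed <- infer_proteins(evidence, min_peptides)
  candidates <- identify_venom_candidates(expr, sp, confirmed)

  utils::write.table(expr, file.path(outdir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sp, file.path(outdir, "signal_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(evidence, file.path(outdir, "protein_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(candidates, file.path(outdir, "venom_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  result <- list(expression = expr, signal_calls = sp, evidence = evidence,
                 confirmed = confirmed, candidates = candidates)

  nv_path <- file.path(indir, "pp_vs_nv.tsv")
  oep_path <- file.path(indir, "pp_vs_oep.tsv")
  if (file.exists(nv_path) && file.exists(oep_path)) {
    paired <- paired_scores(candidates$transcript_id,
                            read_outfmt6(nv_path), read_outfmt6(oep_path))
    venn <- venn_partition(paired)
    utils::write.table(venn$assignments, file.path(outdir, "venn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$paired <- paired
    result$venn <- venn
  }

  summary <- list(
    n_transcripts = length(transcripts),
    n_de = sum(expr$de_flag),
    n_sp = sum(sp$has_sp %in% TRUE),
    n_confirmed = length(confirmed),
    n_candidates = nrow(candidates),
    categories = as.list(table(candidates$category)),
    thresholds = list(fpkm_min = fpkm_min, log2_min = log2_min,
                      q_max = q_max, min_peptides = min_peptides))
  if (!is.null(result$venn)) summary$venn_counts <- as.list(result$venn$counts)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  result$summary <- summary
  result
}

#' Command-line entry point
#'
#' Dispatches `simulate` and `run-all` subcommands, e.g.
#' `Rscript -e 'venomics::venomics_main()' simulate --outdir sim --seed 7`.
#'
#' @param args Character vector of arguments (defaults to the command line).
#' @return Invisibly, the subcommand's result.
#' @export
venomics_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: venomics <simulate|run-all> [--outdir DIR] [--indir DIR]",
    "[--seed N] [--n-transcripts N] [--n-venom N]")
  if (length(args) == 0L) stop(usage, call. = FALSE)
  cmd <- args[[1L]]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[[i + 1L]] else default
  }
  outdir <- opt("--outdir", "venomics_out")
  if (cmd == "simulate") {
    cfg <- simulation_config(
      n_transcripts = as.integer(opt("--n-transcripts", "500")),
      n_venom = as.integer(opt("--n-venom", "20")),
      seed = as.integer(opt("--seed", "1")))
    res <- simulate_inputs(cfg, outdir)
    message("wrote synthetic inputs to ", outdir)
  } else if (cmd == "run-all") {
    res <- run_pipeline(opt("--indir", outdir), outdir)
    message("identified ", nrow(res$candidates), " venom candidates")
  } else {
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
  }
  invisible(res)
}
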