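# PSM filtering by charge-dependent Sequest score thresholds and mapping of
# passing peptides onto predicted proteins to produce the proteomically
# confirmed transcript set.

#' Filter peptide-spectrum matches
#'
#' A PSM passes iff `delta_cn >= dcn_min` and `xcorr >= xcorr_min[charge]`;
#' both thresholds inclusive. Charges above the highest keyed threshold use
#' that highest threshold (charge 4+ behaves like charge 3 under the
#' defaults).
#'
#' @param psms data.frame with columns `peptide`, `charge`, `xcorr`,
#'   `delta_cn` (and optionally `slice`).
#' @param dcn_min Minimum DeltaCn (default 0.1).
#' @param xcorr_min Named numeric vector of per-charge Xcorr thresholds;
#'   names are charges. Default `c("1" = 1.9, "2" = 2.2, "3" = 3.75)`.
#' @return The passing subset of `psms`.
#' @export
#' @examples
#' filter_psms(data.frame(peptide = "PEPTIDEK", charge = 2,
#'                        xcorr = 2.2, delta_cn = 0.1))
filter_psms <- function(psms, dcn_min = 0.1,
                        xcorr_min = c("1" = 1.9, "2" = 2.2, "3" = 3.75)) {
  stopifnot(all(c("peptide", "charge", "xcorr", "delta_cn") %in% names(psms)))
  if (any(psms$charge < 1)) stop("charges must be >= 1")
  known <- as.integer(names(xcorr_min))
  ch <- pmin(psms$charge, max(known))
  thr <- xcorr_min[as.character(ch)]
  if (any(is.na(thr))) stop("no Xcorr threshold for some observed charge")
  psms[psms$delta_cn >= dcn_min & psms$xcorr >= unname(thr), , drop = FALSE]
}

# is 'peptide' a tryptic fragment of 'protein' at match position 'pos'
# (1-based)? Boundaries must coincide with tryptic cut sites or termini.
.tryptic_boundaries_ok <- function(protein, peptide, pos) {
  n <- nchar(protein)
  len <- nchar(peptide)
  left_ok <- pos == 1L || {
    prev <- substring(protein, pos - 1L, pos - 1L)
    first <- substring(peptide, 1L, 1L)
    prev %in% c("K", "R") && first != "P"
  }
  end <- pos + len - 1L
  right_ok <- end == n || {
    last <- substring(peptide, len, len)
    nxt <- substring(protein, end + 1L, end + 1L)
    last %in% c("K", "R") && nxt != "P"
  }
  left_ok && right_ok
}

#' Map peptides onto a protein database
#'
#' A peptide maps to a protein iff it is an exact substring and, when
#' `enzyme_consistent`, every match position has tryptic boundaries (the
#' flanking residue is K/R not followed by P, or a protein terminus).
#' Peptides mapping to more than one protein mark all their target proteins
#' ambiguous. Leucine and isoleucine are treated as distinct.
#'
#' @param peptides Character vector of (typically filter-passing) peptides.
#' @param proteins Named character vector: transcript id -> protein string;
#'   `NA` entries (ORF no-calls) are skipped.
#' @param enzyme_consistent Require tryptic boundaries (default `TRUE`).
#' @return data.frame (one row per evidenced transcript): `transcript_id`,
#'   `n_unique_peptides`, `ambiguous`, `peptides` (semicolon-joined).
#' @export
map_peptides <- function(peptides, proteins, enzyme_consistent = TRUE) {
  proteins <- proteins[!is.na(proteins)]
  if (length(proteins) == 0L) stop("empty protein database")
  peptides <- unique(as.character(peptides))
  hit_ids <- lapply(peptides, function(pep) {
    cand <- names(proteins)[grepl(pep, proteins, fixed = TRUE)]
    if (!enzyme_consistent || length(cand) == 0L) return(cand)
    ok <- vapply(cand, function(id) {
      prot <- proteins[[id]]
      pos <- gregexpr(pep, prot, fixed = TRUE)[[1]]
      any(vapply(pos, function(p) .tryptic_boundaries_ok(prot, pep, p),
                 logical(1)))
    }, logical(1))
    cand[ok]
  })
  shared <- lengths(hit_ids) > 1L
  evid <- new.env(parent = emptyenv())
  for (k in seq_along(peptides)) {
    for (id in hit_ids[[k]]) {
      cur <- if (!is.null(evid[[id]])) evid[[id]] else
        list(peptides = character(0), ambiguous = FALSE)
      cur$peptides <- c(cur$peptides, peptides[k])
      cur$ambiguous <- cur$ambiguous || shared[k]
      evid[[id]] <- cur
    }
  }
  ids <- sort(ls(evid))
  if (length(ids) == 0L) {
    return(data.frame(transcript_id = character(0),
                      n_unique_peptides = integer(0),
                      ambiguous = logical(0), peptides = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(ids, function(id) {
    e <- evid[[id]]
    data.frame(transcript_id = id,
               n_unique_peptides = length(unique(e$peptides)),
               ambiguous = e$ambiguous,
               peptides = paste(sort(unique(e$peptides)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Infer the proteomically confirmed transcript set
#'
#' A transcript is confirmed iff it carries at least `min_peptides` distinct
#' passing peptides. Transcripts supported only by shared (ambiguous)
#' peptides are confirmed but remain flagged in the evidence table.
#'
#' @param evidence Output of [map_peptides()].
#' @param min_peptides Minimum distinct peptides (default 1).
#' @return Character vector of confirmed transcript ids.
#' @export
infer_proteins <- function(evidence, min_peptides = 1L) {
  evidence$transcript_id[evidence$n_unique_peptides >= min_peptides]
}

#' Read a PSM table
#' @param path TSV with columns `peptide`, `charge`, `xcorr`, `delta_cn`,
#'   optional `slice`.
#' @return data.frame of PSMs.
#' @export
read_psm_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "charge", "xcorr", "delta_cn") %in% names(x)))
  x
}
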