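# Secretion-signal calling: annotation transfer through best hits with
# complete N-termini, a built-in weight-matrix/hydropathy heuristic in the
# von Heijne tradition, a reader for external predictions, and cross-method
# concordance.

#' Signal-peptide call
#'
#' @param transcript_id Identifier.
#' @param has_sp `TRUE`, `FALSE`, or `NA` (undetermined).
#' @param method One of `"transfer"`, `"local"`, `"external"`.
#' @param cleavage_pos 1-based index of the last signal residue, in
#'   `[10, 40]`, or `NA`. A position requires `has_sp = TRUE`.
#' @return An object of class `signal_call` (a one-row data.frame).
#' @export
signal_call <- function(transcript_id, has_sp, method, cleavage_pos = NA) {
  method <- match.arg(method, c("transfer", "local", "external"))
  if (!is.na(cleavage_pos)) {
    if (is.na(has_sp) || !has_sp) {
      stop("cleavage_pos requires has_sp = TRUE")
    }
    if (cleavage_pos < 10 || cleavage_pos > 40) {
      stop("cleavage_pos must lie in [10, 40]")
    }
  }
  structure(data.frame(transcript_id = as.character(transcript_id),
                       has_sp = as.logical(has_sp), method = method,
                       cleavage_pos = as.integer(cleavage_pos),
                       stringsAsFactors = FALSE),
            class = c("signal_call", "data.frame"))
}

#' Complete N-terminus rule
#'
#' A transcript's translation is assumed to start at the protein's true
#' N-terminus when the best hit alignment starts at subject position 1.
#'
#' @param hit A [best_hit()] or `NULL`.
#' @return `TRUE`, `FALSE`, or `NA` when no hit is available.
#' @export
has_complete_n_terminus <- function(hit) {
  if (is.null(hit)) return(NA)
  hit$s_start == 1L
}

#' Transfer a signal-peptide call from a reference annotation
#'
#' If the transcript has a best hit whose subject appears in the reference
#' table, the reference's call is transferred; otherwise the result is
#' undetermined (`has_sp = NA`).
#'
#' @param record A [transcript_record()].
#' @param ref Reference table: data.frame with columns `subject_id`,
#'   `has_sp`, and optional `cleavage_pos` (see [read_reference_sp_table()]).
#' @return A `signal_call` row with `method = "transfer"`.
#' @export
transfer_signal_call <- function(record, ref) {
  stopifnot(inherits(record, "transcript_record"))
  hit <- record$best_hit
  if (is.null(hit) || !(hit$subject_id %in% ref$subject_id)) {
    return(signal_call(record$id, NA, "transfer"))
  }
  row <- ref[match(hit$subject_id, ref$subject_id), ]
  cp <- if ("cleavage_pos" %in% names(ref)) row$cleavage_pos else NA
  if (!isTRUE(as.logical(row$has_sp))) cp <- NA
  signal_call(record$id, as.logical(row$has_sp), "transfer", cp)
}

# Kyte-Doolittle hydropathy index
.kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2, X = 0)

#' Built-in signal-peptide heuristic
#'
#' A SignalP stand-in combining the classic three-region architecture:
#' candidate cleavage sites are scanned at positions 10..40 and a signal is
#' called when (i) the net charge of residues 1..5 is >= 0 (K/R = +1,
#' D/E = -1); (ii) some 8-residue window within residues 2..(site - 3) has
#' mean Kyte-Doolittle hydropathy >= `h_min`; and (iii) the residues at the
#' -3 and -1 positions relative to cleavage (site - 2 and site) are small
#' (A/G/S/C/T/V). The reported cleavage position is the best-scoring site
#' (maximum h-window hydropathy, earliest on ties).
#'
#' @param protein Amino-acid string (length >= 15 for a determinate call).
#' @param transcript_id Identifier carried into the call.
#' @param h_min Minimum mean window hydropathy (default 1.6).
#' @return A `signal_call` row with `method = "local"`; `has_sp = NA`
#'   (undetermined) for proteins shorter than 15 aa.
#' @export
local_signal_score <- function(protein, transcript_id = "query",
                               h_min = 1.6) {
  protein <- as.character(protein)
  if (is.na(protein) || nchar(protein) < 15L) {
    return(signal_call(transcript_id, NA, "local"))
  }
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(res)
  charge <- sum(res[1:5] %in% c("K", "R")) - sum(res[1:5] %in% c("D", "E"))
  if (charge < 0) return(signal_call(transcript_id, FALSE, "local"))
  kd <- unname(.kd[res]); kd[is.na(kd)] <- 0
  small <- c("A", "G", "S", "C", "T", "V")
  best_site <- NA_integer_; best_h <- -Inf
  for (site in 10:min(40L, n)) {
    if (!(res[site - 2L] %in% small && res[site] %in% small)) next
    hi <- site - 3L
    if (hi < 9L) next                           # need an 8-window in 2..hi
    starts <- 2:(hi - 7L)
    hmeans <- vapply(starts,
                     function(s) mean(kd[s:(s + 7L)]), numeric(1))
    h <- max(hmeans)
    if (h < h_min) next
    if (h > best_h) { best_h <- h; best_site <- site }
  }
  if (is.na(best_site)) {
    signal_call(transcript_id, FALSE, "local")
  } else {
    signal_call(transcript_id, TRUE, "local", best_site)
  }
}

#' Signal-peptide calls for a set of transcripts
#'
#' Applies annotation transfer where a reference call is available and falls
#' back to the local heuristic on the predicted protein otherwise
#' (`precedence = "transfer"`, the default) or prefers the local call
#' (`precedence = "local"`).
#'
#' @param records List of [transcript_record()]s.
#' @param proteins Named character vector of predicted proteins (may contain
#'   `NA` no-calls).
#' @param ref Optional reference table (see [transfer_signal_call()]).
#' @param precedence `"transfer"` or `"local"`.
#' @return data.frame of `signal_call` rows, one per record.
#' @export
call_signal_peptides <- function(records, proteins, ref = NULL,
                                 precedence = c("transfer", "local")) {
  precedence <- match.arg(precedence)
  rows <- lapply(records, function(rec) {
    tr <- if (!is.null(ref)) transfer_signal_call(rec, ref) else
      signal_call(rec$id, NA, "transfer")
    lc <- local_signal_score(proteins[[rec$id]], rec$id)
    first <- if (precedence == "transfer") tr else lc
    second <- if (precedence == "transfer") lc else tr
    if (!is.na(first$has_sp)) first else second
  })
  do.call(rbind, rows)
}

#' Read external signal-peptide predictions
#'
#' TSV with columns `id` (or `transcript_id`), `has_sp`, and optional
#' `cleavage_pos`; rows become calls with `method = "external"`.
#'
#' @param path Path to the predictions TSV.
#' @return data.frame of `signal_call` rows.
#' @export
read_external_sp <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  idcol <- intersect(c("transcript_id", "id"), names(x))[1]
  if (is.na(idcol)) stop("external predictions need an 'id' column")
  cp <- if ("cleavage_pos" %in% names(x)) x$cleavage_pos else
    rep(NA, nrow(x))
  do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    signal_call(x[[idcol]][i], as.logical(x$has_sp[i]), "external", cp[i])
  }))
}

#' Read a reference signal-peptide annotation table
#'
#' TSV with columns `subject_id`, `has_sp`, optional `cleavage_pos`.
#' Subject ids must be unique.
#'
#' @param path Path to the TSV.
#' @return data.frame usable as `ref` in [transfer_signal_call()].
#' @export
read_reference_sp_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "has_sp") %in% names(x)))
  if (anyDuplicated(x$subject_id)) stop("duplicate subject_id in reference")
  x$has_sp <- as.logical(x$has_sp)
  x
}

#' Concordance between two call sets
#'
#' Fraction of transcripts with equal `has_sp` among those determined in
#' both sets; undetermined pairs are excluded.
#'
#' @param calls_a,calls_b data.frames of `signal_call` rows over the same
#'   id set.
#' @return Fraction in `[0, 1]` (`NaN` if nothing is determined in both).
#' @export
concordance <- function(calls_a, calls_b) {
  ids <- intersect(calls_a$transcript_id, calls_b$transcript_id)
  if (length(ids) == 0L) stop("call sets share no transcript ids")
  a <- calls_a$has_sp[match(ids, calls_a$transcript_id)]
  b <- calls_b$has_sp[match(ids, calls_b$transcript_id)]
  keep <- !is.na(a) & !is.na(b)
  mean(a[keep] == b[keep])
}
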