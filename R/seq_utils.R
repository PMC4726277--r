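# Sequence-level computations shared by all pipeline stages: frame-guided
# translation / ORF prediction, tryptic digestion, assembly length statistics,
# and greedy redundancy clustering.

#' Transcript record
#'
#' A nucleotide sequence plus an optional best-hit annotation used for
#' frame-guided translation and annotation transfer.
#'
#' @param id Transcript identifier.
#' @param sequence Nucleotide string over the alphabet A/C/G/T/N.
#' @param best_hit Optional [best_hit()] annotation, or `NULL`.
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(id, sequence, best_hit = NULL) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("transcript '", id, "': sequence must be non-empty")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("transcript '", id, "': sequence restricted to A/C/G/T/N")
  }
  if (!is.null(best_hit) && !inherits(best_hit, "best_hit")) {
    stop("best_hit must be a best_hit object or NULL")
  }
  structure(list(id = as.character(id), sequence = sequence,
                 best_hit = best_hit),
            class = "transcript_record")
}

#' Best-hit annotation for a transcript
#'
#' Coordinates and scores of the best database hit, as produced by a
#' similarity search in 12-column tabular format. The subject start position
#' drives the complete-N-terminus rule used for signal-peptide annotation
#' transfer, and `frame` drives frame-guided translation.
#'
#' @param query_id,subject_id Identifiers.
#' @param evalue,bitscore Non-negative alignment scores.
#' @param frame Signed reading frame in -3..-1, 1..3.
#' @param q_start,q_end,s_start,s_end 1-based inclusive alignment coordinates.
#' @return An object of class `best_hit`.
#' @export
best_hit <- function(query_id, subject_id, evalue, bitscore, frame = 1L,
                     q_start = 1L, q_end = 1L, s_start = 1L, s_end = 1L) {
  frame <- as.integer(frame)
  if (!(abs(frame) %in% 1:3)) stop("frame must be in {-3..-1, 1..3}")
  if (evalue < 0 || bitscore < 0) stop("evalue and bitscore must be >= 0")
  if (q_start > q_end) stop("q_start must be <= q_end")
  if (s_start < 1) stop("s_start must be >= 1")
  structure(list(query_id = as.character(query_id),
                 subject_id = as.character(subject_id),
                 evalue = as.numeric(evalue), bitscore = as.numeric(bitscore),
                 frame = frame,
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 s_start = as.integer(s_start), s_end = as.integer(s_end)),
            class = "best_hit")
}

# codon -> amino acid lookup; stops are '*', codons containing N become 'X'
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- names(gc)
  tab
})

.revcomp <- function(sequence) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]),
               collapse = ""))
}

#' Translate a nucleotide sequence in a given reading frame
#'
#' Standard genetic code; stop codons are rendered as `*`; a trailing partial
#' codon is dropped; codons containing `N` translate to `X`.
#'
#' @param sequence Nucleotide string (A/C/G/T/N).
#' @param frame Signed frame in -3..-1, 1..3; negative frames translate the
#'   reverse complement.
#' @return Amino-acid string (possibly empty if fewer than 3 usable bases).
#' @export
#' @examples
#' translate_frame("ATGAAA", 1)   # "MK"
#' translate_frame("TTTCAT", -1)  # "MK"
translate_frame <- function(sequence, frame) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  frame <- as.integer(frame)
  if (!(abs(frame) %in% 1:3)) stop("frame must be in {-3..-1, 1..3}")
  if (frame < 0) sequence <- .revcomp(sequence)
  off <- abs(frame) - 1L
  n <- nchar(sequence) - off
  if (n < 3L) return("")
  starts <- seq.int(1L + off, by = 3L, length.out = n %/% 3L)
  codons <- substring(sequence, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# stop-free segments of a protein string: data.frame(start, end, seq) in
# amino-acid coordinates of the translated frame
.stop_free_segments <- function(protein) {
  if (!nzchar(protein)) {
    return(data.frame(start = integer(), end = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(protein, "*", fixed = TRUE)[[1]]
  lens <- nchar(parts)
  ends <- cumsum(lens + 1L) - 1L
  starts <- ends - lens + 1L
  keep <- lens > 0L
  data.frame(start = starts[keep], end = ends[keep], seq = parts[keep],
             stringsAsFactors = FALSE)
}

# trim a stop-free segment to its first Met when one exists
.require_met <- function(segment) {
  m <- regexpr("M", segment, fixed = TRUE)
  if (m > 0L) substring(segment, m) else segment
}

#' Predict the protein encoded by a transcript
#'
#' Frame-guided when a best hit is available: the transcript is translated in
#' the hit's frame and the longest stop-free segment overlapping the aligned
#' region is returned. Without a hit, all six frames are scanned and the
#' longest open reading frame is returned, trimmed to an initiator Met when the
#' segment contains one. Segments shorter than `min_aa` yield a no-call
#' (`NA_character_`), distinct from an error.
#'
#' @param record A [transcript_record()].
#' @param min_aa Minimum protein length to call (default 10 aa).
#' @return Amino-acid string without `*`, or `NA_character_` for no-call.
#' @export
predict_orf <- function(record, min_aa = 10L) {
  stopifnot(inherits(record, "transcript_record"))
  hit <- record$best_hit
  if (!is.null(hit)) {
    prot <- translate_frame(record$sequence, hit$frame)
    segs <- .stop_free_segments(prot)
    if (nrow(segs) == 0L) return(NA_character_)
    # aligned region in aa coordinates of this frame (query coords are nt)
    nlen <- nchar(record$sequence)
    qs <- hit$q_start; qe <- hit$q_end
    if (hit$frame < 0) { tmp <- qs; qs <- nlen - qe + 1L; qe <- nlen - tmp + 1L }
    off <- abs(hit$frame) - 1L
    aa_from <- max(1L, (qs - off + 2L) %/% 3L)
    aa_to <- max(aa_from, (qe - off) %/% 3L)
    overlap <- segs$start <= aa_to & segs$end >= aa_from
    cand <- if (any(overlap)) segs[overlap, , drop = FALSE] else segs
    best <- cand$seq[which.max(nchar(cand$seq))]
  } else {
    # candidate ORFs are stop-free segments trimmed to their first Met when
    # one exists; the longest trimmed candidate wins (earlier frame on tie)
    best <- ""
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      segs <- .stop_free_segments(translate_frame(record$sequence, fr))
      for (seg in segs$seq) {
        cand <- .require_met(seg)
        if (nchar(cand) > nchar(best)) best <- cand
      }
    }
  }
  if (nchar(best) < min_aa) return(NA_character_)
  best
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. With
#' `missed_cleavages = m`, all concatenations of up to `m + 1` adjacent
#' fragments are also emitted. Peptides shorter than `min_len` are excluded.
#'
#' @param protein Amino-acid string.
#' @param missed_cleavages Maximum number of missed cleavage sites (default 0).
#' @param min_len Minimum peptide length to report (default 6).
#' @return Character vector of peptides, in N- to C-terminal order of their
#'   left boundary.
#' @export
#' @examples
#' tryptic_digest("MKRAP", missed_cleavages = 0, min_len = 1)
tryptic_digest <- function(protein, missed_cleavages = 0L, min_len = 6L) {
  protein <- as.character(protein)
  if (!nzchar(protein)) stop("protein must be non-empty")
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)                       # fragment boundaries
  nfrag <- length(bounds) - 1L
  peps <- character(0)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + missed_cleavages)
    for (j in i:jmax) {
      pep <- substring(protein, bounds[i] + 1L, bounds[j + 1L])
      if (nchar(pep) >= min_len) peps <- c(peps, pep)
    }
  }
  peps
}

# tryptic cut positions (residue indices after which trypsin cleaves)
.tryptic_cuts <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(res)
  cuts <- which(res %in% c("K", "R"))
  cuts[cuts < n & res[cuts + 1L] != "P"]
}

#' Assembly length statistics
#'
#' Nx is the length L such that sequences of length >= L contain at least x%
#' of the total assembled bases (descending cumulative sum). `n_over_n50`
#' counts sequences strictly longer than N50.
#'
#' @param lengths Positive integer vector of sequence lengths (bp).
#' @return A list of class `assembly_stats` with fields `n_sequences`,
#'   `shortest`, `longest`, `n50`, `n80`, `n20`, `n_over_n50`.
#' @export
assembly_stats <- function(lengths) {
  if (length(lengths) == 0L) stop("lengths must be non-empty")
  lengths <- as.numeric(lengths)
  if (any(lengths <= 0)) stop("lengths must be positive")
  sl <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(sl)
  total <- cs[length(cs)]
  nx <- function(x) sl[which(cs >= total * x / 100)[1L]]
  n50 <- nx(50)
  structure(list(n_sequences = length(lengths),
                 shortest = min(lengths), longest = max(lengths),
                 n50 = n50, n80 = nx(80), n20 = nx(20),
                 n_over_n50 = sum(lengths > n50)),
            class = "assembly_stats")
}

# global alignment identity: exact matches / length of the shorter sequence.
# Needleman-Wunsch with match=1, mismatch=0, gap=-1; 'X' never counts as a
# match. The alignment is used solely to position matches.
.pair_identity <- function(a, b) {
  ra <- strsplit(a, "", fixed = TRUE)[[1]]
  rb <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(ra); lb <- length(rb)
  match_score <- outer(ra, rb, function(x, y) (x == y & x != "X") + 0)
  # DP over score matrix; traceback not needed: track best matches directly
  # score and matches matrices, (la+1) x (lb+1)
  score <- matrix(0, la + 1L, lb + 1L)
  matches <- matrix(0L, la + 1L, lb + 1L)
  score[, 1L] <- -(0:la); score[1L, ] <- -(0:lb)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      diag <- score[i, j] + match_score[i, j]
      up <- score[i, j + 1L] - 1
      left <- score[i + 1L, j] - 1
      best <- max(diag, up, left)
      score[i + 1L, j + 1L] <- best
      # prefer diagonal on ties so matches accumulate maximally
      matches[i + 1L, j + 1L] <-
        if (best == diag) matches[i, j] + as.integer(match_score[i, j])
        else if (best == up) matches[i, j + 1L]
        else matches[i + 1L, j]
    }
  }
  matches[la + 1L, lb + 1L] / min(la, lb)
}

#' Greedy redundancy clustering of protein sequences
#'
#' Incremental clustering in the style of greedy length-sorted tools: proteins
#' are sorted by descending length; each joins the first existing cluster
#' whose representative shares identity >= `identity_cutoff`, otherwise it
#' founds a new cluster. Identity is exact matches in a global alignment
#' divided by the shorter sequence's length; `X` never matches.
#'
#' @param proteins Named character vector (or list) of amino-acid strings.
#' @param identity_cutoff Fraction in (0, 1]; default 0.5.
#' @return A data.frame with columns `cluster_id`, `representative`, `member`.
#' @export
cluster_redundant <- function(proteins, identity_cutoff = 0.5) {
  proteins <- unlist(proteins)
  if (length(proteins) == 0L) stop("proteins must be non-empty")
  if (is.null(names(proteins))) {
    names(proteins) <- paste0("seq", seq_along(proteins))
  }
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  reps <- character(0)        # representative ids
  assignment <- integer(length(proteins))
  for (k in seq_along(proteins)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (.pair_identity(proteins[[reps[ci]]], proteins[[k]]) >=
          identity_cutoff) {
        assignment[k] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, names(proteins)[k])
      assignment[k] <- length(reps)
    }
  }
  data.frame(cluster_id = assignment,
             representative = reps[assignment],
             member = names(proteins),
             stringsAsFactors = FALSE)[order(assignment), ]
}

#' Read a FASTA file into a named character vector
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(unlist(sequences))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
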