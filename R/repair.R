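#' Globally align an amplicon read to its reference
#'
#' Needleman-Wunsch global alignment with affine gaps via
#' [Biostrings::pairwiseAlignment()], using nucleotide scoring (match +2,
#' mismatch -3, gap open 5, gap extend 2). The reverse complement of the
#' read is also aligned and the orientation with the higher score is kept.
#' Gaps in the read relative to the reference are reported as deletions
#' (left-aligned to a canonical position), gaps in the reference as
#' insertions, and mismatched aligned bases as substitutions.
#'
#' @param reference,read DNA strings over A/C/G/T/N.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return List of class `read_alignment`: `score`, `strand` ("+"/"-"),
#'   `deletions` (data frame `start`, `end`, `len`; 1-based closed
#'   reference coordinates), `insertions` (data frame `ref_pos`, `len`),
#'   `substitutions` (data frame `pos`, `ref`, `read`).
#' @export
align_read <- function(reference, read, match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 2) {
  reference <- toupper(reference)
  read <- toupper(read)
  if (!nchar(reference) || !nchar(read)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGTN]", reference) || grepl("[^ACGTN]", read)) {
    stop("sequences must contain only A/C/G/T/N", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  do_align <- function(rd) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(rd),
      subject = Biostrings::DNAString(reference),
      type = "global", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
  }
  fwd <- do_align(read)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  rev <- do_align(rc)
  strand <- if (Biostrings::score(rev) > Biostrings::score(fwd)) "-" else "+"
  aln <- if (strand == "-") rev else fwd
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  dels <- list(); inss <- list(); subs <- list()
  ref_pos <- 0L
  i <- 1L
  while (i <= length(pat)) {
    if (sub[i] != "-" && pat[i] != "-") {
      ref_pos <- ref_pos + 1L
      if (sub[i] != pat[i] && pat[i] != "N" && sub[i] != "N") {
        subs[[length(subs) + 1L]] <- data.frame(pos = ref_pos, ref = sub[i],
                                                read = pat[i])
      }
      i <- i + 1L
    } else if (pat[i] == "-") {            # gap in read: deletion
      start <- ref_pos + 1L
      len <- 0L
      while (i <= length(pat) && pat[i] == "-") {
        ref_pos <- ref_pos + 1L
        len <- len + 1L
        i <- i + 1L
      }
      dels[[length(dels) + 1L]] <- data.frame(start = start,
                                              end = start + len - 1L,
                                              len = len)
    } else {                               # gap in reference: insertion
      len <- 0L
      while (i <= length(pat) && sub[i] == "-") {
        len <- len + 1L
        i <- i + 1L
      }
      inss[[length(inss) + 1L]] <- data.frame(ref_pos = ref_pos, len = len)
    }
  }
  empty_del <- data.frame(start = integer(), end = integer(), len = integer())
  deletions <- if (length(dels)) do.call(rbind, dels) else empty_del
  if (nrow(deletions)) {
    for (j in seq_len(nrow(deletions))) {
      s <- left_align_deletion(reference, deletions$start[j], deletions$len[j])
      deletions$start[j] <- s
      deletions$end[j] <- s + deletions$len[j] - 1L
    }
  }
  structure(list(
    score = Biostrings::score(aln),
    strand = strand,
    deletions = deletions,
    insertions = if (length(inss)) do.call(rbind, inss) else
      data.frame(ref_pos = integer(), len = integer()),
    substitutions = if (length(subs)) do.call(rbind, subs) else
      data.frame(pos = integer(), ref = character(), read = character())
  ), class = "read_alignment")
}

# shift a deletion [start, start+len-1] leftwards while the base before the
# deletion equals the last deleted base (equivalent placements)
left_align_deletion <- function(reference, start, len) {
  s <- start
  while (s > 1L &&
         substring(reference, s - 1L, s - 1L) ==
         substring(reference, s + len - 1L, s + len - 1L)) {
    s <- s - 1L
  }
  s
}

#' Junction microhomology length of a deletion
#'
#' The length of the longest prefix of the deleted segment that is repeated
#' immediately after the deletion: the largest `m >= 0` such that
#' `reference[start .. start+m-1] == reference[start+len .. start+len+m-1]`
#' (1-based closed coordinates). After left-alignment of the deletion this
#' equals the junction repeat length, the microhomology evidence of
#' annealing-mediated repair.
#'
#' @param reference DNA string.
#' @param start 1-based first deleted position.
#' @param len Deletion length, bp.
#' @return Microhomology length, bp (capped at `len`).
#' @examples
#' microhomology_length("AAGTCGTCAA", start = 3, len = 3)   # deletes GTC -> 3
#' @export
microhomology_length <- function(reference, start, len) {
  n <- nchar(reference)
  if (start < 1L || len < 1L || start + len - 1L > n) {
    stop("deletion interval outside reference", call. = FALSE)
  }
  m <- 0L
  while (m < len && start + len + m <= n &&
         substring(reference, start + m, start + m) ==
         substring(reference, start + len + m, start + len + m)) {
    m <- m + 1L
  }
  m
}

# internal alias used by the read simulator
junction_microhomology <- microhomology_length

#' Classify a repair outcome from a read alignment
#'
#' Applies the amplicon-sequencing outcome rules: `intact` -- no edits;
#' `NHEJ` -- a single 1-5 bp deletion and nothing else; `MMEJ` -- a single
#' > 5 bp deletion with at least 2 bp of junction microhomology and nothing
#' else; `SSTR` -- exactly the three 1-bp donor-templated substitutions and
#' no indel. Everything else (insertions, multiple indels, deletions > 5 bp
#' with < 2 bp microhomology, deletion+substitution compounds, or
#' substitutions not matching the donor) is `other`.
#'
#' @param aln A [align_read()] result.
#' @param reference The reference string the alignment was made against.
#' @param donor_subs Optional donor substitution table (`pos`, `base`, 3
#'   rows); without it no read can be called SSTR.
#' @return List of class `repair_event`: `class`, `del_start`, `del_len`,
#'   `mh_len`, `n_subs`, `n_ins`.
#' @export
classify_event <- function(aln, reference, donor_subs = NULL) {
  stopifnot(inherits(aln, "read_alignment"))
  n_del <- nrow(aln$deletions)
  n_ins <- nrow(aln$insertions)
  n_sub <- nrow(aln$substitutions)
  del_start <- if (n_del == 1L) aln$deletions$start[1] else NA_integer_
  del_len <- if (n_del == 1L) aln$deletions$len[1] else NA_integer_
  mh <- if (n_del == 1L) {
    microhomology_length(reference, del_start, del_len)
  } else NA_integer_

  cls <- "other"
  if (n_del == 0L && n_ins == 0L && n_sub == 0L) {
    cls <- "intact"
  } else if (n_del == 1L && n_ins == 0L && n_sub == 0L) {
    if (del_len >= 1L && del_len <= 5L) {
      cls <- "NHEJ"
    } else if (del_len > 5L && mh >= 2L) {
      cls <- "MMEJ"
    }
  } else if (n_del == 0L && n_ins == 0L && n_sub == 3L &&
             !is.null(donor_subs) && nrow(donor_subs) == 3L) {
    got <- aln$substitutions[order(aln$substitutions$pos), ]
    want <- donor_subs[order(donor_subs$pos), ]
    if (all(got$pos == want$pos) &&
        all(got$read == toupper(want$base))) {
      cls <- "SSTR"
    }
  }
  structure(list(class = cls, del_start = del_start, del_len = del_len,
                 mh_len = mh, n_subs = n_sub, n_ins = n_ins),
            class = "repair_event")
}

#' Classify a set of amplicon reads
#'
#' Aligns each read to the reference ([align_read()]) and classifies the
#' outcome ([classify_event()]).
#'
#' @param reference DNA string.
#' @param reads Named character vector of read sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param donor_subs Optional donor substitution table for SSTR calling.
#' @return List with `calls` (data frame `read_id`, `class`, `del_start`,
#'   `del_len`, `mh_len`, `n_subs`, `n_ins`) and `fractions` (named class
#'   fractions over intact/NHEJ/MMEJ/SSTR/other).
#' @export
classify_reads <- function(reference, reads, donor_subs = NULL) {
  if (inherits(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read_%04d", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    ev <- classify_event(align_read(reference, reads[[i]]), reference,
                         donor_subs)
    data.frame(read_id = names(reads)[i], class = ev$class,
               del_start = ev$del_start, del_len = ev$del_len,
               mh_len = ev$mh_len, n_subs = ev$n_subs, n_ins = ev$n_ins)
  })
  calls <- do.call(rbind, rows)
  lev <- c("intact", "NHEJ", "MMEJ", "SSTR", "other")
  fractions <- prop.table(table(factor(calls$class, levels = lev)))
  list(calls = calls, fractions = stats::setNames(as.numeric(fractions), lev))
}
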