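#' Find candidate microhomology-mediated deletion sites in a reference
#'
#' Enumerates deletions `[start, start + len - 1]` (1-based, closed) such
#' that the first `mh` bases of the deleted segment are repeated immediately
#' after the deletion (junction microhomology of length >= `min_mh`) and the
#' deletion is longer than `min_del - 1` bp. These are the deletions a
#' microhomology-mediated end-joining event would produce.
#'
#' @param reference DNA string (A/C/G/T).
#' @param min_mh Minimum microhomology length, bp (default 2).
#' @param min_del Minimum deletion length, bp (default 6, i.e. > 5 bp).
#' @param max_del Maximum deletion length, bp (default 30).
#' @param center Optional position; only deletions overlapping it are kept.
#' @return Data frame with columns `start`, `len`, `mh` (one row per
#'   candidate), possibly empty.
#' @export
find_mmej_sites <- function(reference, min_mh = 2, min_del = 6,
                            max_del = 30, center = NULL) {
  ref <- strsplit(toupper(reference), "")[[1]]
  n <- length(ref)
  out <- list()
  for (start in 2:(n - min_del)) {             # keep >= 1 flanking base
    for (len in min_del:min(max_del, n - start)) {
      after <- start + len                      # first base following deletion
      m <- 0L
      while (m < len && after + m <= n && ref[start + m] == ref[after + m]) {
        m <- m + 1L
      }
      if (m >= min_mh) {
        if (is.null(center) || (start <= center && center <= start + len - 1L)) {
          out[[length(out) + 1L]] <- data.frame(start = start, len = len, mh = m)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), len = integer(), mh = integer()))
  }
  do.call(rbind, out)
}

#' Simulate Cas9 amplicon reads with known repair outcomes
#'
#' Generates reads from a reference amplicon carrying the sequence outcomes
#' of double-strand-break repair: `intact` (unedited), `NHEJ` (a single
#' 1-5 bp deletion spanning the cut site), `MMEJ` (a single > 5 bp deletion
#' whose junction carries at least 2 bp of microhomology, placed at a
#' repeat pair found in the reference), and `SSTR` (exactly the three 1-bp
#' donor-templated substitutions, no indel). True labels are stored per
#' read.
#'
#' @param reference DNA string, length >= 50.
#' @param mix Named numeric vector of class proportions over
#'   `c("intact", "NHEJ", "MMEJ", "SSTR")`; normalised to sum to 1.
#' @param donor_subs Data frame with columns `pos` (1-based reference
#'   position) and `base` (substituted base differing from the reference);
#'   exactly 3 rows. Required when `mix["SSTR"] > 0`.
#' @param n_reads Number of reads.
#' @param cut_site 1-based position of the Cas9 cut (default: midpoint);
#'   NHEJ/MMEJ deletions are placed to overlap it where possible.
#' @param seed Integer seed.
#' @return List with `reads` (named character vector of read sequences) and
#'   `truth` (data frame: `read_id`, `class`, `del_start`, `del_len`,
#'   `mh_len`).
#' @examples
#' ref <- example_amplicon()
#' sim <- simulate_repair_reads(ref, mix = c(intact = 0.5, NHEJ = 0.5),
#'                              n_reads = 10, seed = 1)
#' table(sim$truth$class)
#' @export
simulate_repair_reads <- function(reference,
                                  mix,
                                  donor_subs = NULL,
                                  n_reads = 1000,
                                  cut_site = NULL,
                                  seed = NULL) {
  reference <- toupper(reference)
  if (nchar(reference) < 50) {
    stop_config("invalid config: reference must be at least 50 bp")
  }
  if (grepl("[^ACGT]", reference)) {
    stop_config("invalid config: reference must contain only A/C/G/T")
  }
  classes <- c("intact", "NHEJ", "MMEJ", "SSTR")
  if (is.null(names(mix)) || !all(names(mix) %in% classes)) {
    stop_config("invalid config: mix must be named with %s",
                paste(classes, collapse = "/"))
  }
  full_mix <- stats::setNames(numeric(4), classes)
  full_mix[names(mix)] <- mix
  if (any(full_mix < 0) || sum(full_mix) <= 0) {
    stop_config("invalid config: mix proportions must be non-negative")
  }
  full_mix <- full_mix / sum(full_mix)
  n <- nchar(reference)
  if (is.null(cut_site)) cut_site <- n %/% 2

  if (full_mix["SSTR"] > 0) {
    if (is.null(donor_subs) || nrow(donor_subs) != 3) {
      stop_config("invalid config: SSTR requires donor_subs with exactly 3 rows")
    }
    refb <- substring(reference, donor_subs$pos, donor_subs$pos)
    if (any(donor_subs$pos < 1 | donor_subs$pos > n)) {
      stop_config("invalid config: donor positions outside reference")
    }
    if (any(toupper(donor_subs$base) == refb)) {
      stop_config("invalid config: donor bases must differ from the reference")
    }
  }
  mmej_sites <- NULL
  if (full_mix["MMEJ"] > 0) {
    mmej_sites <- find_mmej_sites(reference, center = cut_site)
    if (!nrow(mmej_sites)) {
      mmej_sites <- find_mmej_sites(reference)   # relax: anywhere
    }
    if (!nrow(mmej_sites)) {
      stop_config(paste0("reference has no >5 bp deletion with >= 2 bp ",
                         "junction microhomology: cannot generate MMEJ reads"))
    }
  }

  with_seed(seed, {
    labels <- sample(classes, n_reads, replace = TRUE, prob = full_mix)
    reads <- character(n_reads)
    del_start <- rep(NA_integer_, n_reads)
    del_len <- rep(NA_integer_, n_reads)
    mh_len <- rep(NA_integer_, n_reads)
    for (i in seq_len(n_reads)) {
      cls <- labels[i]
      if (cls == "intact") {
        reads[i] <- reference
      } else if (cls == "NHEJ") {
        len <- sample(1:5, 1)
        lo <- max(2L, cut_site - len + 1L)
        hi <- min(n - len, cut_site)
        start <- if (hi >= lo) sample(lo:hi, 1) else max(2L, min(n - len, cut_site))
        reads[i] <- paste0(substring(reference, 1, start - 1L),
                           substring(reference, start + len, n))
        del_start[i] <- start
        del_len[i] <- len
        mh_len[i] <- junction_microhomology(reference, start, len)
      } else if (cls == "MMEJ") {
        row <- mmej_sites[sample.int(nrow(mmej_sites), 1), ]
        reads[i] <- paste0(substring(reference, 1, row$start - 1L),
                           substring(reference, row$start + row$len, n))
        del_start[i] <- row$start
        del_len[i] <- row$len
        mh_len[i] <- row$mh
      } else { # SSTR
        s <- strsplit(reference, "")[[1]]
        s[donor_subs$pos] <- toupper(donor_subs$base)
        reads[i] <- paste(s, collapse = "")
      }
    }
    names(reads) <- sprintf("read_%04d", seq_len(n_reads))
    list(
      reads = reads,
      truth = data.frame(read_id = names(reads), class = labels,
                         del_start = del_start, del_len = del_len,
                         mh_len = mh_len)
    )
  })
}

#' Deterministic example amplicon
#'
#' A synthetic 201 bp amplicon used in examples and tests. It is generated
#' from a fixed seed and carries, by construction, repeat pairs near its
#' midpoint so that microhomology-mediated deletions can be simulated.
#'
#' @return A 201-character DNA string.
#' @export
example_amplicon <- function() {
  base <- with_seed(20240901, paste(sample(c("A", "C", "G", "T"), 201,
                                           replace = TRUE), collapse = ""))
  # plant a 3 bp direct repeat with 8 bp spacing around the midpoint so an
  # MMEJ-compatible deletion (11 bp, 3 bp microhomology) always exists
  s <- strsplit(base, "")[[1]]
  s[95:97] <- c("T", "A", "G")
  s[106:108] <- c("T", "A", "G")
  paste(s, collapse = "")
}
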