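test_that("junction microhomology matches manual enumeration", {
  # AAGTCGTCAA: deleting GTC (positions 3-5) leaves ...GTC... -> MH 3
  expect_equal(microhomology_length("AAGTCGTCAA", start = 3, len = 3), 3)
  # deleted prefix shares nothing with the following bases
  expect_equal(microhomology_length("AAATTTCCCG", start = 1, len = 3), 0)
})

test_that("microhomology agrees with the exhaustive prefix oracle", {
  for (seed in 1:5) {
    ref <- random_dna(40, seed = seed)
    rc <- strsplit(ref, "")[[1]]
    for (len in 1:6) {
      for (start in 1:(40 - len)) {
        expect_identical(microhomology_length(ref, start, len),
                         mh_brute_force(rc, start, len))
      }
    }
  }
})

test_that("deletion calls are left-aligned to a canonical placement", {
  # CCTAGTAGGG: deleting TAG at 3-5 or at 6-8 gives the same read
  ref <- "CCTAGTAGGG"
  read <- "CCTAGGG"
  aln <- align_read(ref, read)
  expect_equal(nrow(aln$deletions), 1)
  expect_equal(aln$deletions$start, 3)
  expect_equal(aln$deletions$len, 3)
  expect_equal(microhomology_length(ref, 3, 3), 3)
})

test_that("alignment reports edits and handles orientation", {
  ref <- random_dna(80, seed = 9)
  aln <- align_read(ref, ref)
  expect_equal(nrow(aln$deletions) + nrow(aln$insertions) +
                 nrow(aln$substitutions), 0)
  expect_identical(aln$strand, "+")

  read_del <- paste0(substring(ref, 1, 39), substring(ref, 43, 80))
  aln2 <- align_read(ref, read_del)
  expect_equal(nrow(aln2$deletions), 1)
  expect_equal(aln2$deletions$len, 3)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  aln3 <- align_read(ref, rc)
  expect_identical(aln3$strand, "-")
  expect_equal(nrow(aln3$deletions) + nrow(aln3$substitutions), 0)

  expect_error(align_read(ref, "ACGTXX"), "A/C/G/T")
})

test_that("classification implements the outcome rules", {
  ref <- example_amplicon()
  del_read <- function(start, len) {
    paste0(substring(ref, 1, start - 1), substring(ref, start + len, nchar(ref)))
  }
  # 3 bp deletion -> NHEJ
  ev <- classify_event(align_read(ref, del_read(100, 3)), ref)
  expect_identical(ev$class, "NHEJ")
  # the planted repeat: deleting 11 bp from the repeat start leaves >= 2 bp MH
  sites <- find_mmej_sites(ref)
  s <- sites[which.max(sites$mh), ]
  ev2 <- classify_event(align_read(ref, del_read(s$start, s$len)), ref)
  expect_identical(ev2$class, "MMEJ")
  expect_gte(ev2$mh_len, 2)
  # intact
  ev3 <- classify_event(align_read(ref, ref), ref)
  expect_identical(ev3$class, "intact")
  # SSTR: exactly the donor substitutions
  refc <- strsplit(ref, "")[[1]]
  donor <- data.frame(pos = c(50, 101, 150))
  donor$base <- ifelse(refc[donor$pos] == "A", "C", "A")
  rd <- refc
  rd[donor$pos] <- donor$base
  ev4 <- classify_event(align_read(ref, paste(rd, collapse = "")), ref, donor)
  expect_identical(ev4$class, "SSTR")
  # without the donor table the same read is 'other'
  ev4b <- classify_event(align_read(ref, paste(rd, collapse = "")), ref)
  expect_identical(ev4b$class, "other")
})

test_that("deletions >5 bp without 2 bp microhomology fall to 'other'", {
  # construct a 6 bp deletion whose junction has < 2 bp microhomology
  ref <- example_amplicon()
  found <- FALSE
  for (start in 20:180) {
    if (microhomology_length(ref, start, 6) < 2 &&
        left_alignment_stable(ref, start, 6)) {
      read <- paste0(substring(ref, 1, start - 1),
                     substring(ref, start + 6, nchar(ref)))
      ev <- classify_event(align_read(ref, read), ref)
      if (ev$del_len == 6) {
        expect_identical(ev$class, "other")
        found <- TRUE
        break
      }
    }
  }
  expect_true(found)
})

test_that("simulated read sets are recalled and mixed correctly", {
  ref <- example_amplicon()
  refc <- strsplit(ref, "")[[1]]
  donor <- data.frame(pos = c(60, 100, 140))
  donor$base <- ifelse(refc[donor$pos] == "A", "C", "A")
  mix <- c(intact = 0.4, NHEJ = 0.3, MMEJ = 0.2, SSTR = 0.1)
  sim <- simulate_repair_reads(ref, mix, donor_subs = donor,
                               n_reads = 400, seed = 91)
  res <- classify_reads(ref, sim$reads, donor_subs = donor)
  for (cls in names(mix)) {
    in_cls <- sim$truth$class == cls
    recall <- mean(res$calls$class[in_cls] == cls)
    expect_gte(recall, 0.99)
  }
  # class fractions track the generating mix (wide CI: 4 simultaneous tests)
  n <- length(sim$reads)
  for (cls in names(mix)) {
    ci <- binom.test(sum(res$calls$class == cls), n,
                     conf.level = 0.999)$conf.int
    expect_gte(mix[[cls]], ci[1] - 1e-9)
    expect_lte(mix[[cls]], ci[2] + 1e-9)
  }
})
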