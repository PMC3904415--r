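# In-memory read records for exercising pairing and tallying without a BAM.
mk_read <- function(qname, flag = 99L, chrom = "chr1", pos = 100L,
                    n = 100L, md = NULL, seq = NULL, qual = NULL) {
  if (is.null(seq)) seq <- strrep("A", n)
  if (is.null(md)) md <- as.character(n)
  if (is.null(qual)) qual <- rep(38L, nchar(seq))
  list(qname = qname, flag = flag, chrom = chrom, pos = pos,
       cigar = paste0(nchar(seq), "M"), md = md, seq = seq, qual = qual)
}

AMP <- data.frame(chrom = "chr1", start = 100L, end = 200L, name = "ampA",
                  stringsAsFactors = FALSE)

test_that("threshold objects validate their ranges", {
  thr <- thresholds()
  expect_equal(thr$absthresh, 2L)
  expect_equal(thr$proportionthresh, 0.15)
  expect_null(thr$qualthresh)
  expect_equal(thr$min_overlap, 0.9)
  expect_error(thresholds(proportionthresh = 1.5))
  expect_error(thresholds(absthresh = -1))
  expect_error(thresholds(min_overlap = 2))
  expect_null(thresholds(qualthresh = NA)$qualthresh)
})

test_that("mate pairing keeps complete primary pairs and counts the rest", {
  r <- function(q, flag = 99L, pos = 100L)
    mk_read(q, flag = flag, pos = pos)
  # two mates spanning the amplicon exactly -> one pair
  cp <- collect_pairs(list(r("p1"), r("p1", 147L)), AMP)
  expect_length(cp$pairs, 1L)

  # a lone read -> no pairs, singleton counted
  cp <- collect_pairs(list(r("lonely")), AMP)
  expect_length(cp$pairs, 0L)
  expect_equal(cp$stats[["singletons"]], 1L)

  # 10 well-formed pairs plus 1 singleton -> 10 pairs
  reads <- c(unlist(lapply(1:10, function(i)
    list(r(paste0("p", i)), r(paste0("p", i), 147L))), recursive = FALSE),
    list(r("odd")))
  cp <- collect_pairs(reads, AMP)
  expect_length(cp$pairs, 10L)
  expect_equal(cp$stats[["singletons"]], 1L)

  # secondary/supplementary and unpaired records are dropped up front
  cp <- collect_pairs(list(r("p1"), r("p1", 147L),
                           r("p1", flag = 355L),       # secondary
                           r("u", flag = 0L)),         # unpaired
                      AMP)
  expect_length(cp$pairs, 1L)
  expect_equal(cp$stats[["nonprimary"]], 2L)

  # three primary records under one name are ambiguous -> dropped
  cp <- collect_pairs(list(r("t"), r("t", 147L), r("t", 163L)), AMP)
  expect_length(cp$pairs, 0L)
  expect_equal(cp$stats[["multimapped_groups"]], 1L)

  # both mates must satisfy the overlap fraction
  cp <- collect_pairs(list(r("p1"), r("p1", 147L, pos = 150L)), AMP, 0.9)
  expect_length(cp$pairs, 0L)
  expect_equal(cp$stats[["low_overlap"]], 1L)
  cp <- collect_pairs(list(r("p1"), r("p1", 147L, pos = 150L)), AMP, 0)
  expect_length(cp$pairs, 1L)
})

test_that("concordance is the identity intersection with a both-mates quality gate", {
  snv <- function(q) extract_read_variants("chr1", 100L, "4M", "2A1",
                                           "ACGT", c(30L, 30L, q, 30L))
  del <- extract_read_variants("chr1", 100L, "2M1D2M", "2^A2", "ACGT",
                               rep(30L, 4))
  ins <- extract_read_variants("chr1", 100L, "2M1I2M", "4", "ACGTT",
                               rep(30L, 5))

  expect_equal(concordant_variants(snv(30L), snv(30L))$key,
               "chr1:102:SNV:A:G")
  expect_equal(nrow(concordant_variants(snv(30L), snv(30L)[0, ])), 0L)
  # quality must clear the bar in BOTH mates
  expect_equal(nrow(concordant_variants(snv(15L), snv(35L), 20)), 0L)
  expect_equal(nrow(concordant_variants(snv(25L), snv(35L), 20)), 1L)
  # deletions carry no base qualities and are exempt from the gate
  expect_equal(concordant_variants(del, del, 40)$key, del$key)
  # mixed sets intersect by identity
  v1 <- rbind(snv(30L), del)
  v2 <- rbind(del, ins)
  expect_equal(concordant_variants(v1, v2)$key, del$key)
})

test_that("tallies count concordant in-bounds variants once per pair", {
  carrier <- function(q) list(
    read1 = mk_read(q, 99L, md = "50C49"),
    read2 = mk_read(q, 147L, md = "50C49"))
  plain <- function(q) list(read1 = mk_read(q, 99L),
                            read2 = mk_read(q, 147L))
  pairs <- c(lapply(paste0("c", 1:3), carrier),
             lapply(paste0("n", 1:7), plain))
  tl <- tally_amplicon(pairs, AMP)
  expect_equal(tl$total_pairs, 10L)
  expect_equal(as.integer(tl$counts["chr1:150:SNV:C:A"]), 3L)
  expect_length(tl$counts, 1L)

  # empty input
  tl0 <- tally_amplicon(list(), AMP)
  expect_equal(tl0$total_pairs, 0L)
  expect_length(tl0$counts, 0L)

  # a concordant variant in the primer region is clipped but the pair still
  # counts in the denominator
  primer <- lapply(paste0("x", 1:5), function(q) list(
    read1 = mk_read(q, 99L, pos = 95L, md = "2C97"),
    read2 = mk_read(q, 147L, pos = 95L, md = "2C97")))
  tl <- tally_amplicon(primer, AMP)
  expect_equal(tl$total_pairs, 5L)
  expect_length(tl$counts, 0L)

  # discordant signals never reach the tally
  disc <- list(list(read1 = mk_read("d", 99L, md = "50C49"),
                    read2 = mk_read("d", 147L)))
  expect_length(tally_amplicon(disc, AMP)$counts, 0L)
})

test_that("mate order does not affect the tally", {
  carrier <- function(q) list(
    read1 = mk_read(q, 99L, md = "50C49"),
    read2 = mk_read(q, 147L, md = "50C49"))
  pairs <- lapply(paste0("c", 1:4), carrier)
  swapped <- lapply(pairs, function(p) list(read1 = p$read2,
                                            read2 = p$read1))
  expect_identical(tally_amplicon(pairs, AMP)$counts,
                   tally_amplicon(swapped, AMP)$counts)
})

test_that("threshold filtering is inclusive on count and proportion", {
  mk_tally <- function(count, total) {
    v <- extract_read_variants("chr1", 148L, "4M", "2A1", "ACGT",
                               rep(30L, 4))
    list(amplicon = AMP, counts = setNames(count, v$key),
         meta = v[, c("chrom", "pos", "kind", "ref", "alt", "key")],
         total_pairs = total)
  }
  called <- apply_thresholds(mk_tally(3L, 10L), thresholds(2, 0.15), "s")
  expect_equal(nrow(called), 1L)
  expect_equal(called$proportion, 0.3)
  expect_equal(called$pairs, 3L)

  expect_equal(nrow(apply_thresholds(mk_tally(1L, 10L),
                                     thresholds(2, 0.15), "s")), 0L)
  # degenerate thresholds pass everything observed
  expect_equal(nrow(apply_thresholds(mk_tally(3L, 10L),
                                     thresholds(0, 0), "s")), 1L)
  # boundary: exactly at both thresholds is kept
  expect_equal(nrow(apply_thresholds(mk_tally(2L, 10L),
                                     thresholds(2, 0.2), "s")), 1L)
  # nothing from an empty amplicon
  empty <- list(amplicon = AMP, counts = integer(0),
                meta = NULL, total_pairs = 0L)
  expect_equal(nrow(apply_thresholds(empty, thresholds(0, 0), "s")), 0L)
})

test_that("whole-file calling reports contract violations and empty inputs", {
  d <- fixture_dir()
  fx <- simulate_amplicon_run(d, seed = 5, n_amplicons = 2,
                              pairs_per_amplicon = c(5L, 0L),
                              sample_names = "s1")
  bam <- fx$files$bam[["s1"]]

  # amplicon on a contig missing from the BAM header -> warning, 0 pairs
  regions <- rbind(fx$regions,
                   data.frame(chrom = "chrZ", start = 0L, end = 100L,
                              name = "ghost", stringsAsFactors = FALSE))
  expect_warning(res <- call_variants_bam(bam, regions, thresholds(), "s1"),
                 "contig chrZ absent")
  expect_equal(res$coverage$pairs, c(5L, 0L, 0L))
  expect_equal(nrow(res$calls), 0L)

  # missing index is an instructive error
  unindexed <- file.path(d, "noindex.bam")
  file.copy(bam, unindexed)
  expect_error(call_variants_bam(unindexed, fx$regions, thresholds(), "s"),
               "samtools index")
  expect_error(call_variants_bam(file.path(d, "nope.bam"), fx$regions,
                                 thresholds(), "s"),
               "cannot read alignment file")
})

test_that("reads without MD tags are rejected with guidance", {
  d <- fixture_dir()
  sam <- file.path(d, "nomd.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:chr1\tLN:1000",
               paste("p1", 99, "chr1", 101, 60, "4M", "=", 101, 4,
                     "ACGT", "IIII", sep = "\t"),
               paste("p1", 147, "chr1", 101, 60, "4M", "=", 101, -4,
                     "ACGT", "IIII", sep = "\t")), sam)
  bam <- Rsamtools::asBam(sam, file.path(d, "nomd"), overwrite = TRUE)
  amp <- data.frame(chrom = "chr1", start = 100L, end = 104L, name = "a",
                    stringsAsFactors = FALSE)
  expect_error(call_variants_bam(bam, amp, thresholds(0, 0, min_overlap = 1),
                                 "s"),
               "calmd")
})
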