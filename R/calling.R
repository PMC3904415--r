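## The calling engine: pair mates by name, intersect their variant sets,
## clip to the amplicon insert, tally per amplicon, apply thresholds.

#' Construct a set of calling thresholds
#'
#' @param absthresh Minimum number of concordant read-pairs supporting a
#'   variant (inclusive). Default 2.
#' @param proportionthresh Minimum fraction of the amplicon's assigned
#'   read-pairs that must concordantly carry the variant (inclusive), in
#'   \[0, 1\]. Default 0.15.
#' @param qualthresh Minimum Phred base quality. When set, an SNV or
#'   insertion is only counted for a pair if every supporting base quality
#'   in *both* mates is at least this value; deletions carry no base
#'   qualities and are exempt. `NULL` (default) disables the filter.
#' @param min_overlap Fraction of its reference span by which each mate must
#'   overlap the amplicon insert for the pair to be assigned. Default 0.9.
#' @return A `pc_thresholds` list.
#' @export
thresholds <- function(absthresh = 2L, proportionthresh = 0.15,
                       qualthresh = NULL, min_overlap = 0.9) {
  absthresh <- as.integer(absthresh)
  stopifnot(length(absthresh) == 1L, !is.na(absthresh), absthresh >= 0L,
            length(proportionthresh) == 1L,
            proportionthresh >= 0, proportionthresh <= 1,
            length(min_overlap) == 1L,
            min_overlap >= 0, min_overlap <= 1)
  if (!is.null(qualthresh)) {
    if (length(qualthresh) != 1L || is.na(qualthresh)) qualthresh <- NULL
  }
  structure(list(absthresh = absthresh,
                 proportionthresh = proportionthresh,
                 qualthresh = qualthresh,
                 min_overlap = min_overlap),
            class = "pc_thresholds")
}

# Flag bit tests (SAM flag field).
flag_bit <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

# Fetch reads overlapping a region from an indexed BAM, as a list of
# per-read lists with the fields variant extraction needs.
fetch_reads <- function(bam, chrom, start, end) {
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(start + 1L, end)),
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = "MD")
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(list())
  seqs <- as.character(res$seq)
  quals <- as.list(methods::as(res$qual, "IntegerList"))
  chroms <- as.character(res$rname)
  md <- res$tag$MD
  lapply(seq_len(n), function(i) {
    list(qname = res$qname[i], flag = res$flag[i], chrom = chroms[i],
         pos = res$pos[i] - 1L, cigar = res$cigar[i],
         md = if (is.null(md)) NA_character_ else md[i],
         seq = seqs[i], qual = quals[[i]])
  })
}

#' Group fetched reads into amplicon-assigned mate pairs
#'
#' Keeps only primary, mapped, paired records; groups them by read name;
#' retains groups of exactly two records on the same chromosome; and keeps a
#' pair only when both mates overlap the amplicon insert by at least
#' `min_overlap` of their own reference span. Singletons, secondary and
#' supplementary records, and name groups of more than two primary records
#' are dropped and counted, never fatal.
#'
#' @param reads List of per-read lists as produced by the BAM fetch (fields
#'   `qname`, `flag`, `chrom`, `pos`, `cigar`, `md`, `seq`, `qual`).
#' @param amplicon One-row data.frame or list with `chrom`, `start`, `end`.
#' @param min_overlap Per-read overlap fraction threshold.
#' @return List with `pairs` (list of `list(read1 =, read2 =)`) and `stats`
#'   (named integer vector: fetched, singletons, multimapped_groups,
#'   low_overlap, nonprimary).
#' @export
collect_pairs <- function(reads, amplicon, min_overlap = 0.9) {
  stats <- c(fetched = length(reads), singletons = 0L,
             multimapped_groups = 0L, low_overlap = 0L, nonprimary = 0L)
  if (length(reads) == 0L) return(list(pairs = list(), stats = stats))
  flags <- vapply(reads, `[[`, integer(1), "flag")
  primary <- !flag_bit(flags, 0x4L) & flag_bit(flags, 0x1L) &
    !flag_bit(flags, 0x100L) & !flag_bit(flags, 0x800L)
  stats["nonprimary"] <- sum(!primary)
  reads <- reads[primary]
  if (length(reads) == 0L) return(list(pairs = list(), stats = stats))
  qnames <- vapply(reads, `[[`, character(1), "qname")
  groups <- split(seq_along(reads), qnames)
  pairs <- list()
  np <- 0L
  for (g in groups) {
    if (length(g) == 1L) {
      stats["singletons"] <- stats["singletons"] + 1L
      next
    }
    if (length(g) > 2L) {
      stats["multimapped_groups"] <- stats["multimapped_groups"] + 1L
      next
    }
    r1 <- reads[[g[1]]]
    r2 <- reads[[g[2]]]
    if (r1$chrom != r2$chrom) {
      stats["singletons"] <- stats["singletons"] + 1L
      next
    }
    s1 <- list(chrom = r1$chrom, start = r1$pos,
               end = r1$pos + cigar_reference_width(r1$cigar))
    s2 <- list(chrom = r2$chrom, start = r2$pos,
               end = r2$pos + cigar_reference_width(r2$cigar))
    if (!pair_assigned_to_amplicon(s1, s2, amplicon, min_overlap)) {
      stats["low_overlap"] <- stats["low_overlap"] + 1L
      next
    }
    np <- np + 1L
    pairs[[np]] <- list(read1 = r1, read2 = r2)
  }
  list(pairs = pairs, stats = stats)
}

#' Variants observed concordantly in both mates of a pair
#'
#' Intersects the two mates' variant tables by identity (chromosome,
#' position, kind, ref, alt). A variant seen in only one read is discarded:
#' under complete read-pair overlap every true variant must appear in both
#' mates, so one-read-only signals are treated as chemistry error. With a
#' quality threshold, an SNV or insertion survives only when every
#' supporting base quality in both mates is at or above it; deletions carry
#' no base qualities and are exempt.
#'
#' @param v1,v2 Variant tables of the two mates
#'   (see [extract_read_variants()]).
#' @param qualthresh Minimum Phred quality, or `NULL` to disable.
#' @return Variant table of the concordant variants (quals from the first
#'   mate).
#' @export
concordant_variants <- function(v1, v2, qualthresh = NULL) {
  shared <- intersect(v1$key, v2$key)
  if (length(shared) == 0L) return(empty_variant_table())
  keep1 <- v1[match(shared, v1$key), , drop = FALSE]
  if (!is.null(qualthresh)) {
    keep2 <- v2[match(shared, v2$key), , drop = FALSE]
    ok <- vapply(seq_along(shared), function(i) {
      if (keep1$kind[i] == "DEL") return(TRUE)
      all(keep1$quals[[i]] >= qualthresh) &&
        all(keep2$quals[[i]] >= qualthresh)
    }, logical(1))
    keep1 <- keep1[ok, , drop = FALSE]
  }
  rownames(keep1) <- NULL
  keep1
}

#' Tally concordant, in-bounds variants over an amplicon's read-pairs
#'
#' For each pair, extracts both mates' variants, intersects them (with the
#' optional quality filter), drops variants whose footprint falls outside
#' the amplicon insert, and counts each survivor once per pair. The
#' denominator `total_pairs` is the number of assigned pairs regardless of
#' whether they contributed variants.
#'
#' @param pairs List of mate pairs from [collect_pairs()].
#' @param amplicon One-row data.frame or list with `chrom`, `start`, `end`,
#'   `name`.
#' @param qualthresh Minimum Phred quality, or `NULL`.
#' @return List with `amplicon`, `counts` (named integer vector keyed by
#'   variant identity), `meta` (data.frame of the distinct variants) and
#'   `total_pairs`.
#' @export
tally_amplicon <- function(pairs, amplicon, qualthresh = NULL) {
  counts <- integer(0)
  meta <- list()
  for (p in pairs) {
    v1 <- extract_read_variants(p$read1$chrom, p$read1$pos, p$read1$cigar,
                                p$read1$md, p$read1$seq, p$read1$qual)
    v2 <- extract_read_variants(p$read2$chrom, p$read2$pos, p$read2$cigar,
                                p$read2$md, p$read2$seq, p$read2$qual)
    cc <- concordant_variants(v1, v2, qualthresh)
    if (nrow(cc) == 0L) next
    cc <- cc[variant_within_amplicon(cc, amplicon), , drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      k <- cc$key[i]
      if (is.na(counts[k])) {
        counts[k] <- 1L
        meta[[k]] <- cc[i, c("chrom", "pos", "kind", "ref", "alt", "key")]
      } else {
        counts[k] <- counts[k] + 1L
      }
    }
  }
  meta_df <- if (length(meta)) do.call(rbind, meta) else
    empty_variant_table()[, c("chrom", "pos", "kind", "ref", "alt", "key")]
  rownames(meta_df) <- NULL
  list(amplicon = amplicon, counts = counts, meta = meta_df,
       total_pairs = length(pairs))
}

#' Apply read-pair support thresholds to an amplicon tally
#'
#' A variant is called when its concordant pair count is at least
#' `absthresh` *and* its share of all assigned pairs is at least
#' `proportionthresh` (both inclusive). An amplicon with no assigned pairs
#' yields no calls.
#'
#' @param tally Result of [tally_amplicon()].
#' @param thr A [thresholds()] object.
#' @param sample Sample identifier recorded on each call.
#' @return Data.frame of calls with columns `chrom`, `pos` (0-based),
#'   `kind`, `ref`, `alt`, `key`, `sample`, `amplicon`, `pairs`,
#'   `pairs_total`, `proportion`.
#' @export
apply_thresholds <- function(tally, thr, sample) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      kind = character(), ref = character(),
                      alt = character(), key = character(),
                      sample = character(), amplicon = character(),
                      pairs = integer(), pairs_total = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE)
  if (tally$total_pairs == 0L || length(tally$counts) == 0L) return(empty)
  keys <- names(tally$counts)
  prop <- as.numeric(tally$counts) / tally$total_pairs
  keep <- tally$counts >= thr$absthresh & prop >= thr$proportionthresh
  if (!any(keep)) return(empty)
  meta <- tally$meta[match(keys[keep], tally$meta$key), , drop = FALSE]
  out <- data.frame(meta,
                    sample = sample,
                    amplicon = tally$amplicon$name,
                    pairs = as.integer(tally$counts[keep]),
                    pairs_total = tally$total_pairs,
                    proportion = prop[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call variants across all amplicons of one alignment file
#'
#' Runs the per-amplicon pipeline — regional fetch, mate pairing,
#' concordance, insert-bounds clipping, tallying, thresholding — over every
#' amplicon in turn and accumulates the calls and the per-amplicon read-pair
#' coverage report. A pair overlapping two amplicons contributes to both
#' tallies; calls carry the amplicon name, so the same variant may be
#' reported once per qualifying amplicon.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file with MD tags.
#' @param amplicons Data.frame from [read_target_regions()].
#' @param thr A [thresholds()] object.
#' @param sample Sample identifier (defaults to the file name stem).
#' @return List with `calls` (data.frame, see [apply_thresholds()]),
#'   `coverage` (data.frame: `amplicon`, `chrom`, `start`, `end`, `pairs`,
#'   in region-file order, zero-pair amplicons included) and `stats`
#'   (summed pairing counters).
#' @export
call_variants_bam <- function(bam, amplicons, thr = thresholds(),
                              sample = sub("\\.bam$", "", basename(bam))) {
  if (!file.exists(bam)) {
    stop("cannot read alignment file: ", bam, call. = FALSE)
  }
  has_index <- file.exists(paste0(bam, ".bai")) ||
    file.exists(sub("\\.bam$", ".bai", bam)) ||
    file.exists(paste0(bam, ".csi"))
  if (!has_index) {
    stop("alignment file ", bam, " has no index; ",
         "create one with 'samtools index'", call. = FALSE)
  }
  header_contigs <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  calls <- list()
  cover <- integer(nrow(amplicons))
  stats <- c(fetched = 0L, singletons = 0L, multimapped_groups = 0L,
             low_overlap = 0L, nonprimary = 0L)
  for (i in seq_len(nrow(amplicons))) {
    amp <- amplicons[i, ]
    if (!amp$chrom %in% header_contigs) {
      warning("amplicon ", amp$name, ": contig ", amp$chrom,
              " absent from ", bam, "; reported with 0 pairs",
              call. = FALSE)
      next
    }
    reads <- fetch_reads(bam, amp$chrom, amp$start, amp$end)
    cp <- collect_pairs(reads, amp, thr$min_overlap)
    stats <- stats + cp$stats
    cover[i] <- length(cp$pairs)
    tally <- tally_amplicon(cp$pairs, amp, thr$qualthresh)
    calls[[i]] <- apply_thresholds(tally, thr, sample)
  }
  calls_df <- do.call(rbind, c(calls, list(apply_thresholds(
    list(total_pairs = 0L, counts = integer(0)), thr, sample))))
  rownames(calls_df) <- NULL
  coverage <- data.frame(amplicon = amplicons$name, chrom = amplicons$chrom,
                         start = amplicons$start, end = amplicons$end,
                         pairs = cover, stringsAsFactors = FALSE)
  list(calls = calls_df, coverage = coverage, stats = stats)
}

# Deterministic output order: lexicographic (C locale) over chrom, then
# position, ref, alt, amplicon name.
sort_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt,
               calls$amplicon, method = "radix")
  out <- calls[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
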