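# Shared fixture builders and the naive brute-force oracle used to
# cross-check the caller.

fixture_dir <- function() {
  d <- tempfile("fixture")
  dir.create(d)
  d
}

# A small default study: two amplicons, one het SNV and one hom deletion.
default_planted <- function() {
  data.frame(amplicon = c(1L, 2L), offset = c(40L, 70L),
             kind = c("SNV", "DEL"), len = c(1L, 2L),
             af = c(0.5, 1.0))
}

# Naive oracle: enumerate the generator's per-pair records directly (no BAM,
# no MD decoding, no regional fetch), assign pairs to amplicons by overlap
# fraction, intersect mate variant sets, clip to the insert, tally, and
# threshold. Returns a data.frame keyed like the caller's output.
oracle_calls <- function(fixture, sample, thr = paircall::thresholds()) {
  regions <- fixture$regions
  pairs <- fixture$samples[[sample]]$pairs
  out <- list()
  for (ai in seq_len(nrow(regions))) {
    amp <- regions[ai, ]
    counts <- integer(0)
    meta <- list()
    total <- 0L
    for (p in pairs) {
      f1 <- paircall::overlap_fraction(fixture$chrom, p$interval1[1],
                                       p$interval1[2], amp$chrom,
                                       amp$start, amp$end)
      f2 <- paircall::overlap_fraction(fixture$chrom, p$interval2[1],
                                       p$interval2[2], amp$chrom,
                                       amp$start, amp$end)
      if (f1 < thr$min_overlap || f2 < thr$min_overlap) next
      total <- total + 1L
      shared <- intersect(p$v1$key, p$v2$key)
      for (k in shared) {
        v <- p$v1[p$v1$key == k, ]
        inb <- if (v$kind == "INS") {
          v$pos >= amp$start && v$pos < amp$end - 1L
        } else {
          v$pos >= amp$start && v$pos + nchar(v$ref) <= amp$end
        }
        if (!inb) next
        if (is.na(counts[k])) {
          counts[k] <- 1L
          meta[[k]] <- v
        } else {
          counts[k] <- counts[k] + 1L
        }
      }
    }
    if (total == 0L || length(counts) == 0L) next
    for (k in names(counts)) {
      if (counts[k] >= thr$absthresh &&
          counts[k] / total >= thr$proportionthresh) {
        out[[length(out) + 1L]] <- data.frame(
          meta[[k]][, c("chrom", "pos", "kind", "ref", "alt", "key")],
          amplicon = amp$name, pairs = as.integer(counts[k]),
          pairs_total = total, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      kind = character(), ref = character(),
                      alt = character(), key = character(),
                      amplicon = character(), pairs = integer(),
                      pairs_total = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$key, res$amplicon, method = "radix"), ]
  rownames(res) <- NULL
  res
}

# Canonical comparable form of a caller call set.
call_signature <- function(calls) {
  if (nrow(calls) == 0L) return(character(0))
  sort(paste(calls$amplicon, calls$key, calls$pairs, calls$pairs_total))
}
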