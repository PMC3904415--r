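## Synthetic amplicon data generator: random reference, planted germline
## variants, fully overlapping read-pairs with independent per-mate errors,
## correct CIGAR/MD tags, and an exact truth table for validation.

BASES <- c("A", "C", "G", "T")

# One amplicon molecule is modelled as parallel per-column vectors:
#   op   "M"/"D"/"I"; refb reference base (NA for I); readb read base
#   (NA for D); posv reference position (NA for I).

apply_planted_to_columns <- function(cols, planted_rows, carries) {
  for (j in order(planted_rows$pos, decreasing = TRUE)) {
    if (!carries[j]) next
    v <- planted_rows[j, ]
    idx <- which(cols$posv == v$pos & cols$op != "I")
    if (v$kind == "SNV") {
      cols$readb[idx] <- v$alt
    } else if (v$kind == "DEL") {
      del_idx <- idx:(idx + nchar(v$ref) - 1L)
      cols$op[del_idx] <- "D"
      cols$readb[del_idx] <- NA_character_
    } else { # INS after the anchor column
      alt <- strsplit(v$alt, "", fixed = TRUE)[[1]]
      n <- length(cols$op)
      ins <- list(op = rep("I", length(alt)),
                  refb = rep(NA_character_, length(alt)),
                  readb = alt,
                  posv = rep(NA_integer_, length(alt)))
      for (f in names(cols)) {
        cols[[f]] <- append(cols[[f]], ins[[f]], after = idx)
      }
      stopifnot(length(cols$op) == n + length(alt))
    }
  }
  cols
}

# Take the first (forward) or last (reverse) `read_length` read bases of the
# molecule, mirroring a sequencer that reads through the proximal primer,
# the insert, and into the distal primer.
slice_mate <- function(cols, read_length, from_start) {
  consuming <- cols$op %in% c("M", "I")
  total <- sum(consuming)
  rl <- min(read_length, total)
  cum <- cumsum(consuming)
  if (from_start) {
    idx <- seq_len(min(which(cum == rl)))
  } else {
    idx <- min(which(cum == total - rl + 1L)):length(cols$op)
  }
  lapply(cols, `[`, idx)
}

# Walk a mate's columns with SAM semantics (reference cursor from the first
# reference-consuming column) and report its variants. This is the
# generator's own bookkeeping path, independent of MD-tag decoding.
mate_variants_from_columns <- function(chrom, cols) {
  pos0 <- cols$posv[match(TRUE, cols$op %in% c("M", "D"))]
  refpos <- pos0
  out <- list()
  n_out <- 0L
  i <- 1L
  n <- length(cols$op)
  while (i <= n) {
    op <- cols$op[i]
    run <- i
    while (run < n && cols$op[run + 1L] == op && op != "M") run <- run + 1L
    if (op == "M") {
      if (!is.na(cols$readb[i]) && cols$readb[i] != cols$refb[i]) {
        n_out <- n_out + 1L
        out[[n_out]] <- data.frame(
          chrom = chrom, pos = refpos, kind = "SNV",
          ref = cols$refb[i], alt = cols$readb[i],
          stringsAsFactors = FALSE)
      }
      refpos <- refpos + 1L
      i <- i + 1L
    } else if (op == "D") {
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        chrom = chrom, pos = refpos, kind = "DEL",
        ref = paste(cols$refb[i:run], collapse = ""), alt = "-",
        stringsAsFactors = FALSE)
      refpos <- refpos + (run - i + 1L)
      i <- run + 1L
    } else { # I
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        chrom = chrom, pos = refpos - 1L, kind = "INS", ref = "-",
        alt = paste(cols$readb[i:run], collapse = ""),
        stringsAsFactors = FALSE)
      i <- run + 1L
    }
  }
  if (n_out == 0L) {
    df <- empty_variant_table()[, c("chrom", "pos", "kind", "ref", "alt",
                                    "key")]
  } else {
    df <- do.call(rbind, out)
    df$key <- variant_key(df$chrom, df$pos, df$kind, df$ref, df$alt)
  }
  list(pos = pos0, ref_width = sum(cols$op %in% c("M", "D")),
       variants = df)
}

cigar_from_columns <- function(cols) {
  r <- rle(cols$op)
  paste0(r$lengths, r$values, collapse = "")
}

md_from_columns <- function(cols) {
  parts <- character(0)
  nmatch <- 0L
  i <- 1L
  n <- length(cols$op)
  while (i <= n) {
    op <- cols$op[i]
    if (op == "I") {
      i <- i + 1L
    } else if (op == "M") {
      if (cols$readb[i] == cols$refb[i]) {
        nmatch <- nmatch + 1L
      } else {
        parts <- c(parts, as.character(nmatch), cols$refb[i])
        nmatch <- 0L
      }
      i <- i + 1L
    } else { # D run
      run <- i
      while (run < n && cols$op[run + 1L] == "D") run <- run + 1L
      parts <- c(parts, as.character(nmatch),
                 paste0("^", paste(cols$refb[i:run], collapse = "")))
      nmatch <- 0L
      i <- run + 1L
    }
  }
  paste(c(parts, as.character(nmatch)), collapse = "")
}

resolve_planted <- function(planted, regions, refchars, insert_length) {
  if (is.null(planted) || nrow(planted) == 0L) {
    return(data.frame(amplicon = integer(), amplicon_name = character(),
                      pos = integer(), kind = character(),
                      ref = character(), alt = character(), af = numeric(),
                      key = character(), stringsAsFactors = FALSE))
  }
  if (is.null(planted$len)) planted$len <- 1L
  if (is.null(planted$alt)) planted$alt <- NA_character_
  out <- vector("list", nrow(planted))
  for (j in seq_len(nrow(planted))) {
    p <- planted[j, ]
    stopifnot(p$kind %in% c("SNV", "INS", "DEL"), p$af >= 0, p$af <= 1,
              p$amplicon >= 1L, p$amplicon <= nrow(regions))
    istart <- regions$start[p$amplicon]
    pos <- istart + as.integer(p$offset)
    bad <- switch(p$kind,
      SNV = p$offset < 0L || p$offset >= insert_length,
      INS = p$offset < 0L || p$offset >= insert_length - 1L,
      DEL = p$offset < 0L || p$offset + p$len > insert_length)
    if (bad) {
      stop("planted ", p$kind, " at offset ", p$offset,
           " falls outside the insert of amplicon ", p$amplicon,
           call. = FALSE)
    }
    ref <- switch(p$kind,
      SNV = refchars[pos + 1L],
      INS = "-",
      DEL = paste(refchars[(pos + 1L):(pos + p$len)], collapse = ""))
    alt <- p$alt
    if (is.na(alt)) {
      alt <- switch(p$kind,
        SNV = sample(setdiff(BASES, ref), 1L),
        INS = paste(sample(BASES, p$len, replace = TRUE), collapse = ""),
        DEL = "-")
    }
    if (p$kind == "SNV" && alt == ref) {
      stop("planted SNV alt equals the reference base at position ", pos,
           call. = FALSE)
    }
    out[[j]] <- data.frame(
      amplicon = as.integer(p$amplicon),
      amplicon_name = regions$name[p$amplicon],
      pos = pos, kind = p$kind, ref = ref, alt = alt, af = p$af,
      key = variant_key(regions$chrom[p$amplicon], pos, p$kind, ref, alt),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a complete short-insert amplicon sequencing study
#'
#' Generates a random reference, a BED file of amplicon insert intervals,
#' and per-sample sorted/indexed BAM files of read-pairs in which both
#' mates span the identical amplicon molecule in opposite orientations —
#' the complete read-pair overlap regime. Germline variants can be planted
#' at chosen allele fractions (0.5 emulates a heterozygote, 1.0 a
#' homozygote); each pair draws its molecule's alleles independently, both
#' mates share that molecule's content, and independent per-base
#' substitution errors are then injected into each mate, emulating
#' sequencing-chemistry error. CIGAR and MD tags are computed exactly
#' against the generated reference.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; fixed seed gives byte-reproducible output.
#' @param n_amplicons Number of amplicons, laid head-to-tail on one contig.
#' @param insert_length Insert (primer-intervening) length in bases; must
#'   not exceed `read_length`.
#' @param read_length Sequenced read length in bases; must cover one primer
#'   plus the whole insert so every mate spans the insert.
#' @param primer_length Length of each flanking primer in bases. The
#'   default geometry (140/150/5) keeps each mate's insert-overlap fraction
#'   at 140/150 > 0.9, the caller's default assignment threshold.
#' @param pairs_per_amplicon Read-pairs per amplicon; recycled across
#'   amplicons, so a vector can give some amplicons zero coverage.
#' @param planted Data.frame of variants to plant, with columns `amplicon`
#'   (1-based index), `offset` (0-based within the insert; for insertions,
#'   the anchor base), `kind` (`"SNV"`, `"INS"`, `"DEL"`), `af` (allele
#'   fraction), and optionally `len` and `alt`. Alleles are drawn randomly
#'   when `alt` is omitted. A footprint outside the insert is an error.
#' @param error_rate Independent per-base substitution probability per mate.
#' @param base_quality Constant Phred quality assigned to bases.
#' @param low_quality,low_quality_rate Optional two-point quality mixture:
#'   each base independently receives `low_quality` with probability
#'   `low_quality_rate`.
#' @param sample_names Character vector; one BAM per sample.
#' @param chrom Contig name.
#' @param gap,margin Bases between amplicons and at contig ends.
#' @return An `amplicon_fixture` list: `dir`, `chrom`, `reference` (one
#'   string), `regions` (BED content as a data.frame), `planted` (resolved
#'   alleles and keys), `files` (paths: `reference`, `regions`, named `sam`
#'   and `bam` vectors), and per-sample `samples[[s]]` with `truth` (exact
#'   concordant pair count per planted variant) and `pairs` (per-pair
#'   records: mate intervals and each mate's variant table, the ground
#'   truth for oracle comparisons).
#' @export
simulate_amplicon_run <- function(dir, seed = 1L, n_amplicons = 2L,
                                  insert_length = 140L, read_length = 150L,
                                  primer_length = 5L,
                                  pairs_per_amplicon = 20L, planted = NULL,
                                  error_rate = 0, base_quality = 38L,
                                  low_quality = NULL, low_quality_rate = 0,
                                  sample_names = "sample1",
                                  chrom = "chr1", gap = 30L, margin = 50L) {
  insert_length <- as.integer(insert_length)
  read_length <- as.integer(read_length)
  primer_length <- as.integer(primer_length)
  if (insert_length > read_length) {
    stop("insert_length must not exceed read_length (complete read-pair ",
         "overlap requires the insert to fit in one read)", call. = FALSE)
  }
  if (read_length < primer_length + insert_length) {
    stop("read_length must be at least primer_length + insert_length so ",
         "each mate spans the whole insert", call. = FALSE)
  }
  stopifnot(error_rate >= 0, error_rate <= 1,
            low_quality_rate >= 0, low_quality_rate <= 1,
            n_amplicons >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(as.integer(seed))

  span <- insert_length + 2L * primer_length
  ref_len <- 2L * margin + n_amplicons * span + (n_amplicons - 1L) * gap
  refchars <- sample(BASES, ref_len, replace = TRUE)
  insert_starts <- margin + (seq_len(n_amplicons) - 1L) * (span + gap) +
    primer_length
  regions <- data.frame(chrom = chrom, start = insert_starts,
                        end = insert_starts + insert_length,
                        name = sprintf("amplicon_%02d",
                                       seq_len(n_amplicons)),
                        stringsAsFactors = FALSE)
  npairs <- rep_len(as.integer(pairs_per_amplicon), n_amplicons)

  ref_path <- file.path(dir, "reference.fa")
  refseq <- paste(refchars, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(refseq, chrom)), ref_path)
  bed_path <- file.path(dir, "regions.bed")
  utils::write.table(regions, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  planted_res <- resolve_planted(planted, regions, refchars, insert_length)

  draw_quals <- function(n) {
    q <- rep(as.integer(base_quality), n)
    if (!is.null(low_quality) && low_quality_rate > 0) {
      low <- stats::runif(n) < low_quality_rate
      q[low] <- as.integer(low_quality)
    }
    q
  }
  inject_errors <- function(cols) {
    readable <- which(cols$op %in% c("M", "I"))
    err <- readable[stats::runif(length(readable)) < error_rate]
    for (i in err) {
      cols$readb[i] <- sample(setdiff(BASES, cols$readb[i]), 1L)
    }
    cols
  }
  sam_record <- function(qname, flag, pos0, mpos0, cigar, md, nm, seq,
                         qual, tlen) {
    paste(qname, flag, chrom, pos0 + 1L, 60L, cigar, "=", mpos0 + 1L,
          tlen, seq, intToUtf8(qual + 33L),
          paste0("NM:i:", nm), paste0("MD:Z:", md), sep = "\t")
  }

  samples <- list()
  sam_paths <- character(0)
  bam_paths <- character(0)
  for (s in sample_names) {
    sam_lines <- c("@HD\tVN:1.6\tSO:unsorted",
                   paste0("@SQ\tSN:", chrom, "\tLN:", ref_len))
    pair_records <- list()
    truth_counts <- stats::setNames(
      rep(0L, nrow(planted_res)),
      if (nrow(planted_res)) paste(planted_res$amplicon,
                                   planted_res$key) else character(0))
    amp_totals <- integer(n_amplicons)
    for (ai in seq_len(n_amplicons)) {
      amp <- regions[ai, ]
      span_start <- amp$start - primer_length
      span_end <- amp$end + primer_length
      base_cols <- list(op = rep("M", span),
                        refb = refchars[(span_start + 1L):span_end],
                        readb = refchars[(span_start + 1L):span_end],
                        posv = span_start:(span_end - 1L))
      amp_planted <- planted_res[planted_res$amplicon == ai, , drop = FALSE]
      amp_totals[ai] <- npairs[ai]
      for (pi in seq_len(npairs[ai])) {
        carries <- stats::runif(nrow(amp_planted)) < amp_planted$af
        cols <- apply_planted_to_columns(base_cols, amp_planted, carries)
        m1 <- inject_errors(slice_mate(cols, read_length, TRUE))
        m2 <- inject_errors(slice_mate(cols, read_length, FALSE))
        mv1 <- mate_variants_from_columns(chrom, m1)
        mv2 <- mate_variants_from_columns(chrom, m2)
        q1 <- draw_quals(sum(m1$op %in% c("M", "I")))
        q2 <- draw_quals(sum(m2$op %in% c("M", "I")))
        qname <- sprintf("%s_a%02d_p%04d", s, ai, pi)
        seq1 <- paste(m1$readb[m1$op != "D"], collapse = "")
        seq2 <- paste(m2$readb[m2$op != "D"], collapse = "")
        tlen <- max(mv1$pos + mv1$ref_width, mv2$pos + mv2$ref_width) -
          min(mv1$pos, mv2$pos)
        sam_lines <- c(sam_lines,
          sam_record(qname, 99L, mv1$pos, mv2$pos,
                     cigar_from_columns(m1), md_from_columns(m1),
                     sum(m1$op == "M" & m1$readb != m1$refb) +
                       sum(m1$op != "M"), seq1, q1, tlen),
          sam_record(qname, 147L, mv2$pos, mv1$pos,
                     cigar_from_columns(m2), md_from_columns(m2),
                     sum(m2$op == "M" & m2$readb != m2$refb) +
                       sum(m2$op != "M"), seq2, q2, -tlen))
        conc <- intersect(mv1$variants$key, mv2$variants$key)
        if (nrow(amp_planted)) {
          hit <- amp_planted$key %in% conc
          truth_counts[paste(ai, amp_planted$key)] <-
            truth_counts[paste(ai, amp_planted$key)] + as.integer(hit)
        }
        pair_records[[length(pair_records) + 1L]] <- list(
          qname = qname, amplicon = ai, amplicon_name = amp$name,
          interval1 = c(mv1$pos, mv1$pos + mv1$ref_width),
          interval2 = c(mv2$pos, mv2$pos + mv2$ref_width),
          v1 = mv1$variants, v2 = mv2$variants,
          q1 = q1, q2 = q2)
      }
    }
    sam_path <- file.path(dir, paste0(s, ".sam"))
    writeLines(sam_lines, sam_path)
    bam_path <- Rsamtools::asBam(sam_path, file.path(dir, s),
                                 overwrite = TRUE)
    sam_paths[s] <- sam_path
    bam_paths[s] <- bam_path
    truth <- if (nrow(planted_res)) {
      data.frame(planted_res[, c("amplicon", "amplicon_name", "pos",
                                 "kind", "ref", "alt", "af", "key")],
                 chrom = chrom,
                 pairs = as.integer(truth_counts),
                 pairs_total = amp_totals[planted_res$amplicon],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(amplicon = integer(), amplicon_name = character(),
                 pos = integer(), kind = character(), ref = character(),
                 alt = character(), af = numeric(), key = character(),
                 chrom = character(), pairs = integer(),
                 pairs_total = integer(), stringsAsFactors = FALSE)
    }
    samples[[s]] <- list(truth = truth, pairs = pair_records,
                         amp_totals = amp_totals)
  }

  structure(list(dir = dir, chrom = chrom, reference = refseq,
                 regions = regions, planted = planted_res,
                 files = list(reference = ref_path, regions = bed_path,
                              sam = sam_paths, bam = bam_paths),
                 params = list(seed = seed, insert_length = insert_length,
                               read_length = read_length,
                               primer_length = primer_length,
                               error_rate = error_rate,
                               base_quality = base_quality),
                 samples = samples),
            class = "amplicon_fixture")
}

#' Expected calls implied by a fixture's truth table
#'
#' Applies the same inclusive count and proportion arithmetic as the caller
#' to the generator's exact concordant-pair counts, yielding the call set
#' the caller must reproduce. Computed entirely from generation-time
#' bookkeeping, independent of any BAM parsing.
#'
#' @param fixture An `amplicon_fixture`.
#' @param sample Sample name within the fixture.
#' @param thr A [thresholds()] object. (`qualthresh` is not modelled:
#'   truth comparisons are meaningful for constant-quality fixtures at or
#'   above any threshold in use.)
#' @return Data.frame of expected calls: `amplicon_name`, `chrom`, `pos`,
#'   `kind`, `ref`, `alt`, `key`, `pairs`, `pairs_total`, `proportion`.
#' @export
truth_expected_calls <- function(fixture, sample = names(fixture$samples)[1],
                                 thr = thresholds()) {
  truth <- fixture$samples[[sample]]$truth
  keep <- truth$pairs >= max(1L, thr$absthresh) &
    truth$pairs / pmax(1L, truth$pairs_total) >= thr$proportionthresh &
    truth$pairs_total > 0L
  out <- truth[keep, c("amplicon_name", "chrom", "pos", "kind", "ref",
                       "alt", "key", "pairs", "pairs_total"), drop = FALSE]
  out$proportion <- out$pairs / out$pairs_total
  rownames(out) <- NULL
  out
}
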