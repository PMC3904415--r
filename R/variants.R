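## Per-read variant extraction: recover the aligned reference from CIGAR + MD,
## then walk the alignment emitting SNVs, insertions and deletions.

# Variant tables are plain data.frames with columns
#   chrom, pos (0-based), kind ("SNV"|"INS"|"DEL"), ref, alt, key,
#   quals (list column of integer Phred scores of the alt bases; empty for DEL)
# Identity for tallying is `key` = chrom:pos:kind:ref:alt; quals are excluded.

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), kind = character(),
             ref = character(), alt = character(), key = character(),
             quals = I(list()), stringsAsFactors = FALSE)
}

variant_key <- function(chrom, pos, kind, ref, alt) {
  paste(chrom, pos, kind, ref, alt, sep = ":")
}

variant_row <- function(chrom, pos, kind, ref, alt, quals) {
  data.frame(chrom = chrom, pos = as.integer(pos), kind = kind,
             ref = ref, alt = alt,
             key = variant_key(chrom, pos, kind, ref, alt),
             quals = I(list(as.integer(quals))), stringsAsFactors = FALSE)
}

# Tokenise a CIGAR string into an op/length table. Padding ('P') is rejected:
# it never occurs in amplicon data and silently ignoring it would miscount.
parse_cigar <- function(cigar) {
  if (length(cigar) != 1L || is.na(cigar) || !nzchar(cigar) || cigar == "*") {
    stop("read has no usable CIGAR string", call. = FALSE)
  }
  op <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  len <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  if (any(op == "P")) {
    stop("padded alignments (CIGAR 'P') are not supported", call. = FALSE)
  }
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

# Width of the alignment on the reference (M/D/N/=/X columns).
cigar_reference_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

md_tokens <- function(md) {
  if (length(md) != 1L || is.na(md) || !nzchar(md)) {
    stop("read has no MD tag; regenerate alignments with MD tags ",
         "(e.g. 'samtools calmd')", call. = FALSE)
  }
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  if (sum(nchar(toks)) != nchar(md)) {
    stop("malformed MD string: ", md, call. = FALSE)
  }
  toks
}

#' Recover the aligned reference sequence from CIGAR, MD and read bases
#'
#' Reconstructs the reference bases covered by an alignment (match/mismatch
#' and deletion columns, in reference order) without a reference FASTA:
#' matched-run lengths in the MD tag copy the read base, MD mismatch letters
#' supply the true reference base, and `^`-prefixed runs supply deleted
#' reference bases. Inserted and soft-clipped read bases contribute nothing.
#'
#' @param cigar CIGAR string (or a parsed op/len data.frame).
#' @param md MD tag string, e.g. `"2A1"` or `"2^A2"`.
#' @param seq Read base string, same orientation as stored in the alignment.
#' @return Single string of reference bases for the aligned span.
#' @details Errors if the MD runs do not exactly tile the aligned columns
#'   implied by the CIGAR (a corrupt or mismatched tag).
#' @examples
#' decode_reference("4M", "2A1", "ACGT")    # "ACAT"
#' decode_reference("2M1D2M", "2^A2", "ACGT") # "ACAGT"
#' @export
decode_reference <- function(cigar, md, seq) {
  cig <- if (is.data.frame(cigar)) cigar else parse_cigar(cigar)
  ops <- rep(cig$op, cig$len)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  consumes_read <- ops %in% c("M", "I", "S", "=", "X")
  if (sum(consumes_read) != length(bases)) {
    stop("CIGAR read length (", sum(consumes_read),
         ") does not match sequence length (", length(bases), ")",
         call. = FALSE)
  }
  read_at <- rep(NA_character_, length(ops))
  read_at[consumes_read] <- bases
  keep <- ops %in% c("M", "=", "X", "D")
  col_op <- ops[keep]
  col_op[col_op %in% c("=", "X")] <- "M"
  col_read <- read_at[keep]

  toks <- md_tokens(md)
  ref <- character(length(col_op))
  i <- 1L
  bad <- function() {
    stop("MD string '", md, "' does not tile the aligned columns of CIGAR",
         call. = FALSE)
  }
  for (tok in toks) {
    first <- substr(tok, 1L, 1L)
    if (first >= "0" && first <= "9") {
      n <- as.integer(tok)
      if (n > 0L) {
        if (i + n - 1L > length(col_op)) bad()
        idx <- i:(i + n - 1L)
        if (any(col_op[idx] != "M")) bad()
        ref[idx] <- col_read[idx]
        i <- i + n
      }
    } else if (first == "^") {
      del <- strsplit(toupper(substring(tok, 2L)), "", fixed = TRUE)[[1]]
      n <- length(del)
      if (i + n - 1L > length(col_op)) bad()
      idx <- i:(i + n - 1L)
      if (any(col_op[idx] != "D")) bad()
      ref[idx] <- del
      i <- i + n
    } else {
      if (i > length(col_op) || col_op[i] != "M") bad()
      ref[i] <- toupper(tok)
      i <- i + 1L
    }
  }
  if (i != length(col_op) + 1L) bad()
  paste(ref, collapse = "")
}

#' Extract the variants implied by a single mapped read
#'
#' Walks the CIGAR with a reference cursor (starting at `pos`) and a read
#' cursor, comparing read bases against the reference recovered by
#' [decode_reference()]. Each mismatching aligned column yields an SNV
#' carrying that base's quality; each insertion run yields one insertion
#' anchored at the reference base immediately to its left, carrying the
#' inserted bases' qualities; each deletion run yields one deletion of the
#' removed reference bases (no base qualities). Soft/hard clips and reference
#' skips are non-variant.
#'
#' @param chrom Chromosome name of the alignment.
#' @param pos 0-based leftmost reference position of the alignment.
#' @param cigar CIGAR string.
#' @param md MD tag string.
#' @param seq Read bases as stored in the alignment record.
#' @param qual Integer Phred qualities, one per base of `seq`.
#' @return A variant table (data.frame; see [concordant_variants()]); zero
#'   rows when the read matches the reference exactly.
#' @examples
#' extract_read_variants("chr1", 100L, "4M", "2A1", "ACGT",
#'                       c(30L, 30L, 25L, 30L))
#' @export
extract_read_variants <- function(chrom, pos, cigar, md, seq, qual) {
  cig <- parse_cigar(cigar)
  refstr <- decode_reference(cig, md, seq)
  refb <- strsplit(refstr, "", fixed = TRUE)[[1]]
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(qual) != length(bases)) {
    stop("quality vector length (", length(qual),
         ") does not match sequence length (", length(bases), ")",
         call. = FALSE)
  }
  out <- list()
  n_out <- 0L
  refpos <- as.integer(pos)   # reference coordinate of next aligned column
  readpos <- 1L               # next read base
  ri <- 1L                    # next decoded-reference base (M and D columns)
  for (k in seq_len(nrow(cig))) {
    op <- cig$op[k]
    len <- cig$len[k]
    if (op %in% c("M", "=", "X")) {
      rseg <- refb[ri:(ri + len - 1L)]
      qseg <- bases[readpos:(readpos + len - 1L)]
      for (m in which(rseg != qseg)) {
        n_out <- n_out + 1L
        out[[n_out]] <- variant_row(chrom, refpos + m - 1L, "SNV",
                                    rseg[m], qseg[m],
                                    qual[readpos + m - 1L])
      }
      refpos <- refpos + len
      readpos <- readpos + len
      ri <- ri + len
    } else if (op == "I") {
      idx <- readpos:(readpos + len - 1L)
      n_out <- n_out + 1L
      out[[n_out]] <- variant_row(chrom, refpos - 1L, "INS", "-",
                                  paste(bases[idx], collapse = ""),
                                  qual[idx])
      readpos <- readpos + len
    } else if (op == "D") {
      n_out <- n_out + 1L
      out[[n_out]] <- variant_row(chrom, refpos, "DEL",
                                  paste(refb[ri:(ri + len - 1L)],
                                        collapse = ""),
                                  "-", integer(0))
      refpos <- refpos + len
      ri <- ri + len
    } else if (op == "S") {
      readpos <- readpos + len
    } else if (op == "N") {
      refpos <- refpos + len
    }
    # H consumes neither cursor
  }
  if (n_out == 0L) return(empty_variant_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Does a variant's reference footprint lie inside an amplicon insert?
#'
#' SNVs and deletions must have their full reference footprint within the
#' half-open insert interval; insertion anchor points must be strictly
#' interior so that both flanking insert bases are in bounds. Positions in
#' the primer regions therefore never survive (coordinate-based primer
#' clipping). Vectorised over the rows of `variants`.
#'
#' @param variants A variant table.
#' @param amplicon A list or one-row data.frame with `chrom`, `start`, `end`.
#' @return Logical vector, one element per variant row.
#' @export
variant_within_amplicon <- function(variants, amplicon) {
  if (nrow(variants) == 0L) return(logical(0))
  foot <- ifelse(variants$kind == "DEL" | variants$kind == "SNV",
                 nchar(variants$ref), 0L)
  ok_span <- ifelse(variants$kind == "INS",
                    variants$pos >= amplicon$start &
                      variants$pos < amplicon$end - 1L,
                    variants$pos >= amplicon$start &
                      variants$pos + foot <= amplicon$end)
  variants$chrom == amplicon$chrom & ok_span
}
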