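#' Read amplicon target regions from a BED file
#'
#' Parses a tab-delimited BED file of amplicon insert intervals, one record
#' per amplicon. Each record gives the chromosome and the 0-based half-open
#' interval of the primer-intervening (insert) sequence, with an optional
#' fourth column naming the amplicon. Lines starting with `track`, `browser`
#' or `#` are skipped, as are blank lines.
#'
#' @param path Path to a BED file (>= 3 tab-delimited columns per data line).
#' @return A data.frame with columns `chrom` (character), `start` and `end`
#'   (0-based half-open, integer) and `name` (character), one row per record
#'   in file order. When the name column is absent the name is synthesised as
#'   `"chrom:start-end"`.
#' @details Malformed lines (fewer than 3 columns, non-integer coordinates,
#'   or `start >= end`) raise an error naming the offending line number. An
#'   empty file yields an empty data.frame with a warning: a target file with
#'   no targets is suspicious but not fatal.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr16\t100\t250\texon4_ampA", bed)
#' read_target_regions(bed)
#' @export
read_target_regions <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read target region file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_data <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  recs <- vector("list", sum(is_data))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!is_data[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("region file ", path, ", line ", i,
           ": fewer than 3 tab-delimited columns", call. = FALSE)
    }
    if (!grepl("^[0-9]+$", fields[2]) || !grepl("^[0-9]+$", fields[3])) {
      stop("region file ", path, ", line ", i,
           ": non-integer coordinates '", fields[2], "', '", fields[3], "'",
           call. = FALSE)
    }
    start <- as.integer(fields[2])
    end <- as.integer(fields[3])
    if (start >= end) {
      stop("region file ", path, ", line ", i,
           ": start (", start, ") must be < end (", end, ")", call. = FALSE)
    }
    name <- if (length(fields) >= 4L && nzchar(fields[4])) {
      fields[4]
    } else {
      sprintf("%s:%d-%d", fields[1], start, end)
    }
    j <- j + 1L
    recs[[j]] <- data.frame(chrom = fields[1], start = start, end = end,
                            name = name, stringsAsFactors = FALSE)
  }
  if (j == 0L) {
    warning("region file ", path, " contains no amplicon records",
            call. = FALSE)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs[seq_len(j)])
  rownames(out) <- NULL
  out
}

#' Fraction of a read's reference span covered by an amplicon
#'
#' The denominator is the read's aligned reference span, so a read lying
#' entirely inside the amplicon interval scores 1. Vectorised over reads.
#'
#' @param read_chrom,read_start,read_end Read interval(s), 0-based half-open.
#' @param amp_chrom,amp_start,amp_end Amplicon insert interval, 0-based
#'   half-open.
#' @return Numeric vector of fractions in \[0, 1\]; 0 when chromosomes differ
#'   or the read span is empty.
#' @export
overlap_fraction <- function(read_chrom, read_start, read_end,
                             amp_chrom, amp_start, amp_end) {
  len <- read_end - read_start
  inter <- pmax(0L, pmin(read_end, amp_end) - pmax(read_start, amp_start))
  out <- ifelse(read_chrom == amp_chrom & len > 0, inter / len, 0)
  as.numeric(out)
}

#' Does a read-pair belong to an amplicon?
#'
#' Both mates must individually overlap the amplicon insert interval by at
#' least `min_fraction` of their own reference span. Requiring both mates
#' guarantees that every assigned pair can be concordance-checked across the
#' full insert.
#'
#' @param r1,r2 Lists (or one-row data.frames) with `chrom`, `start`, `end`
#'   describing each mate's aligned reference span, 0-based half-open.
#' @param amplicon A list or one-row data.frame with `chrom`, `start`, `end`.
#' @param min_fraction Minimum per-read overlap fraction in \[0, 1\]
#'   (default 0.9).
#' @return Logical scalar.
#' @export
pair_assigned_to_amplicon <- function(r1, r2, amplicon, min_fraction = 0.9) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  f1 <- overlap_fraction(r1$chrom, r1$start, r1$end,
                         amplicon$chrom, amplicon$start, amplicon$end)
  f2 <- overlap_fraction(r2$chrom, r2$start, r2$end,
                         amplicon$chrom, amplicon$start, amplicon$end)
  f1 >= min_fraction && f2 >= min_fraction
}
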