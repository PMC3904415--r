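## Output writers, the multi-sample driver, and the command-line front end.

# Convert internal 0-based variant records to the 1-based inclusive
# annotation-input convention: SNV start = end = pos + 1; DEL spans the
# deleted reference bases; INS start = end = anchor + 1 with ref "-".
calls_output_table <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), ref = character(), alt = character(),
                      sample = character(), amplicon = character(),
                      pairs = integer(), pairs_total = integer(),
                      proportion = character(), stringsAsFactors = FALSE))
  }
  start <- calls$pos + 1L
  end <- ifelse(calls$kind == "DEL", calls$pos + nchar(calls$ref), start)
  data.frame(chrom = calls$chrom, start = start, end = as.integer(end),
             ref = calls$ref, alt = calls$alt, sample = calls$sample,
             amplicon = calls$amplicon, pairs = calls$pairs,
             pairs_total = calls$pairs_total,
             proportion = sprintf("%.4f", calls$proportion),
             stringsAsFactors = FALSE)
}

#' Write called variants as a tab-delimited annotation-ready file
#'
#' One row per call with 1-based inclusive `start`/`end` coordinates and
#' `-` alleles for indels (the input dialect of common variant annotation
#' tools), followed by provenance columns: sample, amplicon, supporting
#' pair count, total assigned pairs, and the proportion formatted to four
#' decimal places. Rows are written in the order given (the driver sorts
#' per sample); an empty call set yields a header-only file.
#'
#' @param calls Data.frame of calls (internal 0-based form, see
#'   [apply_thresholds()]).
#' @param path Output file path.
#' @return Invisibly, the output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls_output_table(calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a call file back into internal form
#'
#' Inverse of [write_calls()]: reconstructs the 0-based position, variant
#' kind and identity key from the annotation-style columns.
#'
#' @param path Path to a file written by [write_calls()].
#' @return Data.frame in the internal call layout.
#' @export
read_calls <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character",
                                          alt = "character",
                                          sample = "character",
                                          amplicon = "character"))
  kind <- ifelse(tab$ref == "-", "INS",
                 ifelse(tab$alt == "-", "DEL", "SNV"))
  pos <- tab$start - 1L
  data.frame(chrom = tab$chrom, pos = pos, kind = kind, ref = tab$ref,
             alt = tab$alt, key = variant_key(tab$chrom, pos, kind,
                                              tab$ref, tab$alt),
             sample = tab$sample, amplicon = tab$amplicon,
             pairs = tab$pairs, pairs_total = tab$pairs_total,
             proportion = as.numeric(tab$proportion),
             stringsAsFactors = FALSE)
}

#' Write the per-amplicon read-pair coverage report for one sample
#'
#' One row per region-file record, in region-file order, including
#' amplicons with zero assigned pairs — low rows flag regions that may need
#' further screening.
#'
#' @param coverage Data.frame from [call_variants_bam()] (`amplicon`,
#'   `chrom`, `start`, `end`, `pairs`).
#' @param coverdir Directory for coverage files (created if needed).
#' @param sample Sample identifier; the file is `<sample>.coverage.tsv`.
#' @return Invisibly, the file path.
#' @export
write_coverage <- function(coverage, coverdir, sample) {
  if (!dir.exists(coverdir)) {
    ok <- dir.create(coverdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(coverdir)) {
      stop("cannot create coverage directory: ", coverdir, call. = FALSE)
    }
  }
  path <- file.path(coverdir, paste0(sample, ".coverage.tsv"))
  utils::write.table(coverage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

pc_log <- function(con, ...) {
  msg <- paste0("INFO ", format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  if (is.null(con)) message(msg) else writeLines(msg, con)
}

#' Run the caller over one or more alignment files
#'
#' Parses the region file once, then processes each BAM in order: the
#' sample identifier is the file name stem, calls are accumulated into a
#' single output file (sorted per sample by chromosome, position, alleles,
#' amplicon), and one coverage file per sample is written under
#' `coverdir`. A failure on any input aborts the run.
#'
#' @param primers Path to the BED file of amplicon insert intervals.
#' @param bams Character vector of indexed BAM paths (at least one).
#' @param out Path for the combined tab-delimited call file.
#' @param coverdir Directory for per-sample coverage files, or `NULL` to
#'   skip writing them.
#' @param log Path of a log file, or `NULL` to log to standard error.
#' @param absthresh,proportionthresh,qualthresh,overlap Calling thresholds,
#'   see [thresholds()].
#' @return Invisibly, a list with the combined `calls` data.frame and a
#'   named list of per-sample `coverage` data.frames.
#' @export
paircall_run <- function(primers, bams, out, coverdir = NULL, log = NULL,
                         absthresh = 2L, proportionthresh = 0.15,
                         qualthresh = NULL, overlap = 0.9) {
  stopifnot(length(bams) >= 1L)
  thr <- thresholds(absthresh, proportionthresh, qualthresh, overlap)
  amplicons <- read_target_regions(primers)
  logcon <- NULL
  if (!is.null(log)) {
    logcon <- file(log, open = "at")
    on.exit(close(logcon), add = TRUE)
  }
  pc_log(logcon, "regions: ", nrow(amplicons), " amplicons from ", primers)
  all_calls <- list()
  coverage <- list()
  for (bam in bams) {
    sample <- sub("\\.bam$", "", basename(bam))
    res <- call_variants_bam(bam, amplicons, thr, sample)
    all_calls[[sample]] <- sort_calls(res$calls)
    coverage[[sample]] <- res$coverage
    if (!is.null(coverdir)) write_coverage(res$coverage, coverdir, sample)
    pc_log(logcon, "sample ", sample, ": ", sum(res$coverage$pairs),
           " read-pairs assigned, ", res$stats[["singletons"]],
           " singletons discarded, ", res$stats[["nonprimary"]],
           " non-primary/unpaired records skipped, ",
           nrow(res$calls), " calls emitted")
  }
  calls <- do.call(rbind, c(all_calls, make.row.names = FALSE))
  write_calls(calls, out)
  pc_log(logcon, "wrote ", nrow(calls), " calls to ", out)
  invisible(list(calls = calls, coverage = coverage))
}

cli_parser <- function() {
  optparse::OptionParser(
    usage = paste("%prog --primers REGIONS.bed --out CALLS.tsv [options]",
                  "sample1.bam [sample2.bam ...]"),
    option_list = list(
      optparse::make_option("--primers", type = "character",
        help = "BED file of amplicon insert coordinates [required]"),
      optparse::make_option("--out", type = "character",
        help = "output call file [required]"),
      optparse::make_option("--log", type = "character", default = NULL,
        help = "log file [default: standard error]"),
      optparse::make_option("--coverdir", type = "character",
        default = "coverage",
        help = "directory for per-sample coverage files [default %default]"),
      optparse::make_option("--proportionthresh", type = "double",
        default = 0.15,
        help = "minimum read-pair proportion per call [default %default]"),
      optparse::make_option("--absthresh", type = "integer", default = 2L,
        help = "minimum read-pair count per call [default %default]"),
      optparse::make_option("--qualthresh", type = "double", default = NA,
        help = "minimum base quality in both mates [default: off]"),
      optparse::make_option("--overlap", type = "double", default = 0.9,
        help = "per-read amplicon overlap fraction [default %default]")))
}

#' Command-line entry point
#'
#' Parses a CLI argument vector and runs [paircall_run()]. Installed with
#' the package as the executable script `exec/paircall`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, 1 on a usage error, 2 on a
#'   runtime error.
#' @export
paircall_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parser <- cli_parser()
  opt <- tryCatch(
    optparse::parse_args(parser, args = argv, positional_arguments = TRUE),
    error = function(e) e)
  usage_error <- function(msg) {
    message("usage error: ", msg)
    optparse::print_help(parser)
    invisible(1L)
  }
  if (inherits(opt, "error")) {
    return(usage_error(conditionMessage(opt)))
  }
  o <- opt$options
  if (is.null(o$primers)) return(usage_error("--primers is required"))
  if (is.null(o$out)) return(usage_error("--out is required"))
  if (length(opt$args) == 0L) {
    return(usage_error("at least one alignment (BAM) file is required"))
  }
  status <- tryCatch({
    paircall_run(primers = o$primers, bams = opt$args, out = o$out,
                 coverdir = o$coverdir, log = o$log,
                 absthresh = o$absthresh,
                 proportionthresh = o$proportionthresh,
                 qualthresh = if (is.na(o$qualthresh)) NULL else o$qualthresh,
                 overlap = o$overlap)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
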