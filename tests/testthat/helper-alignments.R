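# Independent constructor for randomized alignment cases. Builds an
# alignment column-by-column (choosing reference and read bases directly),
# then derives CIGAR, MD, SEQ and the expected reference span and variant
# list with its own inline logic, so decode_reference() and
# extract_read_variants() are checked against an oracle that shares no code
# with them.

random_alignment <- function(pos = sample(0:10000, 1), chrom = "chrN") {
  bases <- c("A", "C", "G", "T")
  ops <- character(0)
  refb <- character(0)
  readb <- character(0)
  add_m <- function(n, mism_p) {
    for (i in seq_len(n)) {
      r <- sample(bases, 1)
      q <- if (runif(1) < mism_p) sample(setdiff(bases, r), 1) else r
      ops <<- c(ops, "M")
      refb <<- c(refb, r)
      readb <<- c(readb, q)
    }
  }
  lead_clip <- sample(0:3, 1)
  add_m(sample(3:10, 1), 0.15)
  for (ev in seq_len(sample(0:4, 1))) {
    kind <- sample(c("I", "D"), 1)
    n <- sample(1:3, 1)
    if (kind == "I") {
      ops <- c(ops, rep("I", n))
      refb <- c(refb, rep(NA, n))
      readb <- c(readb, sample(bases, n, replace = TRUE))
    } else {
      ops <- c(ops, rep("D", n))
      refb <- c(refb, sample(bases, n, replace = TRUE))
      readb <- c(readb, rep(NA, n))
    }
    add_m(sample(2:8, 1), 0.15)
  }
  trail_clip <- sample(0:3, 1)
  if (lead_clip > 0) {
    ops <- c(rep("S", lead_clip), ops)
    refb <- c(rep(NA, lead_clip), refb)
    readb <- c(sample(bases, lead_clip, replace = TRUE), readb)
  }
  if (trail_clip > 0) {
    ops <- c(ops, rep("S", trail_clip))
    refb <- c(refb, rep(NA, trail_clip))
    readb <- c(readb, sample(bases, trail_clip, replace = TRUE))
  }

  r <- rle(ops)
  cigar <- paste0(r$lengths, r$values, collapse = "")

  # MD: numbers of matched M columns, mismatch letters, ^-prefixed deletions
  md <- ""
  nmatch <- 0
  i <- 1
  while (i <= length(ops)) {
    if (ops[i] %in% c("I", "S")) {
      i <- i + 1
    } else if (ops[i] == "M") {
      if (readb[i] == refb[i]) {
        nmatch <- nmatch + 1
      } else {
        md <- paste0(md, nmatch, refb[i])
        nmatch <- 0
      }
      i <- i + 1
    } else {
      j <- i
      while (j < length(ops) && ops[j + 1] == "D") j <- j + 1
      md <- paste0(md, nmatch, "^", paste(refb[i:j], collapse = ""))
      nmatch <- 0
      i <- j + 1
    }
  }
  md <- paste0(md, nmatch)

  seq <- paste(readb[ops %in% c("M", "I", "S")], collapse = "")
  qual <- sample(10:40, sum(ops %in% c("M", "I", "S")), replace = TRUE)
  refspan <- paste(refb[ops %in% c("M", "D")], collapse = "")

  # expected variants, walked directly off the columns
  expected <- list()
  refpos <- pos
  i <- 1
  readi <- 0
  while (i <= length(ops)) {
    if (ops[i] == "S") {
      readi <- readi + 1
      i <- i + 1
    } else if (ops[i] == "M") {
      readi <- readi + 1
      if (readb[i] != refb[i]) {
        expected[[length(expected) + 1]] <- data.frame(
          chrom = chrom, pos = refpos, kind = "SNV", ref = refb[i],
          alt = readb[i], qv = I(list(qual[readi])),
          stringsAsFactors = FALSE)
      }
      refpos <- refpos + 1
      i <- i + 1
    } else if (ops[i] == "I") {
      j <- i
      while (j < length(ops) && ops[j + 1] == "I") j <- j + 1
      expected[[length(expected) + 1]] <- data.frame(
        chrom = chrom, pos = refpos - 1, kind = "INS", ref = "-",
        alt = paste(readb[i:j], collapse = ""),
        qv = I(list(qual[(readi + 1):(readi + j - i + 1)])),
        stringsAsFactors = FALSE)
      readi <- readi + (j - i + 1)
      i <- j + 1
    } else {
      j <- i
      while (j < length(ops) && ops[j + 1] == "D") j <- j + 1
      expected[[length(expected) + 1]] <- data.frame(
        chrom = chrom, pos = refpos, kind = "DEL",
        ref = paste(refb[i:j], collapse = ""), alt = "-",
        qv = I(list(integer(0))), stringsAsFactors = FALSE)
      refpos <- refpos + (j - i + 1)
      i <- j + 1
    }
  }
  expected <- if (length(expected)) do.call(rbind, expected) else NULL

  list(chrom = chrom, pos = pos, cigar = cigar, md = md, seq = seq,
       qual = qual, refspan = refspan, expected = expected,
       n_mismatch = sum(ops == "M" & readb != refb, na.rm = TRUE),
       n_ins_runs = sum(rle(ops)$values == "I"),
       n_del_runs = sum(rle(ops)$values == "D"))
}

variant_signature <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(character(0))
  sort(paste(df$chrom, df$pos, df$kind, df$ref, df$alt))
}
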