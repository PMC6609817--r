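DNA_BASES <- c("A", "C", "G", "T")

.datatable.aware <- TRUE

#' Derive a reproducible per-stage seed from a global seed
#'
#' Splits one user-supplied seed into independent seeds for the pipeline's
#' stochastic stages by hashing the stage name, so that re-running a single
#' stage reproduces its output without the user tracking per-stage seeds.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"train"`).
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' stage_seed(1, "train")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- digest::digest2int(paste0("mosaiclr::", stage))
  as.integer((abs(as.double(seed) * 48271 + as.double(h))) %% 2147483646)
}

## decode a phred+33 quality string into integer scores
phred_to_int <- function(qual) {
  if (length(qual) == 0) return(integer(0))
  as.integer(charToRaw(paste(qual, collapse = ""))) - 33L
}

## quality character at one offset per string (vectorised)
qual_at <- function(qual, offset1) {
  ch <- substr(qual, offset1, offset1)
  out <- rep(NA_integer_, length(ch))
  ok <- nchar(ch) == 1L
  if (any(ok)) out[ok] <- as.integer(charToRaw(paste(ch[ok], collapse = ""))) - 33L
  out
}

int_to_phred <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(pmin(x, 93L) + 33L)), character(1))
}

## 0-based query offset of reference position `pos` within each read,
## NA when the position falls in a deletion/skip or outside the read.
## Fast path for pure-match CIGARs; general CIGAR walk otherwise.
query_offset <- function(cigar, start, pos) {
  n <- length(cigar)
  stopifnot(length(start) == n, length(pos) == n)
  off <- rep(NA_integer_, n)
  simple <- grepl("^[0-9]+M$", cigar)
  if (any(simple)) {
    w <- as.integer(sub("M$", "", cigar[simple]))
    o <- pos[simple] - start[simple]
    o[o < 0L | o >= w] <- NA_integer_
    off[simple] <- o
  }
  idx <- which(!simple)
  if (length(idx)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar[idx])
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar[idx])
    for (k in seq_along(idx)) {
      i <- idx[k]
      rp <- start[i]
      qp <- 0L
      res <- NA_integer_
      o <- ops[[k]]
      l <- lens[[k]]
      for (j in seq_along(o)) {
        opj <- o[j]
        lj <- l[j]
        if (opj %in% c("M", "=", "X")) {
          if (pos[i] < rp + lj) {
            res <- qp + (pos[i] - rp)
            break
          }
          rp <- rp + lj
          qp <- qp + lj
        } else if (opj %in% c("I", "S")) {
          qp <- qp + lj
        } else if (opj %in% c("D", "N")) {
          if (pos[i] < rp + lj) break
          rp <- rp + lj
        }
      }
      off[i] <- res
    }
  }
  off
}

## reference span of each CIGAR
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

## longest soft-clip (bp) in each CIGAR
softclip_len <- function(cigar) {
  l <- GenomicAlignments::explodeCigarOpLengths(cigar, ops = "S")
  vapply(l, function(x) if (length(x)) max(x) else 0L, integer(1))
}

## half-open [start, end) homopolymer runs of length >= min_len; returns
## a logical vector over positions `pos` (0-based) indicating membership
in_homopolymer <- function(reference, pos, min_len = 10L) {
  if (length(pos) == 0) return(logical(0))
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths ## 0-based run starts
  long <- which(r$lengths >= min_len)
  hit <- rep(FALSE, length(pos))
  for (i in long) {
    hit <- hit | (pos >= starts[i] & pos < ends[i])
  }
  hit
}

## sequence of one reference chromosome as a plain character string
as_ref_string <- function(reference) {
  if (is.character(reference) && length(reference) == 1) return(reference)
  if (methods::is(reference, "DNAStringSet")) {
    stopifnot(length(reference) >= 1)
    return(as.character(reference[[1]]))
  }
  if (methods::is(reference, "DNAString")) return(as.character(reference))
  abort("reference must be a character string, DNAString or DNAStringSet")
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
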