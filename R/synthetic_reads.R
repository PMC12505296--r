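#' Deterministic barcode sets
#'
#' Generates \code{n} barcodes of the given length with pairwise Hamming
#' distance >= 3 by a greedy scan of k-mers in lexicographic order, so that
#' single-substitution matching (\code{\link{demultiplex}}) is unambiguous.
#' The scan is deterministic: the same (n, length, skip) always yields the
#' same set.
#'
#' @param n Number of barcodes.
#' @param length Barcode length (default 6).
#' @param skip Number of eligible barcodes to discard before collecting, so
#'   that disjoint sets (e.g. row vs column) can be drawn from one scan.
#' @return Character vector of \code{n} barcodes.
#' @export
make_barcodes <- function(n, length = 6L, skip = 0L) {
  b <- c("A", "C", "G", "T")
  kept <- character(0)
  total_needed <- n + skip
  # enumerate k-mers lexicographically without materializing all 4^k at once
  idx <- rep(1L, length)
  repeat {
    cand <- paste(b[idx], collapse = "")
    ok <- TRUE
    for (k in kept) {
      if (hamming_dist(cand, k) < 3L) { ok <- FALSE; break }
    }
    if (ok) {
      kept <- c(kept, cand)
      if (length(kept) >= total_needed) break
    }
    # increment
    j <- length
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= 4L) break
      idx[j] <- 1L
      j <- j - 1L
      if (j == 0L) stop("barcode space exhausted")
    }
  }
  kept[(skip + 1L):total_needed]
}

hamming_dist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Build a sample manifest with row/column barcodes
#'
#' One row per sequencing sample (unique combination of bait, condition,
#' replicate and timepoint found in a count table), with row and column
#' barcodes assigned on a grid so that each sample gets a unique pair.
#'
#' @param counts A count table (see \code{\link{simulate_counts}}), or a
#'   data.frame with columns \code{sample_id}, \code{bait}, \code{condition},
#'   \code{replicate}, \code{timepoint}.
#' @param barcode_length Barcode length (default 6).
#' @return Data.frame with columns \code{sample_id}, \code{bait},
#'   \code{condition}, \code{replicate}, \code{timepoint},
#'   \code{barcode_row}, \code{barcode_col}.
#' @export
build_manifest <- function(counts, barcode_length = 6L) {
  samp <- unique(counts[c("sample_id", "bait", "condition", "replicate",
                          "timepoint")])
  rownames(samp) <- NULL
  n <- nrow(samp)
  n_col <- ceiling(sqrt(n))
  n_row <- ceiling(n / n_col)
  rows <- make_barcodes(n_row, barcode_length)
  cols <- make_barcodes(n_col, barcode_length, skip = n_row)
  i <- seq_len(n) - 1L
  samp$barcode_row <- rows[i %/% n_col + 1L]
  samp$barcode_col <- cols[i %% n_col + 1L]
  samp
}

#' @rdname build_manifest
#' @param path Manifest TSV path.
#' @export
read_manifest <- function(path) {
  read_tsv_checked(path, schema = c(sample_id = "character",
                                    bait = "character",
                                    condition = "character",
                                    replicate = "integer",
                                    timepoint = "character",
                                    barcode_row = "character",
                                    barcode_col = "character"))
}

#' Emit synthetic amplicon reads as FASTQ
#'
#' Writes one full-length amplicon read per counted molecule: the wild-type
#' sequence with the variant's codon substituted, flanked by the sample's row
#' and column barcodes, with independent per-base substitution errors at
#' \code{params$error_rate} and constant Phred quality (Q30). At error rate 0
#' the variant caller recovers the count table exactly.
#'
#' @param design A \code{\link{library_design}}.
#' @param counts Count table from \code{\link{simulate_counts}}.
#' @param params A \code{\link{sim_params}} (seed and error rate are used).
#' @param manifest Sample manifest from \code{\link{build_manifest}}.
#' @param path Output FASTQ path (all samples pooled).
#' @return \code{path}, invisibly.
#' @export
emit_reads <- function(design, counts, params, manifest, path) {
  stopifnot(inherits(design, "library_design"))
  set.seed((params$seed + 2L) %% 2147483647L)
  counts <- counts[counts$count > 0L, ]
  m <- match(counts$sample_id, manifest$sample_id)
  if (anyNA(m)) stop("count table contains samples absent from the manifest")
  body <- variant_sequence(design, counts$codon_position, counts$mutant_codon)
  reads <- paste0(manifest$barcode_row[m], body, manifest$barcode_col[m])
  reads <- rep(reads, counts$count)
  if (params$error_rate > 0) reads <- mutate_reads(reads, params$error_rate)
  w <- nchar(reads[1L])
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("read", seq_along(x))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(rep(strrep("?", w), length(x))))
  invisible(path)
}

# independent per-base substitution errors; vectorized over reads, loop only
# over the (few) reads that drew at least one error
mutate_reads <- function(reads, rate) {
  L <- nchar(reads)
  n_err <- rbinom(length(reads), L, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L[i], n_err[i])
    s <- strsplit(reads[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}
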