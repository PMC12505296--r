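#' Demultiplex barcoded amplicon reads
#'
#' Reads carry a row barcode at the 5' end and a column barcode at the 3' end.
#' A read is assigned to a sample iff both barcodes match a manifest entry
#' within at most one substitution and the match is unique on each side;
#' otherwise it is left unassigned. Barcodes are stripped before alignment.
#'
#' @param reads Character vector of read sequences.
#' @param manifest Manifest data.frame (see \code{\link{build_manifest}});
#'   duplicate barcode pairs are an error.
#' @return A list with \code{sample_id} (character vector parallel to
#'   \code{reads}, \code{NA} for unassigned), \code{stripped} (reads with
#'   barcodes removed) and \code{n_unassigned}.
#' @export
demultiplex <- function(reads, manifest) {
  if (anyDuplicated(paste(manifest$barcode_row, manifest$barcode_col)))
    stop("duplicate barcode pairs in manifest")
  lr <- unique(nchar(manifest$barcode_row))
  lc <- unique(nchar(manifest$barcode_col))
  if (length(lr) != 1L || length(lc) != 1L)
    stop("barcodes must have equal length per side")
  row_lut <- barcode_lookup(unique(manifest$barcode_row))
  col_lut <- barcode_lookup(unique(manifest$barcode_col))
  obs_row <- substr(reads, 1L, lr)
  obs_col <- substring(reads, nchar(reads) - lc + 1L)
  hit_row <- row_lut[obs_row]
  hit_col <- col_lut[obs_col]
  pair <- paste(hit_row, hit_col)
  key <- paste(manifest$barcode_row, manifest$barcode_col)
  sample_id <- manifest$sample_id[match(pair, key)]
  sample_id[is.na(hit_row) | is.na(hit_col)] <- NA_character_
  list(sample_id = sample_id,
       stripped = substr(reads, lr + 1L, nchar(reads) - lc),
       n_unassigned = sum(is.na(sample_id)))
}

# map every sequence within Hamming distance 1 of a barcode to that barcode;
# sequences reachable from two barcodes are ambiguous and dropped
barcode_lookup <- function(barcodes) {
  bases <- c("A", "C", "G", "T")
  keys <- vals <- character(0)
  for (bc in barcodes) {
    s <- strsplit(bc, "")[[1]]
    nb <- bc
    for (p in seq_along(s)) for (b in setdiff(bases, s[p])) {
      t <- s; t[p] <- b
      nb <- c(nb, paste(t, collapse = ""))
    }
    keys <- c(keys, nb)
    vals <- c(vals, rep(bc, length(nb)))
  }
  dup <- keys[duplicated(keys)]
  keep <- !(keys %in% dup)
  setNames(vals[keep], keys[keep])
}

#' Collapse identical reads
#'
#' @param reads Character vector of sequences.
#' @return Data.frame with columns \code{seq} and \code{n}, ordered by
#'   descending multiplicity then lexicographically; multiplicities sum to
#'   \code{length(reads)}.
#' @export
collapse_reads <- function(reads) {
  if (length(reads) == 0L)
    return(data.frame(seq = character(0), n = integer(0)))
  tab <- table(reads)
  df <- data.frame(seq = names(tab), n = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n, df$seq), ]
  rownames(df) <- NULL
  df
}

#' Global alignment to the wild-type reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties, using the
#' usual DNA defaults of the EMBOSS needle tool (match +5, mismatch -4, gap
#' open 10, gap extend 0.5; a gap of length L costs open + L * extend). 'N'
#' scores 0 against anything. Traceback ties are broken deterministically
#' (diagonal, then up, then left).
#'
#' @param seq Read sequence (ACGTN).
#' @param ref Reference sequence.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return List with \code{score}, \code{aligned_query}, \code{aligned_ref}.
#' @export
align_to_reference <- function(seq, ref, match = 5, mismatch = -4,
                               gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq) || !nzchar(ref)) stop("sequences must be nonempty")
  if (grepl("[^ACGTN]", seq) || grepl("[^ACGTN]", ref))
    stop("sequences may contain only A, C, G, T, N")
  .nw_align_cpp(seq, ref, match, mismatch, gap_open, gap_extend)
}

#' Call a single-codon variant from an alignment
#'
#' Policy for the single-mutant library: a read with no gaps whose mismatches
#' are confined to exactly one codon of the mutagenized region is called as
#' that codon variant; zero mismatches is \code{wt_identical}; mismatches in
#' two or more codons, or in a codon outside the mutagenized region, are
#' \code{multi_codon}; any gap (or an alignment that does not cover the
#' region) is \code{indel_other}. Only \code{wt_identical} and single-codon
#' calls enter frequency denominators downstream.
#'
#' @param aligned_query,aligned_ref Aligned sequences from
#'   \code{\link{align_to_reference}} (equal length, \code{-} for gaps).
#' @param design A \code{\link{library_design}} (the reference must be its
#'   \code{wt_nt_seq}).
#' @return List with \code{class} (one of \code{"wt_identical"},
#'   \code{"variant"}, \code{"multi_codon"}, \code{"indel_other"}) and, for
#'   variants, \code{codon_position} and \code{mutant_codon}.
#' @export
call_variant <- function(aligned_query, aligned_ref, design) {
  stopifnot(inherits(design, "library_design"))
  q <- strsplit(aligned_query, "")[[1]]
  r <- strsplit(aligned_ref, "")[[1]]
  if (length(q) != length(r)) stop("aligned sequences differ in length")
  if (any(q == "-") || any(r == "-"))
    return(list(class = "indel_other"))
  if (length(r) != nchar(design$wt_nt_seq))
    return(list(class = "indel_other"))
  mism <- which(q != r)
  if (length(mism) == 0L) return(list(class = "wt_identical"))
  codon_idx <- design$orf_codon_offset + (mism - 1L) %/% 3L
  cods <- unique(codon_idx)
  if (length(cods) > 1L) return(list(class = "multi_codon"))
  if (cods < design$region_start_codon || cods > design$region_end_codon)
    return(list(class = "multi_codon"))
  nt0 <- (cods - design$orf_codon_offset) * 3L
  list(class = "variant", codon_position = as.integer(cods),
       mutant_codon = paste(q[(nt0 + 1L):(nt0 + 3L)], collapse = ""))
}

#' Distinguishable variants of a design
#'
#' The wild-type sentinel variants enumerated at each region position all
#' share the wild-type nucleotide sequence, so count tables carry a single
#' pooled \code{wt_identical} row (at the first region codon). All other
#' single-codon variants have unique sequences.
#'
#' @param design A \code{\link{library_design}}.
#' @return \code{\link{enumerate_variants}} output with duplicate wild-type
#'   sentinels removed.
#' @export
variant_table <- function(design) {
  v <- enumerate_variants(design)
  wt_rows <- which(v$variant_class == "wt_identical")
  if (length(wt_rows) > 1L) v <- v[-wt_rows[-1L], ]
  rownames(v) <- NULL
  v
}

#' Tabulate variant calls into a count table
#'
#' Builds the per-sample count table: every variant enumerated by the design
#' gets a row (zero count if unobserved); the sample depth \code{D} is the sum
#' of assigned single-codon and wild-type-identical reads, and frequencies are
#' counts over \code{D}. Reads in the special classes (\code{multi_codon},
#' \code{indel_other}) are tallied in separate rows but excluded from
#' \code{D}, so sequencing errors do not deflate all frequencies.
#'
#' @param calls Data.frame with columns \code{sample_id}, \code{class},
#'   \code{codon_position}, \code{mutant_codon}, \code{n} (one row per unique
#'   read group).
#' @param design A \code{\link{library_design}}.
#' @param sample_meta Data.frame mapping \code{sample_id} to \code{bait},
#'   \code{condition}, \code{replicate}, \code{timepoint} (e.g. a manifest).
#' @return Count table in the same layout as \code{\link{simulate_counts}},
#'   plus rows with \code{variant_class} in
#'   \code{c("multi_codon", "indel_other")}.
#' @export
tabulate_counts <- function(calls, design, sample_meta) {
  stopifnot(inherits(design, "library_design"))
  v <- variant_table(design)
  unknown <- setdiff(unique(calls$sample_id), sample_meta$sample_id)
  if (length(unknown)) stop("unknown sample_id: ",
                            paste(unknown, collapse = ", "))
  vkey <- paste(v$codon_position, v$mutant_codon)
  wt_row <- which(v$variant_class == "wt_identical")
  out <- list()
  for (sid in sample_meta$sample_id) {
    cs <- calls[calls$sample_id == sid, , drop = FALSE]
    meta <- sample_meta[sample_meta$sample_id == sid, ]
    counts <- integer(nrow(v))
    isvar <- cs$class == "variant"
    if (any(isvar)) {
      idx <- match(paste(cs$codon_position[isvar], cs$mutant_codon[isvar]),
                   vkey)
      bad <- is.na(idx)
      agg <- tapply(cs$n[isvar][!bad], idx[!bad], sum)
      counts[as.integer(names(agg))] <- counts[as.integer(names(agg))] +
        as.integer(agg)
    }
    counts[wt_row] <- counts[wt_row] +
      as.integer(sum(cs$n[cs$class == "wt_identical"]))
    depth <- sum(counts)
    rows <- data.frame(sample_id = sid, bait = meta$bait,
                       condition = meta$condition,
                       replicate = as.integer(meta$replicate),
                       timepoint = meta$timepoint, v, count = counts,
                       depth = depth,
                       frequency = if (depth > 0) counts / depth else NA_real_,
                       stringsAsFactors = FALSE)
    for (cls in c("multi_codon", "indel_other")) {
      n_cls <- sum(cs$n[cs$class == cls])
      rows <- rbind(rows, data.frame(
        sample_id = sid, bait = meta$bait, condition = meta$condition,
        replicate = as.integer(meta$replicate), timepoint = meta$timepoint,
        codon_position = NA_integer_, wt_codon = NA_character_,
        mutant_codon = NA_character_, wt_aa = NA_character_,
        mut_aa = NA_character_, variant_class = cls,
        aa_change_key = NA_character_, count = as.integer(n_cls),
        depth = depth, frequency = NA_real_, stringsAsFactors = FALSE))
    }
    out[[length(out) + 1L]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call codon variants from a FASTQ file
#'
#' Full read-level counting: read FASTQ, demultiplex by row/column barcodes,
#' collapse identical reads, align unique sequences to the wild-type reference
#' (with an exact-match shortcut for sequences identical to an enumerated
#' variant or the wild type, whose alignment is the identity), call
#' single-codon variants and tabulate per-sample counts.
#'
#' @param fastq Path to a FASTQ file (gzip-compressed accepted).
#' @param design A \code{\link{library_design}}.
#' @param manifest Sample manifest (data.frame or TSV path).
#' @param min_mean_quality Optional minimum mean Phred quality per read;
#'   \code{NULL} (default) disables quality filtering.
#' @return A count table (see \code{\link{tabulate_counts}}).
#' @export
call_variants <- function(fastq, design, manifest, min_mean_quality = NULL) {
  stopifnot(inherits(design, "library_design"))
  if (is.character(manifest) && length(manifest) == 1L &&
      file.exists(manifest))
    manifest <- read_manifest(manifest)
  if (is.null(min_mean_quality)) {
    reads <- as.character(Biostrings::readDNAStringSet(fastq,
                                                       format = "fastq"))
  } else {
    x <- Biostrings::readQualityScaledDNAStringSet(fastq)
    q <- as.character(Biostrings::quality(x))
    meanq <- vapply(q, function(s) mean(utf8ToInt(s) - 33L), numeric(1),
                    USE.NAMES = FALSE)
    reads <- as.character(x)[meanq >= min_mean_quality]
  }
  dm <- demultiplex(reads, manifest)
  assigned <- !is.na(dm$sample_id)

  # exact-sequence shortcut: identity alignments need no DP
  v <- variant_table(design)
  vseq <- variant_sequence(design, v$codon_position, v$mutant_codon)
  lut_class <- ifelse(vseq == design$wt_nt_seq, "wt_identical", "variant")
  lut <- data.frame(seq = vseq, class = lut_class,
                    codon_position = v$codon_position,
                    mutant_codon = v$mutant_codon, stringsAsFactors = FALSE)
  lut <- lut[!duplicated(lut$seq), ]
  vkey_set <- paste(v$codon_position, v$mutant_codon)

  calls <- list()
  for (sid in unique(dm$sample_id[assigned])) {
    grp <- collapse_reads(dm$stripped[assigned & dm$sample_id == sid])
    hit <- match(grp$seq, lut$seq)
    known <- !is.na(hit)
    res <- data.frame(sample_id = sid, class = NA_character_,
                      codon_position = NA_integer_,
                      mutant_codon = NA_character_, n = grp$n,
                      stringsAsFactors = FALSE)
    res$class[known] <- lut$class[hit[known]]
    res$codon_position[known] <- ifelse(lut$class[hit[known]] == "variant",
                                        lut$codon_position[hit[known]],
                                        NA_integer_)
    res$mutant_codon[known] <- ifelse(lut$class[hit[known]] == "variant",
                                      lut$mutant_codon[hit[known]],
                                      NA_character_)
    for (i in which(!known)) {
      al <- align_to_reference(grp$seq[i], design$wt_nt_seq)
      cv <- call_variant(al$aligned_query, al$aligned_ref, design)
      res$class[i] <- cv$class
      if (cv$class == "variant") {
        # a called codon may fall outside the degeneracy scheme (e.g. an NNK
        # library read with a sequencing error in the third base); such calls
        # are kept as variants only if enumerated, else counted as multi_codon
        if (paste(cv$codon_position, cv$mutant_codon) %in% vkey_set) {
          res$codon_position[i] <- cv$codon_position
          res$mutant_codon[i] <- cv$mutant_codon
        } else {
          res$class[i] <- "multi_codon"
        }
      }
    }
    calls[[length(calls) + 1L]] <- res
  }
  calls <- do.call(rbind, calls)
  tabulate_counts(calls, design, manifest)
}
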