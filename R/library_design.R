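#' Describe a single-codon mutagenesis library
#'
#' A library design bundles the wild-type nucleotide sequence of the
#' mutagenized locus, its reading frame, the window of codons that was
#' mutagenized, and the degeneracy scheme used to build the library
#' (\code{"NNN"}: all 64 codons per position; \code{"NNK"}: the 32 codons whose
#' third base is G or T).
#'
#' Codon positions are 1-based ORF codon indices so that they match protein
#' residue numbering (e.g. a motif at residues 93-99 lives at codon positions
#' 93-99). \code{orf_codon_offset} gives the ORF codon index of the first full
#' codon contained in \code{wt_nt_seq}, which therefore does not need to start
#' at the ATG.
#'
#' @param wt_nt_seq Wild-type nucleotide sequence (uppercase ACGT, length a
#'   multiple of 3) covering at least the mutagenized region.
#' @param region_start_codon,region_end_codon First and last mutagenized codon
#'   (1-based ORF codon indices, inclusive).
#' @param orf_codon_offset ORF codon index of the first codon of
#'   \code{wt_nt_seq} (default 1).
#' @param scheme Degeneracy scheme, \code{"NNN"} or \code{"NNK"}.
#' @return An object of class \code{"library_design"}.
#' @examples
#' d <- library_design("ATGAAACCA", 2, 3, scheme = "NNN")
#' nrow(enumerate_variants(d))  # 2 x 64
#' @export
library_design <- function(wt_nt_seq, region_start_codon, region_end_codon,
                           orf_codon_offset = 1L, scheme = c("NNN", "NNK")) {
  scheme <- match.arg(scheme)
  wt_nt_seq <- toupper(as.character(wt_nt_seq))
  if (!grepl("^[ACGT]+$", wt_nt_seq))
    stop("wt_nt_seq must contain only A, C, G, T")
  if (nchar(wt_nt_seq) %% 3L != 0L)
    stop("wt_nt_seq length must be a multiple of 3")
  orf_codon_offset <- as.integer(orf_codon_offset)
  region_start_codon <- as.integer(region_start_codon)
  region_end_codon <- as.integer(region_end_codon)
  n_codons <- nchar(wt_nt_seq) %/% 3L
  if (region_start_codon > region_end_codon)
    stop("region_start_codon must be <= region_end_codon")
  if (region_start_codon < orf_codon_offset ||
      region_end_codon > orf_codon_offset + n_codons - 1L)
    stop("mutagenized region lies outside wt_nt_seq")
  codons <- substring(wt_nt_seq,
                      seq(1L, nchar(wt_nt_seq), by = 3L),
                      seq(3L, nchar(wt_nt_seq), by = 3L))
  names(codons) <- seq(orf_codon_offset, length.out = n_codons)
  region_idx <- as.character(seq(region_start_codon, region_end_codon))
  if (any(translate_codons(codons[region_idx]) == "*"))
    stop("wt_nt_seq contains a stop codon inside the mutagenized region")
  structure(
    list(wt_nt_seq = wt_nt_seq,
         orf_codon_offset = orf_codon_offset,
         region_start_codon = region_start_codon,
         region_end_codon = region_end_codon,
         scheme = scheme,
         wt_codons = codons),
    class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat(sprintf("library_design: %d nt (ORF codons %d-%d), region %d-%d, scheme %s\n",
              nchar(x$wt_nt_seq), x$orf_codon_offset,
              x$orf_codon_offset + length(x$wt_codons) - 1L,
              x$region_start_codon, x$region_end_codon, x$scheme))
  invisible(x)
}

#' Translate DNA codons under the standard genetic code
#'
#' @param codons Character vector of 3-letter DNA codons.
#' @return Character vector of single-letter amino acids, with \code{"*"} for
#'   stop codons.
#' @export
translate_codons <- function(codons) {
  codons <- toupper(codons)
  bad <- !grepl("^[ACGT]{3}$", codons)
  if (any(bad))
    stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Wild-type codon at an ORF codon position
#'
#' @param design A \code{library_design}.
#' @param codon_position 1-based ORF codon index.
#' @return 3-letter codon string.
#' @export
wt_codon <- function(design, codon_position) {
  stopifnot(inherits(design, "library_design"))
  cod <- design$wt_codons[as.character(codon_position)]
  if (anyNA(cod)) stop("codon_position outside wt_nt_seq")
  unname(cod)
}

# The 64 (NNN) or 32 (NNK, third base G/T) codons of a degeneracy scheme,
# lexicographically ordered.
scheme_codons <- function(scheme = c("NNN", "NNK")) {
  scheme <- match.arg(scheme)
  b <- c("A", "C", "G", "T")
  third <- if (scheme == "NNK") c("G", "T") else b
  grid <- expand.grid(n3 = third, n2 = b, n1 = b, stringsAsFactors = FALSE)
  sort(paste0(grid$n1, grid$n2, grid$n3))
}

#' Annotate a single-codon variant
#'
#' Classifies a mutant codon at a given position as \code{wt_identical}
#' (identical to the wild-type codon), \code{silent} (different codon, same
#' amino acid), \code{missense} or \code{nonsense}, and builds the amino-acid
#' change key \code{"<wtAA>-<position>-<mutAA>"} (e.g. \code{"I-87-W"}).
#'
#' @param design A \code{library_design}.
#' @param codon_position 1-based ORF codon index within the mutagenized region.
#' @param mutant_codon 3-letter DNA codon.
#' @return A one-row data.frame with columns \code{codon_position},
#'   \code{wt_codon}, \code{mutant_codon}, \code{wt_aa}, \code{mut_aa},
#'   \code{variant_class}, \code{aa_change_key}.
#' @export
annotate_variant <- function(design, codon_position, mutant_codon) {
  stopifnot(inherits(design, "library_design"))
  codon_position <- as.integer(codon_position)
  if (any(codon_position < design$region_start_codon |
          codon_position > design$region_end_codon))
    stop("codon_position outside the mutagenized region")
  mutant_codon <- toupper(mutant_codon)
  wt <- design$wt_codons[as.character(codon_position)]
  wt_aa <- translate_codons(wt)
  mut_aa <- translate_codons(mutant_codon)
  cls <- ifelse(mutant_codon == wt, "wt_identical",
         ifelse(mut_aa == "*", "nonsense",
         ifelse(mut_aa == wt_aa, "silent", "missense")))
  data.frame(codon_position = codon_position,
             wt_codon = unname(wt),
             mutant_codon = mutant_codon,
             wt_aa = wt_aa,
             mut_aa = mut_aa,
             variant_class = cls,
             aa_change_key = paste(wt_aa, codon_position, mut_aa, sep = "-"),
             stringsAsFactors = FALSE)
}

#' Enumerate all single-codon variants of a library design
#'
#' Substitutes every codon of the mutagenized region by every codon of the
#' degeneracy scheme (64 per position for NNN, 32 for NNK). The wild-type
#' codon itself is retained as the \code{wt_identical} sentinel variant, since
#' downstream scoring normalizes against it. Rows are ordered by position,
#' then codon (lexicographic).
#'
#' @param design A \code{library_design}.
#' @return A data.frame with one row per variant (see
#'   \code{\link{annotate_variant}} for columns).
#' @export
enumerate_variants <- function(design) {
  stopifnot(inherits(design, "library_design"))
  positions <- seq(design$region_start_codon, design$region_end_codon)
  codons <- scheme_codons(design$scheme)
  annotate_variant(design,
                   rep(positions, each = length(codons)),
                   rep(codons, times = length(positions)))
}

#' Reconstruct the mutant nucleotide sequence of a variant
#'
#' @param design A \code{library_design}.
#' @param codon_position 1-based ORF codon index.
#' @param mutant_codon 3-letter DNA codon.
#' @return Character vector of full-length mutant sequences (vectorized over
#'   positions/codons).
#' @export
variant_sequence <- function(design, codon_position, mutant_codon) {
  stopifnot(inherits(design, "library_design"))
  codon_position <- as.integer(codon_position)
  # 0-based half-open nt coordinates internally
  start0 <- (codon_position - design$orf_codon_offset) * 3L
  if (any(start0 < 0L | start0 + 3L > nchar(design$wt_nt_seq)))
    stop("codon_position outside wt_nt_seq")
  pre <- substr(rep(design$wt_nt_seq, length(start0)), 1L, start0)
  post <- substring(design$wt_nt_seq, start0 + 4L)
  paste0(pre, toupper(mutant_codon), post)
}

#' Read or write a library design as a key/value text config
#'
#' The design file is YAML with keys \code{wt_nt_seq} (inline sequence or a
#' path to a FASTA file), \code{orf_codon_offset}, \code{region_start_codon},
#' \code{region_end_codon} and \code{scheme}.
#'
#' @param path File path.
#' @return \code{read_design} returns a \code{library_design};
#'   \code{write_design} returns \code{path} invisibly.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("wt_nt_seq", "region_start_codon", "region_end_codon", "scheme")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("design file missing field(s): ",
                         paste(miss, collapse = ", "))
  seqs <- cfg$wt_nt_seq
  if (file.exists(seqs) && !grepl("^[ACGTacgt]+$", seqs)) {
    fa <- Biostrings::readDNAStringSet(seqs)
    seqs <- as.character(fa[[1L]])
  }
  library_design(seqs,
                 region_start_codon = cfg$region_start_codon,
                 region_end_codon = cfg$region_end_codon,
                 orf_codon_offset = if (is.null(cfg$orf_codon_offset)) 1L else
                   cfg$orf_codon_offset,
                 scheme = cfg$scheme)
}

#' @rdname read_design
#' @param design A \code{library_design}.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "library_design"))
  yaml::write_yaml(design[c("wt_nt_seq", "orf_codon_offset",
                            "region_start_codon", "region_end_codon",
                            "scheme")], path)
  invisible(path)
}

#' Example extended-motif library design
#'
#' A fully synthetic design used in examples and tests: a 24-codon stretch of
#' a hypothetical MAP kinase kinase ORF (codons 81-104) carrying the
#' SH3-binding motif KPLPPLP at codons 93-99, with the extended-motif window
#' (codons 85-100) mutagenized under the NNK scheme. The nucleotide sequence
#' is synthetic; only the motif placement mimics the biological system.
#'
#' @param scheme Degeneracy scheme (default \code{"NNK"}).
#' @return A \code{library_design} with a 16-codon mutagenized region.
#' @export
example_design <- function(scheme = "NNK") {
  aa <- c("T", "S", "A", "D",                     # 81-84 flank
          "A", "H", "I", "Q", "Q", "V", "V", "N", # 85-92 extended motif
          "K", "P", "L", "P", "P", "L", "P",      # 93-99 canonical motif
          "S",                                    # 100
          "T", "V", "D", "G")                     # 101-104 flank
  codon_of <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTA",
                M = "ATG", N = "AAT", P = "CCA", Q = "CAA", R = "AGA",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  library_design(paste(codon_of[aa], collapse = ""),
                 region_start_codon = 85L, region_end_codon = 100L,
                 orf_codon_offset = 81L, scheme = scheme)
}

#' Write a variant annotation table as TSV
#'
#' @param variants Data.frame from \code{\link{enumerate_variants}}.
#' @param path Output file path.
#' @param meta Optional named list written as \code{# key: value} header
#'   comments.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(variants, path, meta = NULL) {
  write_tsv_checked(variants, path, meta = meta)
}
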