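test_that("demultiplexing assigns reads by barcode within one substitution", {
  man <- data.frame(sample_id = c("s1", "s2"), bait = "Sho1",
                    condition = "MTX", replicate = 1:2,
                    timepoint = "post",
                    barcode_row = c("AAAAAA", "CCCCCC"),
                    barcode_col = c("GGGGGG", "TTTTTT"),
                    stringsAsFactors = FALSE)
  body <- "ATGATG"
  reads <- c(paste0("AAAAAA", body, "GGGGGG"),   # exact -> s1
             paste0("AAAAAT", body, "GGGGGG"),   # 1 mismatch -> s1
             paste0("AAATTT", body, "GGGGGG"),   # 3 mismatches -> unassigned
             paste0("CCCCCC", body, "GGGGGG"))   # pair not in manifest -> NA
  dm <- demultiplex(reads, man)
  expect_equal(dm$sample_id, c("s1", "s1", NA, NA))
  expect_equal(dm$stripped[1], body)
  expect_equal(dm$n_unassigned, 2)
  man_dup <- man
  man_dup$barcode_row <- "AAAAAA"
  man_dup$barcode_col <- "GGGGGG"
  expect_error(demultiplex(reads, man_dup), "duplicate")
})

test_that("ambiguous barcodes (equidistant from two) are unassigned", {
  # barcodes at Hamming distance 2: their 1-neighborhoods overlap
  man <- data.frame(sample_id = c("a", "b", "c"), bait = "x",
                    condition = "c", replicate = 1:3, timepoint = "post",
                    barcode_row = c("AAAA", "AATT", "GGGG"),
                    barcode_col = c("CCCC", "CCCC", "CCCC"),
                    stringsAsFactors = FALSE)
  # AATA is 1 substitution from both AAAA and AATT
  dm <- demultiplex(paste0("AATA", "ATG", "CCCC"), man)
  expect_true(is.na(dm$sample_id))
})

test_that("read collapsing preserves the multiset and orders groups", {
  r <- c("AAA", "CCC", "AAA", "AAA", "GGG", "CCC")
  cl <- collapse_reads(r)
  expect_equal(cl$seq, c("AAA", "CCC", "GGG"))
  expect_equal(cl$n, c(3L, 2L, 1L))
  expect_equal(sum(cl$n), length(r))
  expect_equal(nrow(collapse_reads(character(0))), 0)
  expect_setequal(rep(cl$seq, cl$n), r)
})

test_that("alignment matches the expected structure on known cases", {
  ref <- "ATGAAACCAGGT"
  al <- align_to_reference(ref, ref)
  expect_equal(al$score, 5 * nchar(ref))
  expect_equal(al$aligned_query, ref)

  sub <- "ATGAAACAAGGT"  # single substitution
  al2 <- align_to_reference(sub, ref)
  expect_equal(al2$score, 5 * 11 - 4)
  expect_false(grepl("-", al2$aligned_query))

  del3 <- "ATGAAAGGT"    # one 3-nt deletion: one contiguous gap
  al3 <- align_to_reference(del3, ref)
  expect_equal(al3$score, 5 * 9 - (10 + 3 * 0.5))
  expect_equal(nchar(gsub("[^-]", "", al3$aligned_query)), 3)
  # affine gaps: one length-3 gap beats three isolated gaps
  expect_gt(-(10 + 3 * 0.5), -3 * (10 + 0.5))
  expect_error(align_to_reference("AXA", ref), "A, C, G, T")
})

test_that("alignment scores agree with an independent DP oracle", {
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(5:20, 1)
    n2 <- sample(5:20, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n1, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), n2, TRUE), collapse = "")
    expect_equal(align_to_reference(a, b)$score, nw_score_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("variant calls follow the single-codon policy", {
  d <- example_design()
  wt <- d$wt_nt_seq
  v87 <- variant_sequence(d, 87, "TGG")
  al <- align_to_reference(v87, wt)
  cv <- call_variant(al$aligned_query, al$aligned_ref, d)
  expect_equal(cv$class, "variant")
  expect_equal(cv$codon_position, 87L)
  expect_equal(cv$mutant_codon, "TGG")

  expect_equal(call_variant(wt, wt, d)$class, "wt_identical")

  two <- variant_sequence(d, 87, "TGG")
  substr(two, (90 - 81) * 3 + 1, (90 - 81) * 3 + 1) <- "T"
  al2 <- align_to_reference(two, wt)
  expect_equal(call_variant(al2$aligned_query, al2$aligned_ref, d)$class,
               "multi_codon")

  # mismatch confined to a codon outside the mutagenized region
  flank <- wt
  substr(flank, 1, 1) <- "T"
  al3 <- align_to_reference(flank, wt)
  expect_equal(call_variant(al3$aligned_query, al3$aligned_ref, d)$class,
               "multi_codon")

  gap <- paste0(substr(wt, 1, 30), substr(wt, 34, nchar(wt)))
  al4 <- align_to_reference(gap, wt)
  expect_equal(call_variant(al4$aligned_query, al4$aligned_ref, d)$class,
               "indel_other")
})

test_that("tabulation yields frequencies over assigned reads only", {
  d <- tiny_design("NNN")
  meta <- data.frame(sample_id = "s1", bait = "Sho1", condition = "MTX",
                     replicate = 1L, timepoint = "post",
                     stringsAsFactors = FALSE)
  calls <- data.frame(sample_id = "s1",
                      class = c("variant", "wt_identical", "multi_codon"),
                      codon_position = c(2L, NA, NA),
                      mutant_codon = c("TTT", NA, NA),
                      n = c(60L, 40L, 25L), stringsAsFactors = FALSE)
  tab <- tabulate_counts(calls, d, meta)
  expect_equal(tab$depth[1], 100L)
  expect_equal(tab$frequency[which(tab$mutant_codon == "TTT" &
                                     tab$codon_position == 2L)], 0.6)
  expect_equal(tab$frequency[tab$variant_class == "wt_identical"], 0.4)
  expect_equal(tab$count[tab$variant_class == "multi_codon"], 25L)
  expect_true(is.na(tab$frequency[tab$variant_class == "multi_codon"]))
  expect_equal(sum(tab$frequency, na.rm = TRUE), 1)
  # enumerated but unobserved variants are present with zero counts
  expect_gt(sum(tab$count == 0), 100)
  # degenerate sample: only unusable reads
  calls2 <- data.frame(sample_id = "s1", class = "multi_codon",
                       codon_position = NA_integer_,
                       mutant_codon = NA_character_, n = 5L,
                       stringsAsFactors = FALSE)
  tab2 <- tabulate_counts(calls2, d, meta)
  expect_equal(unique(tab2$depth), 0L)
  expect_true(all(is.na(tab2$frequency)))
  expect_error(tabulate_counts(transform(calls, sample_id = "zz"), d, meta),
               "unknown sample_id")
})

test_that("reads round-trip exactly through the caller at error rate 0", {
  d <- tiny_design("NNK")
  p <- sim_params(seed = 21, read_depth = 4000, conditions = "MTX_sorbitol",
                  baits = "Sho1", error_rate = 0, barcode_length = 5)
  cnt <- simulate_counts(d, simulate_effects(d, p), p)
  man <- build_manifest(cnt, barcode_length = 5)
  fq <- withr::local_tempfile(fileext = ".fastq")
  emit_reads(d, cnt, p, man, fq)
  rec <- call_variants(fq, d, man)
  k <- function(x) paste(x$sample_id, x$codon_position, x$mutant_codon)
  m <- match(k(cnt), k(rec))
  expect_false(anyNA(m))
  expect_equal(rec$count[m], cnt$count)
  expect_equal(sum(rec$count[rec$variant_class %in%
                               c("multi_codon", "indel_other")]), 0)
  # zero-count variants emit no reads
  expect_equal(sum(rec$count), sum(cnt$count))
})
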