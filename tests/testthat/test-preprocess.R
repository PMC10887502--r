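test_that("levenshtein matches hand-checkable cases and the DP oracle", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("ACGT", "ACGA"), 1L)
  expect_equal(levenshtein("", "ACG"), 3L)
  expect_equal(levenshtein("GATTACA", "GACTATA"), 2L)  # frozen from the DP oracle
  expect_equal(lev_oracle("GATTACA", "GACTATA"), 2L)

  lens <- mitodemix:::with_seed(7L, sample(0:30, 2000, replace = TRUE))
  a <- random_dna(1000, 1, seed = 1)  # placeholder, regenerated below
  pairs <- mitodemix:::with_seed(8L, lapply(seq_len(1000), function(i) {
    c(paste(sample(c("A", "C", "G", "T"), lens[2 * i - 1], TRUE), collapse = ""),
      paste(sample(c("A", "C", "G", "T"), lens[2 * i], TRUE), collapse = ""))
  }))
  for (p in pairs) {
    expect_identical(levenshtein(p[1], p[2]), as.integer(lev_oracle(p[1], p[2])))
  }
})

test_that("levenshtein is symmetric and satisfies the triangle inequality", {
  trips <- mitodemix:::with_seed(9L, lapply(1:100, function(i) {
    vapply(1:3, function(j) paste(sample(c("A", "C", "G", "T"),
                                         sample(1:25, 1), TRUE), collapse = ""),
           character(1))
  }))
  for (t in trips) {
    ab <- levenshtein(t[1], t[2]); ba <- levenshtein(t[2], t[1])
    bc <- levenshtein(t[2], t[3]); ac <- levenshtein(t[1], t[3])
    expect_identical(ab, ba)
    expect_lte(ac, ab + bc)
    expect_identical(ab == 0L, t[1] == t[2])
  }
})

make_pair <- function(frag, q1 = 30L, q2 = 30L, rl = nchar(frag)) {
  s1 <- substr(frag, 1, rl)
  s2 <- mitodemix:::revcomp(substr(frag, nchar(frag) - rl + 1, nchar(frag)))
  read_pairs("p1", s1, strrep(mitodemix:::int_to_phred(q1), rl),
             s2, strrep(mitodemix:::int_to_phred(q2), rl))
}

test_that("identical overlapping mates pass through unchanged", {
  frag <- random_dna(1, 80, seed = 11)
  p <- make_pair(frag)
  out <- correct_pair(p)
  expect_identical(out$seq1, p$seq1)
  expect_identical(out$seq2, p$seq2)
})

test_that("a single disagreement is replaced by the higher-quality call in both mates", {
  frag <- random_dna(1, 80, seed = 12)
  p <- make_pair(frag, q1 = 12L, q2 = 35L)
  truth <- substr(p$seq1, 30, 30)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  substr(p$seq1, 30, 30) <- wrong     # read 1 (Q12) disagrees with read 2 (Q35)
  out <- correct_pair(p)
  expect_identical(substr(out$seq1, 30, 30), truth)
  expect_identical(out$seq2, p$seq2)
  expect_identical(substr(out$qual1, 30, 30), mitodemix:::int_to_phred(35L))
  # and symmetrically: the reverse mate is patched when read 1 wins
  p2 <- make_pair(frag, q1 = 35L, q2 = 12L)
  substr(p2$seq2, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(p2$seq2, 10, 10))[1]
  out2 <- correct_pair(p2)
  expect_identical(out2$seq2, make_pair(frag)$seq2)
})

test_that("equal qualities keep the read-1 call", {
  frag <- random_dna(1, 80, seed = 19)
  p <- make_pair(frag, q1 = 30L, q2 = 30L)
  truth <- substr(p$seq1, 40, 40)
  wrong <- setdiff(c("A", "C", "G", "T"), truth)[1]
  substr(p$seq1, 40, 40) <- wrong
  out <- correct_pair(p)
  expect_identical(substr(out$seq1, 40, 40), wrong)  # read 1 wins the tie
})

test_that("pairs with more than two disagreements pass through unchanged", {
  frag <- random_dna(1, 80, seed = 13)
  p <- make_pair(frag, q1 = 12L, q2 = 35L)
  for (pos in c(20, 40, 60)) {
    substr(p$seq1, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                        substr(p$seq1, pos, pos))[1]
  }
  out <- correct_pair(p)
  expect_identical(out$seq1, p$seq1)
  expect_identical(out$seq2, p$seq2)
})

test_that("pair correction is idempotent", {
  ref <- synthetic_reference()
  tree <- synthetic_phylotree(ref)
  sim <- simulate_sole_source(ref, tree, haplogroup = "M7a",
                              n_fragments = 300, seed = 14)
  once <- correct_pairs(sim$pairs)
  twice <- correct_pairs(once$pairs)
  expect_identical(twice$pairs, once$pairs)
  expect_equal(twice$metrics$pairs_corrected, 0L)
})

test_that("non-overlapping mates pass through and are counted", {
  p <- read_pairs("x", random_dna(1, 60, seed = 15), strrep("?", 60),
                  random_dna(1, 60, seed = 16), strrep("?", 60))
  out <- correct_pairs(p)
  expect_identical(out$pairs$seq1, p$seq1)
  expect_true(is.na(out$offset[1]))
  expect_equal(out$metrics$pairs_no_overlap, 1L)
})

test_that("primer trimming removes terminal occurrences only", {
  primers <- primer_set(c("A", "B"), c("ACGTACGTTGCAACGGT", "TTGGCCAATTGGCCTTA"),
                        "either")
  insert <- random_dna(1, 90, seed = 17)
  read <- paste0("ACGTACGTTGCAACGGT", insert)
  tr <- trim_primers(read, primers)
  expect_identical(tr$seqs, insert)
  expect_identical(tr$report$primer_id, "A")
  # interior occurrence untouched
  mid <- paste0(substr(insert, 1, 40), "ACGTACGTTGCAACGGT", substr(insert, 41, 90))
  expect_identical(trim_primers(mid, primers)$seqs, mid)
  # primerA + insert + revcomp(primerB): both ends removed, both reported
  both <- paste0("ACGTACGTTGCAACGGT", insert, mitodemix:::revcomp("TTGGCCAATTGGCCTTA"))
  tr2 <- trim_primers(both, primers)
  expect_identical(tr2$seqs, insert)
  expect_setequal(tr2$report$primer_id, c("A", "B"))
  expect_equal(sum(tr2$report$bases), 34L)
})

test_that("primer trimming tolerates one mismatch but not two, and never lengthens", {
  pset <- primer_set("P", "ACGTACGTTGCAACGGT", "5p")
  insert <- random_dna(1, 60, seed = 18)
  one <- paste0("ACGTACGTTGCAACGGA", insert)   # 1 mismatch at primer base 17
  two <- paste0("ACGAACGTTGCAACGGA", insert)   # 2 mismatches
  expect_identical(trim_primers(one, pset)$seqs, insert)
  expect_identical(trim_primers(two, pset)$seqs, two)
  reads <- paste0(random_dna(20, 10, seed = 19), insert)
  tr <- trim_primers(reads, pset)
  expect_true(all(nchar(tr$seqs) <= nchar(reads)))
  expect_equal(sum(nchar(reads)) - sum(nchar(tr$seqs)), sum(tr$report$bases))
})

test_that("degenerate primer bases are expanded to explicit variants", {
  pset <- primer_set("D", "ACGTRCGT", "5p")
  expect_setequal(pset$sequence, c("ACGTACGT", "ACGTGCGT"))
  expect_error(primer_set("bad", "ACGZ", "5p"), "invalid base")
})

test_that("circularization appends the leading pad bases", {
  toy <- mito_reference("ACGTACGTAC", name = "toy")
  expect_identical(circularize_reference(toy, 3L), "ACGTACGTACACG")
  expect_error(circularize_reference(toy, 0L), "pad")
  expect_error(circularize_reference(toy, 10L), "pad")
})

test_that("reads spanning the origin align contiguously on the padded reference", {
  ref <- mito_reference(random_dna(1, 400, seed = 20))
  padded <- circularize_reference(ref, 60L)
  # a read covering positions 391..420 on the circle (wraps at 400)
  read <- substr(padded, 391, 420)
  al <- align_to_reference(read, kmer_index(padded))
  expect_true(al$mapped)
  expect_equal(al$start, 391L)
  expect_equal(al$lev, 0)
  expect_false(al$soft_clipped)
})

test_that("reads overhanging the indexed sequence are soft-clipped", {
  ref_seq <- random_dna(1, 300, seed = 21)
  read <- paste0(substr(ref_seq, 281, 300), random_dna(1, 20, seed = 22))
  al <- align_to_reference(read, kmer_index(ref_seq))
  expect_true(al$soft_clipped)
})

test_that("NUMT candidate and classification rules follow strict inequalities", {
  al <- data.frame(read_id = c("a", "b", "c", "d"),
                   mapped = c(TRUE, TRUE, TRUE, FALSE),
                   soft_clipped = c(FALSE, FALSE, TRUE, FALSE),
                   lev = c(2, 3, 1, Inf))
  expect_identical(numt_candidates(al), "a")

  nuc <- c(a = 1, b = 2, c = 0)
  mito <- c(a = 4, b = 2, c = Inf)
  expect_identical(classify_numts(c("a", "b", "c"), nuc, mito), c("a", "c"))
  expect_identical(classify_numts(character(0), nuc, mito), character(0))
  expect_error(classify_numts("z", nuc, mito), "missing a distance")
})

test_that("removal never touches non-candidate reads", {
  ref <- synthetic_reference()
  tree <- synthetic_phylotree(ref)
  cat_ <- build_numt_catalogue(ref)
  sim <- simulate_sole_source(ref, tree, haplogroup = "H1",
                              n_fragments = 1500, seed = 23)
  mix <- spike_numts(list(pairs = sim$pairs, manifest = sim$manifest),
                     cat_, 100L, seed = 24)
  pre <- preprocess_pipeline(mix$pairs, NULL, ref, cat_$sequences)
  expect_setequal(pre$removed_ids, mix$manifest$numt_ids)
  expect_equal(pre$metrics$numts_removed, 100L)
  expect_gte(pre$metrics$numt_candidates, 100L)
})

test_that("an empty stream produces empty output and zero metrics", {
  ref <- synthetic_reference()
  empty <- read_pairs(character(0), character(0), character(0),
                      character(0), character(0))
  pre <- preprocess_pipeline(empty, NULL, ref, NULL)
  expect_equal(nrow(pre$pairs), 0L)
  expect_equal(pre$metrics$input_fragments, 0L)
  expect_equal(pre$metrics$numts_removed, 0L)
})

test_that("with no primers, NUMTs or discordance the pipeline is a byte-level no-op", {
  ref <- synthetic_reference()
  tree <- synthetic_phylotree(ref)
  sim <- simulate_sole_source(ref, tree, haplogroup = "B2", n_fragments = 400,
                              seed = 25, error_rate = 0)
  pre <- preprocess_pipeline(sim$pairs, NULL, ref, NULL)
  expect_identical(pre$pairs$seq1, sim$pairs$seq1)
  expect_identical(pre$pairs$seq2, sim$pairs$seq2)
  expect_identical(pre$pairs$qual1, sim$pairs$qual1)
  expect_equal(pre$metrics$fragments_out, 400L)
})
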