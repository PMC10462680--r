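test_that("revcomp handles the alphabet and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT")          # palindrome
  expect_equal(revcomp("AAC"), "GTT")
  expect_equal(revcomp("ANT"), "ANT")            # N maps to N
  expect_error(revcomp("ACXG"), "invalid character")
  set.seed(21)
  for (i in 1:25) {
    s <- rseq(sample(5:200, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("k-mer index canonicalises and matches brute-force enumeration", {
  set.seed(22)
  k <- 11L
  kmer <- rseq(k)
  # contig containing a k-mer and its reverse complement: one index entry,
  # two occurrences
  ctg <- xeno_seqs("c", paste0(kmer, revcomp(kmer)))
  idx <- build_kmer_index(ctg, k = k)
  occ <- kmer_occurrences(idx, kmer)
  expect_equal(nrow(occ), 2)
  expect_setequal(occ$pos, c(0, 11))
  # identical lookup under the reverse complement (canonicality)
  expect_equal(nrow(kmer_occurrences(idx, revcomp(kmer))), 2)

  # distinct canonical k-mer count agrees with an R enumeration oracle
  s <- rseq(300)
  idx2 <- build_kmer_index(xeno_seqs("c", s), k = k)
  subs <- substring(s, 1:(300 - k + 1), 1:(300 - k + 1) + k - 1)
  canon <- pmin(subs, revcomp(subs))
  expect_equal(kmer_index_info(idx2)$n_kmers, length(unique(canon)))

  # contigs shorter than k contribute nothing; N voids covering k-mers
  expect_equal(kmer_index_info(build_kmer_index(xeno_seqs("s", "ACGT"),
                                                k = k))$n_kmers, 0)
  withN <- paste0(rseq(5), "N", rseq(5))        # every 11-mer touches the N
  expect_equal(kmer_index_info(build_kmer_index(xeno_seqs("n", withN),
                                                k = k))$n_kmers, 0)
})

test_that("exact substrings map on both strands with identity 1", {
  set.seed(23)
  ctg <- xeno_seqs("c1", rseq(2000))
  idx <- build_kmer_index(ctg, k = 21)
  rd <- substr(ctg$seq, 501, 600)
  m <- map_reads(xeno_seqs(c("f", "r"), c(rd, revcomp(rd))), idx)
  expect_true(all(m$mapped))
  expect_equal(m$identity, c(1, 1))
  expect_equal(m$aligned_frac, c(1, 1))
  expect_equal(m$strand, c("+", "-"))
  expect_equal(m$s_start, c(500, 500))
  expect_equal(m$s_end, c(600, 600))

  # too-short reads are flagged, not errors
  short <- map_reads(xeno_seqs("s", "ACGTACGT"), idx)
  expect_false(short$mapped)
  expect_true(short$too_short)
})

test_that("reads below the identity threshold are rejected (oracle check)", {
  set.seed(24)
  ctg <- rseq(10000)
  idx <- build_kmer_index(xeno_seqs("c", ctg), k = 21)

  # a random 100-mer sharing no 21-mer with the contig is unmapped
  repeat {
    rd <- rseq(100)
    if (!shares_kmer(rd, ctg, 21)) break
  }
  expect_false(map_reads(xeno_seqs("r", rd), idx)$mapped)

  # 12 spread substitutions push best identity below 0.90: never mapped
  rd2 <- mutate_at(substr(ctg, 2001, 2100), seq(5, 93, by = 8))
  orc <- sw_oracle(rd2, ctg)
  expect_lt(orc$identity, 0.90)
  expect_false(map_reads(xeno_seqs("r2", rd2), idx)$mapped)
})

test_that("per-base coverage does interval arithmetic and conserves depth", {
  mk <- function(s, e) data.frame(s_start = s, s_end = e)
  expect_equal(per_base_coverage(10, mk(numeric(0), numeric(0))),
               rep(0L, 10))
  cov <- per_base_coverage(1000, mk(0, 100))
  expect_equal(cov, c(rep(1L, 100), rep(0L, 900)))
  cov2 <- per_base_coverage(200, mk(c(0, 50), c(100, 150)))
  expect_equal(unique(cov2[51:100]), 2L)
  expect_equal(sum(cov2), 200)                 # conservation
  expect_error(per_base_coverage(50, mk(0, 60)), "out of bounds")
})

test_that("self- and reverse-complement alignments give full-length HSPs", {
  set.seed(25)
  s <- xeno_seqs("s", rseq(500))
  h <- find_hsps(s, s)
  expect_equal(nrow(h), 1)
  expect_equal(h$length, 500)
  expect_equal(h$identity, 1)
  expect_equal(h$strand, "+")
  h2 <- find_hsps(xeno_seqs("q", revcomp(s$seq)), s)
  expect_equal(h2$strand, "-")
  expect_equal(h2$length, 500)
  expect_equal(h2$identity, 1)
})

test_that("a 300 bp shared block with 3 substitutions is a 99% window", {
  set.seed(26)
  bp <- block_pair(300, 3)
  h <- find_hsps(xeno_seqs("q", bp$query), xeno_seqs("s", bp$subject))
  expect_equal(nrow(h), 1)
  expect_equal(h$win_len, 300)
  expect_equal(h$win_matches, 297)
  expect_equal(h$win_identity, 0.99)
  # block coordinates recovered exactly (0-based, past the 350 bp flank)
  expect_equal(h$win_q_start, 350)
  expect_equal(h$win_q_end, 650)
})

test_that("HSP sets are symmetric and strand-invariant", {
  set.seed(27)
  for (i in 1:5) {
    blk <- rseq(sample(200:400, 1))
    a <- xeno_seqs("a", paste0(rseq(300), blk, rseq(200)))
    b <- xeno_seqs("b", paste0(rseq(150), mutate_at(blk, c(50, 120)),
                               rseq(350)))
    hab <- find_hsps(a, b)
    hba <- find_hsps(b, a)
    expect_equal(sort(paste(hab$length, hab$matches)),
                 sort(paste(hba$length, hba$matches)))
    # reverse complementing the query flips strands, keeps stats
    hrc <- find_hsps(xeno_seqs("a", revcomp(a$seq)), b)
    expect_equal(sort(paste(hab$length, hab$matches)),
                 sort(paste(hrc$length, hrc$matches)))
    expect_true(all(hrc$strand != hab$strand))
  }
})

test_that("outfmt6 export uses 1-based inclusive coordinates, minus via swap", {
  set.seed(28)
  s <- xeno_seqs("s", rseq(400))
  h <- rbind(find_hsps(s, s),
             find_hsps(xeno_seqs("q", revcomp(s$seq)), s))
  f <- tempfile()
  write_hsps_outfmt6(h, f)
  tab <- read.delim(f, header = FALSE)
  plus <- tab[1, ]; minus <- tab[2, ]
  expect_equal(unlist(plus[, 7:10], use.names = FALSE), c(1, 400, 1, 400))
  expect_equal(unlist(minus[, 9:10], use.names = FALSE), c(400, 1))
  expect_equal(plus$V3, 100)  # percent identity
})
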