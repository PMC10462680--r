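test_that("graph construction matches brute-force canonical k-mer counting", {
  set.seed(31)
  k <- 15L
  rd <- rseq(60)
  g <- build_graph(rd, k = k)
  info <- graph_info(g)
  expect_equal(info$total_multiplicity, 60 - k + 1)

  # oracle: enumerate k-mers, canonicalise, count
  subs <- substring(rd, 1:(60 - k + 1), 1:(60 - k + 1) + k - 1)
  canon <- sort(pmin(subs, revcomp(subs)))
  edges <- graph_edges(g)
  expect_equal(edges$kmer, unique(canon))
  expect_equal(edges$count, as.integer(table(canon)[unique(canon)]),
               ignore_attr = TRUE)

  # two identical reads double every multiplicity
  g2 <- build_graph(c(rd, rd), k = k)
  expect_equal(graph_edges(g2)$count, 2L * edges$count)

  # strand canonicality: the reverse-complement read builds the same graph
  g3 <- build_graph(revcomp(rd), k = k)
  expect_identical(graph_edges(g3), edges)

  # empty input, short reads, N handling
  expect_equal(graph_info(build_graph(character(0), k = k))$n_kmers, 0)
  expect_equal(graph_info(build_graph("ACGT", k = k))$n_kmers, 0)
  gn <- build_graph(paste0(rseq(7), "N", rseq(7)), k = k)
  expect_equal(graph_info(gn)$n_kmers, 0)
})

test_that("cleaning removes read errors and is idempotent", {
  set.seed(32)
  src <- rseq(2000)
  starts <- c(seq(1, 1901, by = 20), 1901)
  clean_reads <- substring(src, starts, starts + 99)
  # 50 clean copies of one region plus a single read with one substitution
  err_read <- mutate_at(substring(src, 501, 600), 50)
  g_err <- clean_graph(build_graph(c(clean_reads, err_read), k = 21),
                       min_edge_cov = 3)
  g_ref <- clean_graph(build_graph(clean_reads, k = 21), min_edge_cov = 3)
  expect_identical(graph_edges(g_err)$kmer, graph_edges(g_ref)$kmer)

  # error-free graph survives cleaning unchanged at min_edge_cov = 1
  g0 <- build_graph(clean_reads, k = 21)
  g1 <- clean_graph(g0, min_edge_cov = 1)
  expect_identical(graph_edges(g1), graph_edges(g0))

  # fixpoint: clean(clean(g)) == clean(g), also with errors present
  noisy <- vapply(1:300, function(i) {
    s <- substring(src, p <- sample(1901, 1), p + 99)
    if (runif(1) < 0.5) mutate_at(s, sample(100, 1)) else s
  }, "")
  gc1 <- clean_graph(build_graph(noisy, k = 21))
  gc2 <- clean_graph(gc1)
  expect_identical(graph_edges(gc2), graph_edges(gc1))
})

test_that("error-free reads reconstruct their source as one unitig", {
  set.seed(33)
  k <- 31L
  src <- rseq(10000)
  starts <- sample(1:9901, 3000, TRUE)         # ~30x coverage
  reads <- substring(src, starts, starts + 99)
  flip <- runif(3000) < 0.5
  reads[flip] <- revcomp(reads[flip])
  u <- assemble_reads(reads, k = k, min_edge_cov = 2)
  expect_equal(length(u$id), 1)
  expect_gte(nchar(u$seq), 10000 - (k - 1))
  expect_lte(nchar(u$seq), 10000 + (k - 1))
  expect_true(grepl(u$seq, src, fixed = TRUE) ||
              grepl(u$seq, revcomp(src), fixed = TRUE))

  # determinism: shuffled input yields byte-identical contigs
  u2 <- assemble_reads(sample(reads), k = k, min_edge_cov = 2)
  expect_identical(u$seq, u2$seq)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(u, f1); write_fasta(u2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("unrelated sources separate; tandem repeats break the assembly", {
  set.seed(34)
  srcs <- c(rseq(5000), rseq(5000))
  reads <- unlist(lapply(srcs, function(s) {
    starts <- sample(1:(nchar(s) - 99), 1500, TRUE)
    substring(s, starts, starts + 99)
  }))
  u <- assemble_reads(reads, k = 31, min_edge_cov = 2)
  expect_equal(length(u$id), 2)
  for (s in u$seq)
    expect_true(any(vapply(srcs, function(x)
      grepl(s, x, fixed = TRUE) || grepl(s, revcomp(x), fixed = TRUE),
      logical(1))))

  # a perfect 100 bp tandem repeat creates a branching node: > 1 unitig
  rep100 <- rseq(100)
  src <- paste0(rseq(2000), rep100, rep100, rseq(2000))
  starts <- seq(1, nchar(src) - 99, by = 4)
  u2 <- assemble_reads(substring(src, starts, starts + 99),
                       k = 31, min_edge_cov = 1, min_contig_len = 100)
  expect_gt(length(u2$id), 1)
})
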