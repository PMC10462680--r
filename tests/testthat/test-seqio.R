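test_that("read_fasta parses records, folds lines and keeps descriptions", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a first contig", "ACGT", ">b", "AC", "GT", ">c", "ttnn"), f)
  x <- read_fasta(f)
  expect_equal(x$id, c("a", "b", "c"))
  expect_equal(x$desc[1], "first contig")
  expect_equal(x$seq, c("ACGT", "ACGT", "TTNN"))  # folded + normalised

  bad <- tempfile(fileext = ".fasta")
  writeLines("ACGT", bad)                         # no header at all
  expect_error(read_fasta(bad), "format error")

  empty <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", ">c", "AA"), empty)
  expect_error(read_fasta(empty), "format error")
})

test_that("FASTA round-trips through plain and gzipped files", {
  set.seed(11)
  x <- xeno_seqs(paste0("c", 1:5), vapply(1:5, function(i) rseq(137), ""),
                 desc = paste("desc", 1:5))
  for (ext in c(".fasta", ".fasta.gz")) {
    f <- tempfile(fileext = ext)
    write_fasta(x, f)
    y <- read_fasta(f)
    expect_equal(y$id, x$id)
    expect_equal(y$seq, x$seq)
    expect_equal(y$desc, x$desc)
  }
})

test_that("FASTQ round-trip is the identity on (id, seq, qual)", {
  set.seed(12)
  n <- 100
  qual <- vapply(seq_len(n), function(i)
    int_to_phred(sample(0:40, 80, TRUE)), "")
  x <- xeno_reads(paste0("r", seq_len(n)),
                  vapply(seq_len(n), function(i) rseq(80), ""), qual)
  for (ext in c(".fastq", ".fastq.gz")) {
    f <- tempfile(fileext = ext)
    write_fastq(x, f)
    y <- read_fastq(f)
    expect_identical(y$id, x$id)
    expect_identical(y$seq, x$seq)
    expect_identical(y$qual, x$qual)
  }
  # Phred+33: 'I' encodes Q40
  expect_equal(phred_to_int("IIII"), rep(40L, 4))
})

test_that("malformed FASTQ (seq/qual length mismatch) is a format error", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "format error")
  expect_error(xeno_reads("r", "ACGT", "III"), "length")
})

test_that("quality_trim matches a hand-simulated window scan", {
  # all high quality: unchanged
  r <- list(id = "a", seq = rseq(60), qual = rep(40L, 60))
  expect_identical(quality_trim(r, 4, 20, 40)$seq, r$seq)

  # 100 bases with a 20-base Q2 tail: windows of 4 are cut until the
  # trailing window mean reaches Q20, leaving 80 bases
  set.seed(13)
  r <- list(id = "b", seq = rseq(100), qual = c(rep(40L, 80), rep(2L, 20)))
  tr <- quality_trim(r, window = 4, min_mean_q = 20, min_len = 40)
  expect_identical(nchar(tr$seq), 80L)
  expect_identical(tr$seq, substr(r$seq, 1, 80))
  expect_identical(tr$qual, r$qual[1:80])

  # falling below min_len discards the read
  r <- list(id = "c", seq = rseq(50), qual = c(rep(40L, 28), rep(2L, 22)))
  expect_null(quality_trim(r, 4, 20, 40))

  # records without qualities are a contract error
  expect_error(quality_trim(list(id = "d", seq = "ACGT"), 4, 20, 1),
               "qualities")
})

test_that("trimmed reads are always prefixes; batch agrees with an oracle", {
  trim_oracle <- function(q, window, minq, minlen) {
    len <- length(q)
    while (len >= window && mean(q[(len - window + 1):len]) < minq)
      len <- len - window
    if (len < minlen) NA_integer_ else len
  }
  set.seed(14)
  n <- 200
  reads <- xeno_reads(paste0("r", 1:n),
                      vapply(1:n, function(i) rseq(100), ""),
                      vapply(1:n, function(i)
                        int_to_phred(sample(0:40, 100, TRUE)), ""))
  out <- trim_reads(reads, window = 4, min_mean_q = 20, min_len = 40)
  expect_lte(length(out$id), n)
  exp_len <- vapply(seq_len(n), function(i)
    as.integer(trim_oracle(phred_to_int(reads$qual[i]), 4, 20, 40)),
    NA_integer_)
  expect_identical(out$id, reads$id[!is.na(exp_len)])
  for (j in seq_along(out$id)) {
    i <- match(out$id[j], reads$id)
    expect_identical(nchar(out$seq[j]), as.integer(exp_len[i]))
    expect_identical(out$seq[j], substr(reads$seq[i], 1, exp_len[i]))
  }
})

test_that("manifest loading validates structure and round-trips", {
  mf <- write_dummy_manifest(file.path(tempdir(), "man1"))
  m <- load_manifest(mf)
  expect_s3_class(m, "xeno_manifest")
  expect_equal(nrow(m), 4)
  # write/load round trip preserves the table
  mf2 <- tempfile(fileext = ".tsv")
  write_manifest(m, mf2)
  m2 <- load_manifest(mf2)
  expect_equal(as.data.frame(m2), as.data.frame(m))
  # case-insensitive tokens (paths already resolved to absolute by load)
  raw <- as.data.frame(m)
  raw$treatment <- tolower(raw$treatment)
  raw$role <- toupper(raw$role)
  f3 <- tempfile(fileext = ".tsv")
  write.table(raw, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(load_manifest(f3)$treatment, m$treatment)
})

test_that("manifest validation rejects the documented failure modes", {
  dir <- file.path(tempdir(), "man2")
  mf <- write_dummy_manifest(dir)
  m <- read.delim(mf, stringsAsFactors = FALSE)
  m$reads1 <- file.path(dir, m$reads1)

  dup <- m; dup$timepoint[2] <- 0     # duplicate (community, timepoint)
  expect_error(validate_manifest(dup), "duplicate")

  orphan <- m[m$role == "derived", ]  # derived without any ancestor
  expect_error(validate_manifest(orphan), "earlier timepoint")

  badtr <- m; badtr$treatment[1] <- "x"
  expect_error(validate_manifest(badtr), "allowed values are H, V")

  gone <- m; gone$reads1[1] <- file.path(dir, "absent.fastq")
  expect_error(validate_manifest(gone), "not found")
})
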