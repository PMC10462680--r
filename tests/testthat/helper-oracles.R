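# shared helpers: random sequences, constructed fixtures, independent oracles

rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# deterministic substitution: replace base at 1-based positions by the next
# base in A->C->G->T->A order
mutate_at <- function(seq, positions) {
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in positions) substr(seq, p, p) <- nxt[[substr(seq, p, p)]]
  seq
}

# query/subject contig pair sharing one block, embedded in adversarial
# homopolymer flanks (A vs C) so no alignment can extend past the block
block_pair <- function(block_len = 300L, nsub = 0L, flank = 350L) {
  blk <- rseq(block_len)
  mut <- if (nsub > 0) {
    pos <- round(seq(1, block_len, length.out = nsub + 2))
    mutate_at(blk, pos[2:(nsub + 1)])
  } else blk
  list(query = paste0(strrep("A", flank), blk, strrep("A", flank)),
       subject = paste0(strrep("C", flank), mut, strrep("C", flank)),
       block = blk)
}

# independent Smith-Waterman oracle (Biostrings, unbanded, same scoring as
# the mapper: match +1 / mismatch -2 / linear gap -3); best over both strands
sw_oracle <- function(read, contig) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  one <- function(r) {
    a <- Biostrings::pairwiseAlignment(r, contig, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 3)
    cols <- nchar(as.character(Biostrings::pattern(a)))  # incl. gap columns
    list(score = Biostrings::score(a),
         identity = Biostrings::nmatch(a) / cols,
         frac = (BiocGenerics::end(Biostrings::pattern(a)) -
                 BiocGenerics::start(Biostrings::pattern(a)) + 1) /
                nchar(read))
  }
  f <- one(read)
  r <- one(revcomp(read))
  if (r$score > f$score) r else f
}

# exists-semantics oracle for substitution-only cases: is there a gapless
# alignment window of >= min_frac of the read with identity >= min_id on
# either strand? Scans every diagonal; rows are prefiltered by total match
# count before the exact window scan.
exists_qualifying_window <- function(read, contig, min_id = 0.90,
                                     min_frac = 0.60,
                                     require_seed_run = 0) {
  L <- nchar(read)
  wmin <- ceiling(min_frac * L)
  scan_one <- function(r) {
    Rv <- strsplit(r, "")[[1]]
    Cv <- strsplit(contig, "")[[1]]
    m <- length(Cv)
    if (m < wmin) return(FALSE)
    for (d in (-(L - wmin)):(m - wmin)) {   # read pos i sits at contig d+i
      i0 <- max(1, 1 - d)
      i1 <- min(L, m - d)
      ov <- i1 - i0 + 1
      if (ov < wmin) next
      mv <- Rv[i0:i1] == Cv[(d + i0):(d + i1)]
      if (sum(mv) < min_id * wmin) next
      if (require_seed_run > 0) {
        # a seed-and-extend mapper can only reach this diagonal through an
        # exact k-mer: require an intact match run of that length
        runs <- rle(mv)
        if (!any(runs$lengths >= require_seed_run & runs$values)) next
      }
      ms <- cumsum(c(0, mv))
      for (w in wmin:ov) {
        if (any(ms[(w + 1):(ov + 1)] - ms[1:(ov - w + 1)] >=
                min_id * w - 1e-9)) return(TRUE)
      }
    }
    FALSE
  }
  scan_one(read) || scan_one(revcomp(read))
}

# does the read share an exact k-mer with the contig (either strand)?
shares_kmer <- function(read, contig, k = 21L) {
  subs <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  }
  length(intersect(subs(read), c(subs(contig), subs(revcomp(contig))))) > 0
}

# session-level cache for expensive end-to-end fixtures
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# run a benchmark scenario end to end and score it
run_and_score <- function(scenario, seed, workers = 1L,
                          params = xeno_params()) {
  sim <- file.path(tempdir(), paste0("sim_", substr(tempfile(""), 1, 0),
                                     basename(tempfile("b"))))
  out <- file.path(tempdir(), basename(tempfile("run")))
  bm <- make_benchmark(scenario, sim, seed = seed)
  res <- suppressMessages(xeno_run(bm$manifest, out, params,
                                   workers = workers))
  xen <- list()
  for (sid in bm$manifest$sample_id[bm$manifest$role == "derived"]) {
    cid <- bm$manifest$community_id[bm$manifest$sample_id == sid]
    x <- xenotrace:::read_fasta_or_empty(
      file.path(out, "xenotypic", paste0(sid, ".fasta")))
    if (length(x$id))
      xen[[cid]] <- if (is.null(xen[[cid]])) x else
        xeno_seqs(c(xen[[cid]]$id, x$id), c(xen[[cid]]$seq, x$seq))
  }
  score <- score_benchmark(bm$truth, res$links, xen, bm$elements)
  list(bm = bm, res = res, xen = xen, score = score, outdir = out,
       simdir = sim)
}

# minimal on-disk manifest whose read files exist (content rarely used)
write_dummy_manifest <- function(dir, communities = c("A", "B"),
                                 treatments = c("H", "H")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- NULL
  for (i in seq_along(communities)) {
    for (tp in 0:1) {
      sid <- sprintf("%s_t%d", communities[i], tp)
      fq <- file.path(dir, paste0(sid, ".fastq"))
      writeLines(c("@r1", "ACGTACGTACGTACGTACGTACGTACGT", "+",
                   strrep("I", 28)), fq)
      rows <- rbind(rows, data.frame(
        sample_id = sid, community_id = communities[i],
        treatment = treatments[i], timepoint = tp,
        role = if (tp == 0) "ancestral" else "derived",
        reads1 = basename(fq), stringsAsFactors = FALSE))
    }
  }
  mf <- file.path(dir, "manifest.tsv")
  write.table(rows, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  mf
}
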