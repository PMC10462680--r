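#' Reverse complement
#'
#' @param seq character vector over the alphabet A, C, G, T, N (case kept
#'   upper on output); any other character is an error.
#' @return The reverse complement of each element; an involution.
#' @examples
#' revcomp("AAC")
#' @export
revcomp <- function(seq) revcomp_cpp(toupper(as.character(seq)))

#' Build a canonical k-mer index over a contig set
#'
#' Every N-free k-mer of the contigs is stored under its canonical form
#' (the lexicographically smaller of the k-mer and its reverse complement),
#' so a k-mer and its reverse complement share one index entry. The index is
#' the shared seed source for both read mapping ([map_reads()]) and HSP
#' discovery ([find_hsps()]).
#'
#' @param contigs an [xeno_seqs] object (an empty one yields an empty index).
#' @param k odd k-mer size in `[11, 31]`.
#' @return An object of class `xeno_kmer_index`.
#' @export
build_kmer_index <- function(contigs, k = 21L) {
  stopifnot(inherits(contigs, "xeno_seqs"))
  ptr <- build_kmer_index_cpp(contigs$id, contigs$seq, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), names = contigs$id),
            class = "xeno_kmer_index")
}

#' @export
print.xeno_kmer_index <- function(x, ...) {
  info <- kmer_index_info_cpp(x$ptr)
  cat("xeno_kmer_index: k =", info$k, "|", info$n_contigs, "contigs |",
      info$n_kmers, "canonical k-mers |", info$total_len, "bp\n")
  invisible(x)
}

#' Occurrences of k-mers in an index
#'
#' @param index an `xeno_kmer_index`.
#' @param kmers character vector of k-mers (length must equal the index k).
#' @return A data.frame with one row per occurrence: `kmer`, `contig`,
#'   `pos` (0-based) and `fwd_is_canonical`.
#' @export
kmer_occurrences <- function(index, kmers) {
  stopifnot(inherits(index, "xeno_kmer_index"))
  kmer_lookup_cpp(index$ptr, toupper(kmers))
}

#' @rdname kmer_occurrences
#' @export
kmer_index_info <- function(index) kmer_index_info_cpp(index$ptr)

#' Map reads against an indexed contig set
#'
#' Seed-and-extend mapping: canonical k-mer seed hits are grouped by
#' (contig, strand, diagonal) and each candidate group is scored by a banded
#' local alignment (match +1, mismatch -2, linear gap -3). A read is mapped
#' when some candidate alignment contains a window with identity at least
#' `min_identity` spanning at least `min_aligned_frac` of the read (the
#' window scan makes the decision independent of which co-optimal traceback
#' the aligner happens to return). The reported placement is the best
#' qualifying window, chosen deterministically: highest window score, then
#' lexicographic contig id, then smallest contig position. Reads shorter
#' than the seed size are reported unmapped with `too_short = TRUE`. Each
#' mate of a pair is classified independently.
#'
#' @param reads an [xeno_reads] or [xeno_seqs] object.
#' @param index an `xeno_kmer_index` (its k is the seed size).
#' @param min_identity minimum alignment identity (matches / columns).
#' @param min_aligned_frac minimum fraction of the read covered by the
#'   alignment.
#' @param band alignment band half-width.
#' @return A data.frame with one row per read: `id`, `mapped`, `too_short`,
#'   and for mapped reads the placement (`contig`, `s_start`/`s_end`
#'   0-based half-open on the contig forward strand, `strand`, `identity`,
#'   `aligned_frac`, `score`).
#' @export
map_reads <- function(reads, index, min_identity = 0.90,
                      min_aligned_frac = 0.60, band = 16L) {
  stopifnot(inherits(index, "xeno_kmer_index"))
  map_reads_cpp(index$ptr, reads$id, reads$seq, min_identity,
                min_aligned_frac, as.integer(band), 1L, -2L, 3L, 32L)
}

#' @rdname map_reads
#' @param read a single record (list with `id` and `seq`).
#' @return `map_read` returns a one-row data.frame.
#' @export
map_read <- function(read, index, min_identity = 0.90,
                     min_aligned_frac = 0.60, band = 16L) {
  map_reads(xeno_seqs(read$id, read$seq), index, min_identity,
            min_aligned_frac, band)
}

#' Find high-scoring segment pairs (HSPs) between queries and subjects
#'
#' BLAST-like local alignment: shared canonical k-mer seeds are chained
#' along diagonals and each chain is extended by a banded local alignment
#' (match +1, mismatch -2, linear gap -3; extension abandons scores more
#' than `x_drop` below the running maximum by construction of the local
#' recurrence). Overlapping HSPs on the same (subject, strand) keep the
#' highest score. Subject coordinates are always reported on the subject
#' forward strand; all coordinates are 0-based half-open.
#'
#' In addition to whole-HSP statistics, the longest alignment window whose
#' identity is at least `win_id` is reported per HSP (`win_len`,
#' `win_matches`, `win_identity` and its coordinates). Donor linking
#' qualifies HSPs on this window, so that a shared block is not disqualified
#' by a few chance-matching columns of flanking extension.
#'
#' @param query an [xeno_seqs] object of query contigs.
#' @param subjects an [xeno_seqs] object or a prebuilt `xeno_kmer_index`.
#' @param seed_k seed k-mer size (ignored when an index is supplied).
#' @param x_drop retained for interface compatibility; extension trimming is
#'   performed by the local-alignment traceback.
#' @param band alignment band half-width.
#' @param win_id identity threshold for the reported best window.
#' @param min_hsp_len minimum HSP length (alignment columns) to report.
#' @return A data.frame with one row per HSP.
#' @export
find_hsps <- function(query, subjects, seed_k = 31L, x_drop = 20L,
                      band = 16L, win_id = 0.99, min_hsp_len = NULL) {
  stopifnot(inherits(query, "xeno_seqs"))
  idx <- if (inherits(subjects, "xeno_kmer_index")) subjects
         else build_kmer_index(subjects, k = seed_k)
  if (is.null(min_hsp_len)) min_hsp_len <- idx$k
  find_hsps_cpp(query$id, query$seq, idx$ptr, as.integer(band),
                1L, -2L, 3L, as.integer(min_hsp_len), 400L, 100L, win_id)
}

#' Per-base coverage of a contig from mapping placements
#'
#' @param contig_length contig length in bases (or an `xeno_seqs` of one
#'   contig).
#' @param mappings a data.frame with `s_start`/`s_end` columns (0-based
#'   half-open intervals on the contig); rows with `mapped == FALSE` are
#'   ignored if a `mapped` column is present.
#' @return An integer vector: `depth[i]` = number of intervals containing
#'   position i (1-based vector over 0-based positions).
#' @export
per_base_coverage <- function(contig_length, mappings) {
  if (inherits(contig_length, "xeno_seqs")) {
    stopifnot(length(contig_length$seq) == 1)
    contig_length <- nchar(contig_length$seq)
  }
  if (!is.null(mappings$mapped)) mappings <- mappings[mappings$mapped, , drop = FALSE]
  interval_depth_cpp(as.integer(contig_length),
                     as.numeric(mappings$s_start),
                     as.numeric(mappings$s_end))
}

#' Export HSPs as BLAST outfmt-6-style TSV
#'
#' Columns qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send; coordinates 1-based inclusive, with subject start > end encoding a
#' minus-strand HSP. Gap columns are counted individually (linear gap
#' penalties), so `gapopen` reports gap columns.
#'
#' @param hsps a data.frame from [find_hsps()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hsps_outfmt6 <- function(hsps, path) {
  qspan <- hsps$q_end - hsps$q_start
  sspan <- hsps$s_end - hsps$s_start
  gapcols <- (hsps$length - qspan) + (hsps$length - sspan)
  out <- data.frame(
    qseqid = hsps$qid, sseqid = hsps$sid,
    pident = round(100 * hsps$identity, 3),
    length = hsps$length,
    mismatch = hsps$length - gapcols - hsps$matches,
    gapopen = gapcols,
    qstart = hsps$q_start + 1, qend = hsps$q_end,
    sstart = ifelse(hsps$strand == "+", hsps$s_start + 1, hsps$s_end),
    send = ifelse(hsps$strand == "+", hsps$s_end, hsps$s_start + 1))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
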