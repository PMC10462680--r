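#' Sequence containers
#'
#' `xeno_seqs` holds contigs or genomes (id, optional description, sequence);
#' `xeno_reads` holds reads with Phred+33 quality strings. Sequences are
#' normalised to upper case over the alphabet A, C, G, T, N on construction.
#'
#' @param id character vector of non-empty identifiers (first whitespace
#'   token of a FASTA/FASTQ header).
#' @param seq character vector of sequences, same length as `id`.
#' @param desc optional descriptions (header text after the first token).
#' @param qual Phred+33 quality strings, same lengths as `seq`.
#' @return An object of class `xeno_seqs` or `xeno_reads`: a list with the
#'   validated, normalised fields.
#' @examples
#' xeno_seqs("chr1", "acgtn")$seq
#' @export
xeno_seqs <- function(id, seq, desc = NULL) {
  id <- as.character(id)
  seq <- normalise_seq(seq)
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  if (is.null(desc)) desc <- rep("", length(id))
  structure(list(id = id, desc = as.character(desc), seq = seq),
            class = "xeno_seqs")
}

#' @rdname xeno_seqs
#' @export
xeno_reads <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- normalise_seq(seq)
  if (any(!nzchar(id))) stop("empty read id")
  if (!is.null(qual)) {
    qual <- as.character(qual)
    if (length(qual) == 1 && length(seq) > 1)
      qual <- rep(qual, length(seq))
    if (length(qual) != length(seq))
      stop("qual and seq vector lengths differ")
    bad <- which(nchar(qual) != nchar(seq))
    if (length(bad))
      stop("read ", id[bad[1]], ": sequence length ", nchar(seq[bad[1]]),
           " != quality length ", nchar(qual[bad[1]]))
  }
  structure(list(id = id, seq = seq, qual = qual), class = "xeno_reads")
}

normalise_seq <- function(seq) {
  seq <- toupper(as.character(seq))
  gsub("[^ACGTN]", "N", seq)
}

#' @export
print.xeno_seqs <- function(x, ...) {
  cat("xeno_seqs:", length(x$id), "sequences,",
      sum(nchar(x$seq)), "bp total\n")
  invisible(x)
}

#' @export
print.xeno_reads <- function(x, ...) {
  cat("xeno_reads:", length(x$id), "reads",
      if (is.null(x$qual)) "(no qualities)" else "(with qualities)", "\n")
  invisible(x)
}

#' @export
length.xeno_seqs <- function(x) length(x$id)

#' @export
length.xeno_reads <- function(x) length(x$id)

subset_reads <- function(x, i) {
  xeno_reads(x$id[i], x$seq[i], if (!is.null(x$qual)) x$qual[i])
}

#' Read and write FASTA
#'
#' Plain or gzip-compressed files are handled transparently (detection is by
#' content, not file extension). Multi-line sequences are concatenated;
#' the description after the first whitespace of each header is kept
#' separately from the id.
#'
#' @param path file path.
#' @param x an [xeno_seqs] object.
#' @param width line-wrapping width for output.
#' @return `read_fasta` returns an [xeno_seqs]; `write_fasta` returns `path`
#'   invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("FASTA format error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(dss) == 0) stop("FASTA format error in '", path, "': no records")
  if (any(Biostrings::width(dss) == 0))
    stop("FASTA format error in '", path, "': empty sequence for record ",
         names(dss)[which(Biostrings::width(dss) == 0)[1]])
  hdr <- names(dss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  xeno_seqs(id, as.character(dss), desc)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "xeno_seqs") || inherits(x, "xeno_reads"))
  dss <- Biostrings::DNAStringSet(x$seq)
  desc <- if (!is.null(x$desc)) x$desc else rep("", length(x$id))
  names(dss) <- ifelse(nzchar(desc), paste(x$id, desc), x$id)
  Biostrings::writeXStringSet(dss, filepath = path, format = "fasta",
                              width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read and write FASTQ (Phred+33)
#'
#' Four-line records with Phred+33 quality encoding; gzip transparent.
#' `write_fastq` followed by `read_fastq` is the identity on
#' (id, sequence, quality).
#'
#' @param path file path (a trailing `.gz` compresses output).
#' @param x an [xeno_reads] object with qualities.
#' @return `read_fastq` returns an [xeno_reads]; `write_fastq` returns
#'   `path` invisibly.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "r")         # reads plain files too (content-sniffed)
  on.exit(close(con))
  lines <- readLines(con)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0 || length(lines) %% 4 != 0)
    stop("FASTQ format error in '", path,
         "': record count is not a multiple of 4 lines")
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- lines[seq(2, length(lines), by = 4)]
  sep <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ format error in '", path, "': record ", bad[1],
         " (line ", 4 * (bad[1] - 1) + 1, ") does not start with '@'")
  bad <- which(!startsWith(sep, "+"))
  if (length(bad))
    stop("FASTQ format error in '", path, "': record ", bad[1],
         " is missing its '+' separator line")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("FASTQ format error in '", path, "': record ", bad[1],
         ": sequence length ", nchar(seq[bad[1]]),
         " != quality length ", nchar(qual[bad[1]]))
  id <- sub("\\s.*$", "", substring(hdr, 2))
  xeno_reads(id, seq, qual)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "xeno_reads"))
  if (is.null(x$qual)) stop("write_fastq requires qualities")
  dss <- Biostrings::DNAStringSet(x$seq)
  names(dss) <- x$id
  Biostrings::writeXStringSet(dss, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(x$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Phred+33 conversions
#'
#' @param qual a Phred+33 quality string.
#' @param q integer Phred scores.
#' @return An integer vector, or a quality string.
#' @export
phred_to_int <- function(qual) utf8ToInt(qual) - 33L

#' @rdname phred_to_int
#' @export
int_to_phred <- function(q) intToUtf8(as.integer(q) + 33L)

#' Quality-trim a read from its 3' end
#'
#' Sliding-window mean-quality trimming: while the trailing window of
#' `window` bases has mean quality below `min_mean_q`, the window is cut and
#' the next trailing window inspected. A read ending shorter than `min_len`
#' is discarded (`NULL`). Surviving bases are never altered, so the result
#' is always a prefix of the input.
#'
#' @param record a list with `id`, `seq` and `qual` (integer Phred scores or
#'   a Phred+33 string).
#' @param window window size in bases.
#' @param min_mean_q minimum mean Phred quality of the trailing window.
#' @param min_len minimum surviving read length; shorter reads are discarded.
#' @return The trimmed record, or `NULL` if discarded.
#' @examples
#' r <- list(id = "r", seq = strrep("A", 8), qual = c(rep(40L, 4), rep(2L, 4)))
#' quality_trim(r, window = 4, min_mean_q = 20, min_len = 1)$seq
#' @export
quality_trim <- function(record, window = 4L, min_mean_q = 20L,
                         min_len = 40L) {
  if (is.null(record$qual))
    stop("quality_trim requires qualities (FASTA reads bypass trimming)")
  qual <- record$qual
  if (is.numeric(qual)) qual <- int_to_phred(qual)
  res <- trim_reads_cpp(record$seq, qual, as.integer(window),
                        as.integer(min_mean_q), as.integer(min_len))
  if (!res$keep[1]) return(NULL)
  out <- record
  out$seq <- res$seq[1]
  out$qual <- if (is.numeric(record$qual)) phred_to_int(res$qual[1]) else res$qual[1]
  out
}

#' @rdname quality_trim
#' @param reads an [xeno_reads] object.
#' @return `trim_reads` returns the trimmed [xeno_reads] (discarded reads
#'   removed), with attributes `n_in` and `n_kept`.
#' @export
trim_reads <- function(reads, window = 4L, min_mean_q = 20L, min_len = 40L) {
  stopifnot(inherits(reads, "xeno_reads"))
  if (is.null(reads$qual))
    stop("trim_reads requires qualities (FASTA reads bypass trimming)")
  res <- trim_reads_cpp(reads$seq, reads$qual, as.integer(window),
                        as.integer(min_mean_q), as.integer(min_len))
  keep <- res$keep
  out <- xeno_reads(reads$id[keep], res$seq[keep], res$qual[keep])
  attr(out, "n_in") <- length(reads$id)
  attr(out, "n_kept") <- sum(keep)
  out
}

MANIFEST_COLS <- c("sample_id", "community_id", "treatment", "timepoint",
                   "role", "reads1")

#' Load and validate a sample manifest
#'
#' The manifest is a tab-separated table with header columns `sample_id`,
#' `community_id`, `treatment` (H or V), `timepoint` (non-negative integer,
#' weeks), `role` (ancestral or derived) and `reads1` (optionally `reads2`
#' for paired reads). Relative read paths are resolved against the manifest
#' directory. Validation enforces: unique sample ids, unique
#' (community, timepoint) pairs, every derived sample having a same-community
#' entry at a strictly earlier timepoint, and (optionally) existence of all
#' read files.
#'
#' @param path manifest TSV path.
#' @param check_files verify that referenced read files exist.
#' @return A `data.frame` of class `xeno_manifest`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  comment.char = "#", check.names = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(m))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  if (!"reads2" %in% names(m)) m$reads2 <- NA_character_
  m$reads2[!is.na(m$reads2) & !nzchar(m$reads2)] <- NA_character_
  base <- dirname(normalizePath(path))
  for (col in c("reads1", "reads2")) {
    rel <- !is.na(m[[col]]) & !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  validate_manifest(m, check_files = check_files)
}

#' @rdname load_manifest
#' @param m a manifest `data.frame`.
#' @export
validate_manifest <- function(m, check_files = TRUE) {
  m$treatment <- toupper(trimws(m$treatment))
  m$role <- tolower(trimws(m$role))
  bad <- setdiff(unique(m$treatment), c("H", "V"))
  if (length(bad))
    stop("invalid treatment '", bad[1], "': allowed values are H, V")
  bad <- setdiff(unique(m$role), c("ancestral", "derived"))
  if (length(bad))
    stop("invalid role '", bad[1],
         "': allowed values are ancestral, derived")
  m$timepoint <- as.integer(m$timepoint)
  if (any(is.na(m$timepoint)) || any(m$timepoint < 0))
    stop("timepoint must be a non-negative integer")
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id: ", m$sample_id[duplicated(m$sample_id)][1])
  key <- paste(m$community_id, m$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (community_id, timepoint): ", key[duplicated(key)][1])
  for (i in which(m$role == "derived")) {
    earlier <- m$community_id == m$community_id[i] &
      m$timepoint < m$timepoint[i]
    if (!any(earlier))
      stop("derived sample '", m$sample_id[i],
           "' has no same-community entry at an earlier timepoint")
  }
  if (check_files) {
    paths <- c(m$reads1, m$reads2)
    paths <- paths[!is.na(paths)]
    gone <- paths[!file.exists(paths)]
    if (length(gone)) stop("read file not found: ", gone[1])
  }
  class(m) <- c("xeno_manifest", "data.frame")
  m
}

#' @rdname load_manifest
#' @export
write_manifest <- function(m, path) {
  out <- as.data.frame(m)[, c(MANIFEST_COLS, "reads2")]
  out <- out[, c(MANIFEST_COLS[1:5], "reads1", "reads2")]
  if (all(is.na(out$reads2))) out$reads2 <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# reads for one manifest row: both mates pooled, each classified on its own
load_sample_reads <- function(m, sample_id) {
  row <- m[m$sample_id == sample_id, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown sample: ", sample_id)
  r <- read_fastq(row$reads1)
  if (!is.na(row$reads2)) {
    r2 <- read_fastq(row$reads2)
    r <- xeno_reads(c(paste0(r$id, "/1"), paste0(r2$id, "/2")),
                    c(r$seq, r2$seq), c(r$qual, r2$qual))
  }
  r
}
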