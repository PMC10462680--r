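#' De Bruijn graph construction from reads
#'
#' Builds the k-mer multiset of the reads in canonical form: a k-mer and its
#' reverse complement are the same edge, and multiplicities accumulate
#' across reads and strands. Nodes are the implied (k-1)-mer overlaps.
#' K-mers containing N are skipped.
#'
#' @param reads an [xeno_reads]/[xeno_seqs] object or a character vector of
#'   sequences.
#' @param k odd k-mer size in `[15, 31]` (single-k assembly; default 31).
#' @return An object of class `xeno_dbg`.
#' @export
build_graph <- function(reads, k = 31L) {
  seqs <- if (is.character(reads)) toupper(reads) else reads$seq
  structure(list(ptr = dbg_build_cpp(seqs, as.integer(k)),
                 k = as.integer(k)),
            class = "xeno_dbg")
}

#' @export
print.xeno_dbg <- function(x, ...) {
  info <- dbg_info_cpp(x$ptr)
  cat("xeno_dbg: k =", info$k, "|", info$n_kmers, "canonical k-mers |",
      "total multiplicity", info$total_multiplicity, "\n")
  invisible(x)
}

#' @rdname build_graph
#' @param graph an `xeno_dbg`.
#' @return `graph_info` returns a list (k, number of distinct canonical
#'   k-mers, total multiplicity); `graph_edges` a data.frame of canonical
#'   k-mers and multiplicities (small graphs only).
#' @export
graph_info <- function(graph) dbg_info_cpp(graph$ptr)

#' @rdname build_graph
#' @export
graph_edges <- function(graph) dbg_edges_cpp(graph$ptr)

#' Clean a de Bruijn graph
#'
#' Iteratively removes (i) edges with multiplicity below `min_edge_cov`,
#' (ii) edges weaker than `junction_rel` times their strongest sibling at a
#' branch point, and (iii) tips (maximal non-branching walks dangling at
#' exactly one end) shorter than `tip_len_factor * k` bases, until a
#' fixpoint is reached — cleaning an already-clean graph is the identity.
#' The junction-relative rule removes recurrent sequencing errors, which at
#' high coverage pass any small absolute cutoff, without harming genuinely
#' low-abundance replicons (their branch-free edges have no dominant
#' sibling).
#'
#' @param graph an `xeno_dbg`.
#' @param tip_len_factor tips shorter than this multiple of k are removed.
#' @param min_edge_cov minimum k-mer multiplicity to keep an edge.
#' @param junction_rel relative multiplicity floor at branch points
#'   (0 disables).
#' @return A cleaned `xeno_dbg` (the input is not modified).
#' @export
clean_graph <- function(graph, tip_len_factor = 2, min_edge_cov = 2L,
                        junction_rel = 0.125) {
  structure(list(ptr = dbg_clean_cpp(graph$ptr, tip_len_factor,
                                     as.integer(min_edge_cov),
                                     junction_rel),
                 k = graph$k),
            class = "xeno_dbg")
}

#' Extract unitigs from a (cleaned) de Bruijn graph
#'
#' Unitigs are maximal non-branching walks, reported in canonical
#' orientation (the lexicographically smaller of the sequence and its
#' reverse complement) and sorted by sequence, so identical read multisets
#' yield byte-identical output regardless of input order.
#'
#' @param graph an `xeno_dbg`, normally after [clean_graph()].
#' @param min_contig_len unitigs shorter than this many bases are dropped.
#' @param prefix id prefix for the emitted contigs.
#' @return An [xeno_seqs] of unitigs; mean k-mer multiplicity along each
#'   unitig is stored in the `coverage` attribute and echoed in `desc`.
#' @export
extract_unitigs <- function(graph, min_contig_len = 200L, prefix = "utg") {
  u <- dbg_unitigs_cpp(graph$ptr, as.integer(min_contig_len))
  n <- length(u$seq)
  ids <- if (n) sprintf("%s%06d", prefix, seq_len(n)) else character(0)
  out <- xeno_seqs(ids, u$seq,
                   desc = if (n) sprintf("cov=%.2f len=%d", u$coverage,
                                         nchar(u$seq)) else NULL)
  attr(out, "coverage") <- u$coverage
  out
}

#' One-call assembly: build, clean, extract
#'
#' @inheritParams build_graph
#' @inheritParams clean_graph
#' @inheritParams extract_unitigs
#' @return An [xeno_seqs] of unitigs (see [extract_unitigs()]).
#' @export
assemble_reads <- function(reads, k = 31L, min_edge_cov = 2L,
                           tip_len_factor = 2, min_contig_len = 200L,
                           prefix = "utg") {
  g <- build_graph(reads, k = k)
  g <- clean_graph(g, tip_len_factor = tip_len_factor,
                   min_edge_cov = min_edge_cov)
  extract_unitigs(g, min_contig_len = min_contig_len, prefix = prefix)
}
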