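#' Pipeline parameters
#'
#' One object carries every tunable of the find/link/trace pipeline.
#' Defaults: seed k-mers of 21 for read mapping (error tolerant) and 31 for
#' contig linking (near-identity regime); subtraction mapping at
#' `min_identity` 0.90 over `min_aligned_frac` 0.60 of the read, so
#' junction-spanning reads count as mapped and only reads fully inside novel
#' sequence survive subtraction; donor linking at a minimum HSP window of
#' 300 bp and 99% nucleotide identity; assembly with single k = 31,
#' edge coverage >= 2 and a 200 bp contig floor. `min_query_len` skips
#' contigs too short to carry a qualifying HSP (300); set it to 10000 to
#' reproduce a >10 kb analysis-stage filter. `ancestor_mode` selects the
#' reference for a derived sample: `"serial"` uses the same community's
#' sample at the largest earlier timepoint, `"first"` always uses the
#' earliest sample.
#'
#' @param ... overrides of any default listed above.
#' @return A named list of class `xeno_params`.
#' @export
xeno_params <- function(...) {
  p <- list(
    k_map = 21L, k_link = 31L, k_assembly = 31L,
    min_identity = 0.90, min_aligned_frac = 0.60, band = 16L,
    link_min_len = 300L, link_min_id = 0.99, min_query_len = 300L,
    trim_window = 4L, trim_min_q = 20L, trim_min_len = 40L,
    min_edge_cov = 2L, tip_len_factor = 2, min_contig_len = 200L,
    x_drop = 20L, ancestor_mode = "serial",
    workers = 1L, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$ancestor_mode %in% c("serial", "first"),
            p$link_min_id > 0, p$link_min_id <= 1,
            p$min_identity > 0, p$min_identity <= 1,
            p$min_aligned_frac > 0, p$min_aligned_frac <= 1)
  structure(p, class = c("xeno_params", "list"))
}

params_string <- function(p) {
  keep <- !vapply(p, is.null, logical(1))
  paste(names(p)[keep], unlist(lapply(p[keep], paste, collapse = ",")),
        sep = "=", collapse = " ")
}

# every emitted table starts with an audit comment line
write_tsv_commented <- function(df, path, subcommand, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# xenotrace v%s | %s | %s", xeno_version(),
                     subcommand, params_string(params)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identify unique contigs by subtractive assembly (find stage)
#'
#' Derived-sample reads are quality trimmed, mapped against the community's
#' ancestral contigs (assembled on the fly from ancestral reads when contigs
#' are not supplied), and the unmapped remainder is assembled into *unique
#' contigs*: stretches of sequence newly appeared in the community relative
#' to its own ancestry.
#'
#' @param derived an [xeno_reads] object (the evolved/query sample).
#' @param ancestral ancestral reads ([xeno_reads]) to assemble, or
#'   precomputed ancestral contigs ([xeno_seqs]).
#' @param params an [xeno_params] object.
#' @param sample_id,community,timepoint,ancestor_id provenance labels echoed
#'   into the result.
#' @return A list of class `xeno_unique_set`: `contigs` (an [xeno_seqs]),
#'   `stats` (reads in / mapped / unmapped, contig count, unique bp) and the
#'   `ancestral_contigs` used as bait. `stats$n_mapped + stats$n_unmapped ==
#'   stats$n_reads` (the post-trimming read count).
#' @export
xeno_find <- function(derived, ancestral, params = xeno_params(),
                      sample_id = "sample", community = NA,
                      timepoint = NA, ancestor_id = NA) {
  stopifnot(inherits(derived, "xeno_reads"))
  if (length(derived$id) == 0) stop("derived sample has no reads")
  n_raw <- length(derived$id)
  if (!is.null(derived$qual)) {
    derived <- trim_reads(derived, window = params$trim_window,
                          min_mean_q = params$trim_min_q,
                          min_len = params$trim_min_len)
  }
  if (inherits(ancestral, "xeno_seqs")) {
    bait <- ancestral
  } else {
    stopifnot(inherits(ancestral, "xeno_reads"))
    bait <- assemble_reads(ancestral, k = params$k_assembly,
                           min_edge_cov = params$min_edge_cov,
                           tip_len_factor = params$tip_len_factor,
                           min_contig_len = params$min_contig_len,
                           prefix = paste0(sample_id, "_anc"))
  }
  n_reads <- length(derived$id)
  if (length(bait$id) > 0 && n_reads > 0) {
    idx <- build_kmer_index(bait, k = params$k_map)
    mp <- map_reads(derived, idx, min_identity = params$min_identity,
                    min_aligned_frac = params$min_aligned_frac,
                    band = params$band)
    unmapped <- !mp$mapped
  } else {
    unmapped <- rep(TRUE, n_reads)
  }
  n_unmapped <- sum(unmapped)
  contigs <- if (n_unmapped > 0) {
    assemble_reads(subset_reads(derived, unmapped), k = params$k_assembly,
                   min_edge_cov = params$min_edge_cov,
                   tip_len_factor = params$tip_len_factor,
                   min_contig_len = params$min_contig_len,
                   prefix = paste0(sample_id, "_uc"))
  } else {
    xeno_seqs(character(0), character(0))
  }
  structure(list(
    sample_id = sample_id, community = community, timepoint = timepoint,
    ancestor_id = ancestor_id, contigs = contigs,
    ancestral_contigs = bait,
    stats = list(n_reads_raw = n_raw, n_reads = n_reads,
                 n_mapped = n_reads - n_unmapped, n_unmapped = n_unmapped,
                 n_contigs = length(contigs$id),
                 unique_bp = sum(nchar(contigs$seq)))),
    class = "xeno_unique_set")
}

#' @export
print.xeno_unique_set <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "xeno_unique_set %s: reads in=%d mapped=%d unmapped=%d | %d unique contigs, %d bp\n",
    x$sample_id, s$n_reads, s$n_mapped, s$n_unmapped, s$n_contigs,
    s$unique_bp))
  invisible(x)
}

#' Link unique contigs to allopatric donor communities (link stage)
#'
#' A unique contig is *xenotypic* when it has at least one HSP window of
#' length >= `min_len` with identity >= `min_id` against the ancestral
#' contigs of at least one allopatric (different-lineage) community. One
#' link record is emitted per (contig, donor) pair — a contig matching
#' several donors keeps all of them. Contigs shorter than `min_query_len`
#' are skipped.
#'
#' @param unique_contigs an `xeno_unique_set` or [xeno_seqs] of the acceptor
#'   community's unique contigs.
#' @param allopatric named list of [xeno_seqs] (or `xeno_kmer_index`), one
#'   per allopatric community's ancestral contigs; must not contain the
#'   acceptor.
#' @param acceptor acceptor community id.
#' @param min_len minimum qualifying HSP window length (bp).
#' @param min_id minimum qualifying nucleotide identity.
#' @param min_query_len contigs shorter than this are not tested.
#' @param params an [xeno_params] (supplies k and band defaults).
#' @return A list of class `xeno_link_result`: `links` (data.frame
#'   `query_id`, `acceptor`, `donor`, `hsp_len`, `hsp_identity`, `n_hsps`)
#'   and `xenotypic` (an [xeno_seqs] of linked contigs).
#' @export
xeno_link <- function(unique_contigs, allopatric, acceptor = NA,
                      min_len = NULL, min_id = NULL, min_query_len = NULL,
                      params = xeno_params()) {
  if (inherits(unique_contigs, "xeno_unique_set")) {
    if (is.na(acceptor)) acceptor <- unique_contigs$community
    unique_contigs <- unique_contigs$contigs
  }
  stopifnot(inherits(unique_contigs, "xeno_seqs"))
  if (is.null(min_len)) min_len <- params$link_min_len
  if (is.null(min_id)) min_id <- params$link_min_id
  if (is.null(min_query_len)) min_query_len <- params$min_query_len
  if (!is.na(acceptor) && acceptor %in% names(allopatric))
    stop("allopatric sets must exclude the acceptor community '",
         acceptor, "'")
  empty <- data.frame(query_id = character(0), acceptor = character(0),
                      donor = character(0), hsp_len = numeric(0),
                      hsp_identity = numeric(0), n_hsps = integer(0),
                      stringsAsFactors = FALSE)
  keep <- nchar(unique_contigs$seq) >= min_query_len
  q <- xeno_seqs(unique_contigs$id[keep], unique_contigs$seq[keep])
  links <- empty
  if (length(q$id) > 0) {
    for (donor in sort(names(allopatric))) {
      subj <- allopatric[[donor]]
      if (inherits(subj, "xeno_seqs") && length(subj$id) == 0) next
      h <- find_hsps(q, subj, seed_k = params$k_link, band = params$band,
                     win_id = min_id)
      ok <- h[h$win_len >= min_len &
              h$win_identity + 1e-12 >= min_id, , drop = FALSE]
      if (nrow(ok) == 0) next
      for (qq in unique(ok$qid)) {
        hq <- ok[ok$qid == qq, , drop = FALSE]
        best <- hq[order(-hq$score, -hq$win_len)[1], , drop = FALSE]
        links <- rbind(links, data.frame(
          query_id = qq, acceptor = as.character(acceptor), donor = donor,
          hsp_len = best$win_len, hsp_identity = best$win_identity,
          n_hsps = nrow(hq), stringsAsFactors = FALSE))
      }
    }
  }
  links <- links[order(links$query_id, links$donor), , drop = FALSE]
  rownames(links) <- NULL
  xeno_ids <- unique(links$query_id)
  sel <- unique_contigs$id %in% xeno_ids
  structure(list(links = links,
                 xenotypic = xeno_seqs(unique_contigs$id[sel],
                                       unique_contigs$seq[sel],
                                       unique_contigs$desc[sel])),
            class = "xeno_link_result")
}

#' @export
print.xeno_link_result <- function(x, ...) {
  cat("xeno_link_result:", nrow(x$links), "links |",
      length(x$xenotypic$id), "xenotypic contigs\n")
  invisible(x)
}

#' Trace contig depth and breadth across all samples (trace stage)
#'
#' Maps the reads of every sample against the given contigs with the same
#' thresholds as subtraction mapping, and reports per (contig, sample):
#' depth = total aligned bases / contig length, and breadth = fraction of
#' contig positions covered by at least one read. `breadth == 0` iff
#' `depth == 0`.
#'
#' @param contigs an [xeno_seqs] (normally xenotypic contigs).
#' @param reads named list of [xeno_reads], one per sample, or `NULL` to
#'   load each sample from `manifest`.
#' @param manifest an `xeno_manifest` supplying sample metadata (and read
#'   paths when `reads` is `NULL`).
#' @param params an [xeno_params].
#' @return A data.frame with columns `contig_id`, `sample_id`,
#'   `community_id`, `timepoint`, `treatment`, `depth`, `breadth`.
#' @export
xeno_trace <- function(contigs, reads = NULL, manifest = NULL,
                       params = xeno_params()) {
  stopifnot(inherits(contigs, "xeno_seqs"))
  if (is.null(reads) && is.null(manifest))
    stop("supply reads or a manifest")
  sample_ids <- if (!is.null(reads)) names(reads)
                else sort(manifest$sample_id)
  meta <- function(sid, col) {
    if (is.null(manifest) || !sid %in% manifest$sample_id) return(NA)
    manifest[[col]][manifest$sample_id == sid]
  }
  out <- data.frame(contig_id = character(0), sample_id = character(0),
                    community_id = character(0), timepoint = integer(0),
                    treatment = character(0), depth = numeric(0),
                    breadth = numeric(0), stringsAsFactors = FALSE)
  if (length(contigs$id) == 0) return(out)
  idx <- build_kmer_index(contigs, k = params$k_map)
  clen <- setNames(nchar(contigs$seq), contigs$id)
  for (sid in sample_ids) {
    r <- if (!is.null(reads)) reads[[sid]] else load_sample_reads(manifest, sid)
    mp <- map_reads(r, idx, min_identity = params$min_identity,
                    min_aligned_frac = params$min_aligned_frac,
                    band = params$band)
    mp <- mp[mp$mapped, , drop = FALSE]
    for (cid in contigs$id) {
      mc <- mp[mp$contig == cid, , drop = FALSE]
      if (nrow(mc) == 0) {
        depth <- 0; breadth <- 0
      } else {
        depth <- sum(mc$s_end - mc$s_start) / clen[[cid]]
        cov <- interval_depth_cpp(as.integer(clen[[cid]]),
                                  mc$s_start, mc$s_end)
        breadth <- mean(cov >= 1)
      }
      out <- rbind(out, data.frame(
        contig_id = cid, sample_id = sid,
        community_id = as.character(meta(sid, "community_id")),
        timepoint = meta(sid, "timepoint"),
        treatment = as.character(meta(sid, "treatment")),
        depth = depth, breadth = breadth, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Donor-acceptor transfer network
#'
#' Builds a directed network over communities: an edge donor -> acceptor
#' weighted by the number of distinct xenotypic contigs of the acceptor
#' linked to that donor. Isolated communities keep their nodes. A link with
#' `donor == acceptor` violates the link contract and is an error.
#'
#' @param links a link data.frame (see [xeno_link()]), optionally with a
#'   `timepoint` column.
#' @param communities node set; defaults to communities present in `links`.
#' @param timepoint if given, restrict to links of that acceptor timepoint.
#' @return A list of class `xeno_network`: `graph` (an igraph directed
#'   graph) and `edges` (data.frame `donor`, `acceptor`, `weight`).
#' @export
build_transfer_network <- function(links, communities = NULL,
                                   timepoint = NULL) {
  if (!is.null(timepoint) && "timepoint" %in% names(links))
    links <- links[links$timepoint == timepoint, , drop = FALSE]
  if (nrow(links) && any(links$donor == links$acceptor))
    stop("self-loop in link records: donor == acceptor")
  if (is.null(communities))
    communities <- sort(unique(c(links$donor, links$acceptor)))
  edges <- if (nrow(links)) {
    agg <- stats::aggregate(query_id ~ donor + acceptor, data = links,
                            FUN = function(x) length(unique(x)))
    names(agg)[3] <- "weight"
    agg[order(agg$donor, agg$acceptor), , drop = FALSE]
  } else {
    data.frame(donor = character(0), acceptor = character(0),
               weight = integer(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = communities))
  structure(list(graph = g, edges = edges, communities = communities),
            class = "xeno_network")
}

#' @export
print.xeno_network <- function(x, ...) {
  cat("xeno_network:", length(x$communities), "communities,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Group means and standard errors of per-community counts
#'
#' @param df a data.frame of per-community values.
#' @param value name of the value column.
#' @param by grouping column names (e.g. treatment and timepoint).
#' @return A data.frame with one row per group: `n`, `mean` and `se`
#'   (sample sd / sqrt(n); `NA` when n == 1, never reported as 0).
#' @export
summarize_counts <- function(df, value = "count",
                             by = c("treatment", "timepoint")) {
  stopifnot(value %in% names(df), all(by %in% names(df)))
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  groups <- split(df, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- g[[value]]
    cbind(g[1, by, drop = FALSE],
          data.frame(n = length(v), mean = mean(v),
                     se = if (length(v) > 1) sd(v) / sqrt(length(v))
                          else NA_real_))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

# reference ancestor for a derived manifest row under the chaining rule
ancestor_for <- function(m, i, mode = "serial") {
  cand <- which(m$community_id == m$community_id[i] &
                m$timepoint < m$timepoint[i])
  if (!length(cand)) return(NA_integer_)
  if (mode == "first") cand[which.min(m$timepoint[cand])]
  else cand[which.max(m$timepoint[cand])]
}

# FASTA reader tolerating a record-less file (empty stage outputs)
read_fasta_or_empty <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(xeno_seqs(character(0), character(0)))
  read_fasta(path)
}

empty_links <- function() {
  data.frame(query_id = character(0), acceptor = character(0),
             donor = character(0), hsp_len = numeric(0),
             hsp_identity = numeric(0), n_hsps = integer(0),
             timepoint = integer(0), stringsAsFactors = FALSE)
}

#' Pipeline stages over an output directory
#'
#' The three stages share a fixed directory layout under `outdir` and are
#' composable: running them in sequence is identical to [xeno_run()].
#' `run_find_stage` assembles each referenced ancestor sample into bait
#' contigs (`anc/<sample>.fasta`), subtracts every derived sample against
#' its ancestor and writes `unique/<sample>.fasta` plus `find_stats.tsv`.
#' `run_link_stage` links unique contigs to the allopatric bait assemblies
#' and writes `xenotypic/<sample>.fasta`, `links.tsv`, `network.tsv` and
#' `counts.tsv`. `run_trace_stage` maps every sample's reads over all
#' xenotypic contigs and writes `trace.tsv`. Inputs are never modified.
#'
#' Sample work units are independent: with `workers > 1` they run in
#' parallel via forked processes and outputs are byte-identical to a
#' serial run.
#'
#' @param manifest an `xeno_manifest` or manifest TSV path.
#' @param outdir pipeline output directory (created if absent).
#' @param params an [xeno_params].
#' @param workers number of parallel workers.
#' @return Each stage returns its main table or object list, invisibly.
#' @export
run_find_stage <- function(manifest, outdir, params = xeno_params(),
                           workers = params$workers) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  m <- manifest
  dir.create(file.path(outdir, "anc"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "unique"), showWarnings = FALSE)
  writeLines(c(sprintf("# xenotrace v%s", xeno_version()),
               params_string(params)),
             file.path(outdir, "run_config.txt"))
  derived_idx <- which(m$role == "derived")
  derived_idx <- derived_idx[order(m$sample_id[derived_idx])]
  anc_rows <- unique(vapply(derived_idx, function(i)
    ancestor_for(m, i, params$ancestor_mode), integer(1)))
  anc_rows <- sort(anc_rows[!is.na(anc_rows)])
  apply_fun <- function(X, FUN) {
    if (workers > 1) parallel::mclapply(X, FUN, mc.cores = workers)
    else lapply(X, FUN)
  }
  bait_list <- apply_fun(anc_rows, function(i) {
    assemble_reads(load_sample_reads(m, m$sample_id[i]),
                   k = params$k_assembly,
                   min_edge_cov = params$min_edge_cov,
                   tip_len_factor = params$tip_len_factor,
                   min_contig_len = params$min_contig_len,
                   prefix = paste0(m$sample_id[i], "_anc"))
  })
  names(bait_list) <- m$sample_id[anc_rows]
  for (sid in names(bait_list))
    write_fasta(bait_list[[sid]],
                file.path(outdir, "anc", paste0(sid, ".fasta")))
  finds <- apply_fun(derived_idx, function(i) {
    anc_i <- ancestor_for(m, i, params$ancestor_mode)
    xeno_find(load_sample_reads(m, m$sample_id[i]),
              bait_list[[m$sample_id[anc_i]]], params = params,
              sample_id = m$sample_id[i], community = m$community_id[i],
              timepoint = m$timepoint[i], ancestor_id = m$sample_id[anc_i])
  })
  names(finds) <- m$sample_id[derived_idx]
  stats <- NULL
  for (f in finds) {
    message(sprintf(
      "[find] %s: reads=%d mapped=%d unmapped=%d contigs=%d unique_bp=%d",
      f$sample_id, f$stats$n_reads, f$stats$n_mapped, f$stats$n_unmapped,
      f$stats$n_contigs, f$stats$unique_bp))
    write_fasta(f$contigs, file.path(outdir, "unique",
                                     paste0(f$sample_id, ".fasta")))
    stats <- rbind(stats, data.frame(
      sample_id = f$sample_id, ancestor_id = f$ancestor_id,
      n_reads = f$stats$n_reads, n_mapped = f$stats$n_mapped,
      n_unmapped = f$stats$n_unmapped, n_contigs = f$stats$n_contigs,
      unique_bp = f$stats$unique_bp, stringsAsFactors = FALSE))
  }
  write_tsv_commented(stats, file.path(outdir, "find_stats.tsv"),
                      "find", params)
  invisible(finds)
}

#' @rdname run_find_stage
#' @export
run_link_stage <- function(manifest, outdir, params = xeno_params()) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  m <- manifest
  if (!dir.exists(file.path(outdir, "unique")))
    stop("link stage requires the find stage outputs under ", outdir)
  dir.create(file.path(outdir, "xenotypic"), showWarnings = FALSE)
  derived_idx <- which(m$role == "derived")
  derived_idx <- derived_idx[order(m$sample_id[derived_idx])]
  bait_ids <- sub("\\.fasta$", "",
                  list.files(file.path(outdir, "anc"), "\\.fasta$"))
  all_links <- NULL
  cnt <- NULL
  for (i in derived_idx) {
    sid <- m$sample_id[i]
    uniq <- read_fasta_or_empty(file.path(outdir, "unique",
                                          paste0(sid, ".fasta")))
    allo <- list()
    for (cid in sort(setdiff(unique(m$community_id), m$community_id[i]))) {
      rows <- which(m$community_id == cid & m$timepoint < m$timepoint[i] &
                    m$sample_id %in% bait_ids)
      if (!length(rows)) next
      r <- if (params$ancestor_mode == "first")
             rows[which.min(m$timepoint[rows])]
           else rows[which.max(m$timepoint[rows])]
      allo[[cid]] <- read_fasta_or_empty(
        file.path(outdir, "anc", paste0(m$sample_id[r], ".fasta")))
    }
    lr <- xeno_link(uniq, allo, acceptor = m$community_id[i],
                    params = params)
    message(sprintf("[link] %s: %d unique -> %d xenotypic (%d links)",
                    sid, length(uniq$id), length(lr$xenotypic$id),
                    nrow(lr$links)))
    if (nrow(lr$links)) {
      lr$links$timepoint <- m$timepoint[i]
      all_links <- rbind(all_links, lr$links)
    }
    write_fasta(lr$xenotypic, file.path(outdir, "xenotypic",
                                        paste0(sid, ".fasta")))
    cnt <- rbind(cnt, data.frame(
      sample_id = sid, community_id = m$community_id[i],
      treatment = m$treatment[i], timepoint = m$timepoint[i],
      n_unique = length(uniq$id),
      n_xenotypic = length(lr$xenotypic$id), stringsAsFactors = FALSE))
  }
  if (is.null(all_links)) all_links <- empty_links()
  write_tsv_commented(all_links, file.path(outdir, "links.tsv"),
                      "link", params)
  net <- build_transfer_network(all_links,
                                communities = sort(unique(m$community_id)))
  write_tsv_commented(net$edges, file.path(outdir, "network.tsv"),
                      "network", params)
  igraph::write_graph(net$graph, file.path(outdir, "network.graphml"),
                      format = "graphml")
  write_tsv_commented(cnt, file.path(outdir, "counts.tsv"), "counts", params)
  invisible(list(links = all_links, network = net, counts = cnt))
}

#' @rdname run_find_stage
#' @export
run_trace_stage <- function(manifest, outdir, params = xeno_params()) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  m <- manifest
  xdir <- file.path(outdir, "xenotypic")
  if (!dir.exists(xdir))
    stop("trace stage requires the link stage outputs under ", outdir)
  xeno_all <- xeno_seqs(character(0), character(0))
  for (f in sort(list.files(xdir, "\\.fasta$", full.names = TRUE))) {
    x <- read_fasta_or_empty(f)
    if (length(x$id))
      xeno_all <- xeno_seqs(c(xeno_all$id, x$id), c(xeno_all$seq, x$seq))
  }
  tr <- xeno_trace(xeno_all, manifest = m, params = params)
  write_tsv_commented(tr, file.path(outdir, "trace.tsv"), "trace", params)
  invisible(tr)
}

#' Run the full pipeline over a manifest (find, link, trace)
#'
#' Equivalent to [run_find_stage()], [run_link_stage()] and
#' [run_trace_stage()] in sequence over the same output directory; see
#' those stages for the directory layout. All tables carry a comment line
#' with the tool version and the full parameter set.
#'
#' @inheritParams run_find_stage
#' @return Invisibly, a list with `unique` (per-sample `xeno_unique_set`),
#'   `links`, `network`, `counts` and `trace`.
#' @export
xeno_run <- function(manifest, outdir, params = xeno_params(),
                     workers = params$workers) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  finds <- run_find_stage(manifest, outdir, params, workers = workers)
  lk <- run_link_stage(manifest, outdir, params)
  tr <- run_trace_stage(manifest, outdir, params)
  invisible(list(unique = finds, links = lk$links, network = lk$network,
                 counts = lk$counts, trace = tr))
}
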