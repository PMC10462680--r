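#' Generate a random mock genome
#'
#' I.i.d. bases with P(G) + P(C) = `gc`, reproducible from `seed`.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction, strictly inside (0, 1).
#' @param seed integer seed.
#' @param id genome identifier.
#' @return A list with `id`, `seq`, `length`, `gc`, `seed`.
#' @export
make_genome <- function(length, gc = 0.5, seed = 1L, id = "genome") {
  stopifnot(length >= 1000, gc > 0, gc < 1)
  seq <- with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
  list(id = id, seq = seq, length = length, gc = gc, seed = seed)
}

#' Assemble genomes into a mock community with an abundance model
#'
#' `even` gives every genome abundance 1/G; `skewed` a geometric series
#' a_i proportional to r^(i-1) (heavily dominated by the first genomes),
#' normalised to sum to 1.
#'
#' @param genomes a list of genomes from [make_genome()] or an [xeno_seqs].
#' @param model `"even"` or `"skewed"`.
#' @param r geometric ratio of the skewed model.
#' @param abundance explicit relative abundances overriding the model.
#' @param id community identifier.
#' @return A list of class `mock_community`: `id`, `replicons` (an
#'   [xeno_seqs]), `abundance` (named, sums to 1) and `model`.
#' @export
make_community <- function(genomes, model = c("even", "skewed"), r = 0.3,
                           abundance = NULL, id = "community") {
  model <- match.arg(model)
  if (!inherits(genomes, "xeno_seqs")) {
    genomes <- xeno_seqs(vapply(genomes, `[[`, "", "id"),
                         vapply(genomes, `[[`, "", "seq"))
  }
  G <- length(genomes$id)
  stopifnot(G >= 2 || !is.null(abundance))
  if (is.null(abundance)) {
    abundance <- switch(model, even = rep(1 / G, G), skewed = r^(0:(G - 1)))
  }
  stopifnot(length(abundance) == G, all(abundance > 0))
  abundance <- abundance / sum(abundance)
  structure(list(id = id, replicons = genomes,
                 abundance = setNames(abundance, genomes$id),
                 model = model),
            class = "mock_community")
}

#' Describe a horizontal transfer event
#'
#' @param element_id element identifier.
#' @param element_seq element sequence (length at least the linking minimum,
#'   300 bp).
#' @param donor,recipient community ids (ground truth).
#' @param recipient_genome id of the recipient replicon hosting the element.
#' @param mode `"integrative"` (spliced into the host genome) or
#'   `"episomal"` (separate replicon tied to the host's abundance).
#' @param position 0-based insertion offset (integrative only).
#' @param copy_abundance episomal copy number relative to the host.
#' @return A list of class `hgt_event`.
#' @export
make_hgt_event <- function(element_id, element_seq, donor, recipient,
                           recipient_genome, mode = c("episomal",
                                                      "integrative"),
                           position = NA, copy_abundance = 1) {
  mode <- match.arg(mode)
  element_seq <- normalise_seq(element_seq)
  stopifnot(nchar(element_seq) >= 300)
  structure(list(element_id = element_id, element_seq = element_seq,
                 donor = donor, recipient = recipient,
                 recipient_genome = recipient_genome, mode = mode,
                 position = position, copy_abundance = copy_abundance),
            class = "hgt_event")
}

#' Apply a transfer event to a mock community
#'
#' Integrative: the element is spliced into the host replicon at the stated
#' position (flanks preserved). Episomal: the element is appended as an
#' extra replicon whose abundance is the host's abundance times
#' `copy_abundance`.
#'
#' @param community a `mock_community`.
#' @param event an `hgt_event` whose `recipient_genome` is present.
#' @return The modified `mock_community`.
#' @export
apply_hgt <- function(community, event) {
  stopifnot(inherits(community, "mock_community"),
            inherits(event, "hgt_event"))
  gi <- match(event$recipient_genome, community$replicons$id)
  if (is.na(gi)) stop("recipient genome '", event$recipient_genome,
                      "' not in community ", community$id)
  if (event$mode == "integrative") {
    host <- community$replicons$seq[gi]
    pos <- event$position
    if (is.na(pos) || pos < 0 || pos > nchar(host))
      stop("integrative position ", pos, " out of range [0, ",
           nchar(host), "]")
    community$replicons$seq[gi] <- paste0(
      substr(host, 1, pos), event$element_seq,
      substr(host, pos + 1, nchar(host)))
  } else {
    community$replicons <- xeno_seqs(
      c(community$replicons$id, event$element_id),
      c(community$replicons$seq, event$element_seq))
    community$abundance <- c(
      community$abundance,
      setNames(community$abundance[[event$recipient_genome]] *
                 event$copy_abundance, event$element_id))
    community$abundance <- community$abundance / sum(community$abundance)
  }
  community
}

#' Simulate Illumina-like paired-end reads from a mock community
#'
#' Fragments are drawn from replicons proportional to abundance x length,
#' positions uniform, mates read inward from opposite fragment ends at a
#' Gaussian (truncated) insert size. Substitution errors are i.i.d. at
#' `error_rate` per base; qualities are constant at the Phred equivalent of
#' the error rate (Q40 when error-free). No indels. Read ids carry the
#' source replicon, 0-based fragment start and strand, enabling exact
#' audits of subtraction behaviour. Deterministic given `seed`.
#'
#' @param community a `mock_community`.
#' @param n_pairs number of read pairs.
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd fragment-size distribution (>= read_len).
#' @param error_rate per-base substitution probability in `[0, 0.25)`.
#' @param seed integer seed.
#' @return A list with [xeno_reads] `r1` and `r2` (mates in pair order).
#' @export
simulate_reads <- function(community, n_pairs = 40000L, read_len = 150L,
                           insert_mean = 400, insert_sd = 50,
                           error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(community, "mock_community"),
            error_rate >= 0, error_rate < 0.25, insert_mean >= read_len)
  reps <- community$replicons
  L <- nchar(reps$seq)
  w <- community$abundance[reps$id] * L
  w <- w / sum(w)
  with_seed(seed, {
    frag <- pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))
    ri <- sample.int(length(L), n_pairs, replace = TRUE, prob = w)
    bad <- which(L[ri] < frag)
    for (i in bad) {
      elig <- which(L >= frag[i])
      if (!length(elig)) stop("no replicon as long as fragment of ",
                              frag[i], " bp")
      ri[i] <- if (length(elig) == 1) elig
               else sample(elig, 1, prob = w[elig] / sum(w[elig]))
    }
    start <- floor(runif(n_pairs) * (L[ri] - frag + 1))
    minus <- runif(n_pairs) < 0.5
    gs <- reps$seq[ri]
    left <- substring(gs, start + 1, start + read_len)
    right <- substring(gs, start + frag - read_len + 1, start + frag)
    r1 <- ifelse(minus, revcomp(right), left)
    r2 <- ifelse(minus, revcomp(left), revcomp(right))
    if (error_rate > 0) {
      r1 <- mutate_seqs(r1, error_rate)
      r2 <- mutate_seqs(r2, error_rate)
    }
    q <- if (error_rate > 0) min(40L, as.integer(round(-10 * log10(error_rate))))
         else 40L
    qual <- strrep(intToUtf8(q + 33L), read_len)
    ids <- sprintf("p%07d:%s:%d:%s", seq_len(n_pairs), reps$id[ri], start,
                   ifelse(minus, "-", "+"))
    list(r1 = xeno_reads(ids, r1, rep(qual, n_pairs)),
         r2 = xeno_reads(ids, r2, rep(qual, n_pairs)))
  })
}

# i.i.d. substitutions at `rate` per base (RNG state of the caller)
mutate_seqs <- function(seqs, rate) {
  nerr <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(s), nerr[i])
    for (p in pos) {
      alt <- bases[bases != s[p]]
      s[p] <- alt[sample.int(3, 1)]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Benchmark scenario presets
#'
#' `default_scenario()` is the standard benchmark: 4 communities (2
#' horizontal, 2 vertical), 6 random 100 kb genomes each (disjoint pools),
#' one 20 kb episomal element transferred into each horizontal community
#' from a distinct donor, 40,000 read pairs of 2 x 150 bp per sample
#' (about 20x community coverage) at 0.1% substitution error.
#' `hard_scenario()` repeats it with ten-fold elevated error (1%) and
#' highly skewed abundances, adding a third transfer whose recipient host
#' is far below 5% abundance (an expected, reported recovery failure).
#' `confounder_scenario()` has no transfer at all: its only perturbation is
#' a rare ancestral taxon (0.05x expected coverage) amplifying to 30x in
#' the derived sample — the demographic false-positive source.
#'
#' @param n_pairs read pairs per sample.
#' @param error_rate per-base substitution error rate.
#' @param genome_len genome length (bp).
#' @param n_genomes genomes per community.
#' @return A scenario list consumed by [make_benchmark()].
#' @export
default_scenario <- function(n_pairs = 40000L, error_rate = 0.001,
                             genome_len = 100000L, n_genomes = 6L) {
  list(
    communities = data.frame(
      id = c("H1", "H2", "V1", "V2"),
      treatment = c("H", "H", "V", "V"), stringsAsFactors = FALSE),
    n_genomes = n_genomes, genome_len = genome_len, gc = 0.5,
    abundance_model = "even", skew_r = 0.3,
    events = data.frame(
      donor = c("H2", "H1"), recipient = c("H1", "H2"),
      mode = c("episomal", "episomal"),
      element_len = c(20000L, 20000L),
      donor_genome = c(1L, 1L), recipient_genome = c(1L, 2L),
      copy_abundance = c(1, 1), stringsAsFactors = FALSE),
    confounder = NULL,
    n_pairs = n_pairs, read_len = 150L,
    insert_mean = 400, insert_sd = 50, error_rate = error_rate,
    compress = FALSE)
}

#' @rdname default_scenario
#' @export
hard_scenario <- function(n_pairs = 40000L) {
  sc <- default_scenario(n_pairs = n_pairs, error_rate = 0.01)
  sc$abundance_model <- "skewed"
  sc$events <- data.frame(
    donor = c("H2", "H1", "H2"), recipient = c("H1", "H2", "H1"),
    mode = c("episomal", "episomal", "episomal"),
    element_len = c(20000L, 20000L, 20000L),
    donor_genome = c(1L, 1L, 2L), recipient_genome = c(1L, 2L, 5L),
    copy_abundance = c(1, 1, 1), stringsAsFactors = FALSE)
  sc
}

#' @rdname default_scenario
#' @export
confounder_scenario <- function(n_pairs = 10000L, error_rate = 0.001) {
  list(
    communities = data.frame(
      id = c("H1", "V1"), treatment = c("H", "V"), stringsAsFactors = FALSE),
    n_genomes = 3L, genome_len = 50000L, gc = 0.5,
    abundance_model = "even", skew_r = 0.3,
    events = data.frame(
      donor = character(0), recipient = character(0), mode = character(0),
      element_len = integer(0), donor_genome = integer(0),
      recipient_genome = integer(0), copy_abundance = numeric(0),
      stringsAsFactors = FALSE),
    confounder = list(communities = "H1", length = 20000L,
                      anc_depth = 0.05, der_depth = 30),
    n_pairs = n_pairs, read_len = 150L,
    insert_mean = 400, insert_sd = 50, error_rate = error_rate,
    compress = FALSE)
}

# relative weight giving a replicon of length `len` an expected depth
# `depth` next to a baseline of total weighted length S at total read bases T
conf_weight <- function(depth, len, total_bases, S) {
  if (total_bases <= depth * len)
    stop("not enough reads to reach the requested confounder depth")
  depth * S / (total_bases - depth * len)
}

#' Generate a full benchmark: samples, manifest and ground truth
#'
#' Builds every community from its own random genome pool, emits an
#' ancestral sample (timepoint 0) per community, then a derived sample
#' (timepoint 1) in which horizontal communities carry the scenario's
#' transfer events and vertical communities are unchanged. Each transferred
#' element is a random slice of a donor genome, so the donor's ancestral
#' assembly contains it — the property donor linking relies on. The optional
#' confounder adds a rare taxon at sub-assembly ancestral coverage that
#' amplifies in the derived sample without any transfer.
#'
#' @param scenario a scenario list (see [default_scenario()]).
#' @param outdir directory for FASTQ files, `manifest.tsv`, `truth.tsv` and
#'   `elements.fasta`.
#' @param seed global seed; every sample and genome derives its own stream.
#' @return A list with `manifest` (validated `xeno_manifest`), `truth`
#'   (data.frame of events), `elements` ([xeno_seqs]) and `outdir`.
#' @export
make_benchmark <- function(scenario = default_scenario(), outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  comms <- scenario$communities
  total_bases <- scenario$n_pairs * 2 * scenario$read_len

  # ancestral communities from disjoint genome pools
  anc <- list()
  for (ci in seq_len(nrow(comms))) {
    cid <- comms$id[ci]
    genomes <- lapply(seq_len(scenario$n_genomes), function(gi)
      make_genome(scenario$genome_len, gc = scenario$gc,
                  seed = derive_seed(seed, paste0(cid, "_g", gi)),
                  id = paste0(cid, "_g", gi)))
    com <- make_community(genomes, model = scenario$abundance_model,
                          r = scenario$skew_r, id = cid)
    if (!is.null(scenario$confounder) &&
        cid %in% scenario$confounder$communities) {
      rare <- make_genome(scenario$confounder$length, gc = scenario$gc,
                          seed = derive_seed(seed, paste0(cid, "_rare")),
                          id = paste0(cid, "_rare"))
      S <- sum(com$abundance * nchar(com$replicons$seq))
      w <- conf_weight(scenario$confounder$anc_depth, rare$length,
                       total_bases, S)
      com$replicons <- xeno_seqs(c(com$replicons$id, rare$id),
                                 c(com$replicons$seq, rare$seq))
      com$abundance <- c(com$abundance, setNames(w, rare$id))
      com$abundance <- com$abundance / sum(com$abundance)
    }
    anc[[cid]] <- com
  }

  # elements and events; element = slice of a donor genome
  ev <- scenario$events
  truth <- NULL
  elements <- xeno_seqs(character(0), character(0))
  events <- list()
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      donor <- ev$donor[i]
      dg <- anc[[donor]]$replicons
      src_id <- paste0(donor, "_g", ev$donor_genome[i])
      src <- dg$seq[match(src_id, dg$id)]
      elen <- ev$element_len[i]
      pos <- with_seed(derive_seed(seed, paste0("mge", i)),
                       sample.int(nchar(src) - elen + 1, 1)) - 1
      eseq <- substr(src, pos + 1, pos + elen)
      eid <- sprintf("mge%02d", i)
      recipient <- ev$recipient[i]
      if (src_id %in% anc[[recipient]]$replicons$id)
        warning("event ", eid, ": recipient pool shares the element's ",
                "source genome; donor attribution is confounded")
      host <- paste0(recipient, "_g", ev$recipient_genome[i])
      ins <- if (ev$mode[i] == "integrative") {
        hseq <- anc[[recipient]]$replicons$seq[
          match(host, anc[[recipient]]$replicons$id)]
        with_seed(derive_seed(seed, paste0("ins", i)),
                  sample.int(nchar(hseq) + 1, 1)) - 1
      } else NA
      events[[i]] <- make_hgt_event(eid, eseq, donor, recipient, host,
                                    mode = ev$mode[i], position = ins,
                                    copy_abundance = ev$copy_abundance[i])
      elements <- xeno_seqs(c(elements$id, eid), c(elements$seq, eseq))
      truth <- rbind(truth, data.frame(
        event_id = eid, donor = donor, recipient = recipient,
        recipient_genome = host, mode = ev$mode[i], element_id = eid,
        element_len = elen, source_genome = src_id, source_pos = pos,
        insert_pos = ins, copy_abundance = ev$copy_abundance[i],
        host_abundance = unname(anc[[recipient]]$abundance[host]),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(truth))
    truth <- data.frame(event_id = character(0), donor = character(0),
                        recipient = character(0),
                        recipient_genome = character(0), mode = character(0),
                        element_id = character(0), element_len = integer(0),
                        source_genome = character(0), source_pos = integer(0),
                        insert_pos = integer(0), copy_abundance = numeric(0),
                        host_abundance = numeric(0), stringsAsFactors = FALSE)

  # derived communities: events applied; confounder amplified
  der <- anc
  for (e in events) der[[e$recipient]] <- apply_hgt(der[[e$recipient]], e)
  if (!is.null(scenario$confounder)) {
    for (cid in scenario$confounder$communities) {
      com <- der[[cid]]
      rare_id <- paste0(cid, "_rare")
      keep <- com$replicons$id != rare_id
      S <- sum(com$abundance[com$replicons$id[keep]] *
                 nchar(com$replicons$seq[keep]))
      w <- conf_weight(scenario$confounder$der_depth,
                       nchar(com$replicons$seq[!keep]), total_bases, S)
      com$abundance[rare_id] <- w * sum(com$abundance[com$replicons$id[keep]])
      com$abundance <- com$abundance / sum(com$abundance)
      der[[cid]] <- com
    }
  }

  # emit samples and manifest
  ext <- if (isTRUE(scenario$compress)) ".fastq.gz" else ".fastq"
  rows <- NULL
  for (ci in seq_len(nrow(comms))) {
    cid <- comms$id[ci]
    for (tp in c(0L, 1L)) {
      sid <- sprintf("%s_t%d", cid, tp)
      com <- if (tp == 0) anc[[cid]] else der[[cid]]
      rd <- simulate_reads(com, n_pairs = scenario$n_pairs,
                           read_len = scenario$read_len,
                           insert_mean = scenario$insert_mean,
                           insert_sd = scenario$insert_sd,
                           error_rate = scenario$error_rate,
                           seed = derive_seed(seed, sid))
      f1 <- file.path(outdir, paste0(sid, "_R1", ext))
      f2 <- file.path(outdir, paste0(sid, "_R2", ext))
      write_fastq(rd$r1, f1)
      write_fastq(rd$r2, f2)
      rows <- rbind(rows, data.frame(
        sample_id = sid, community_id = cid, treatment = comms$treatment[ci],
        timepoint = tp, role = if (tp == 0) "ancestral" else "derived",
        reads1 = basename(f1), reads2 = basename(f2),
        stringsAsFactors = FALSE))
    }
  }
  mpath <- file.path(outdir, "manifest.tsv")
  write.table(rows, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(elements$id))
    write_fasta(elements, file.path(outdir, "elements.fasta"))
  list(manifest = load_manifest(mpath), truth = truth, elements = elements,
       outdir = outdir)
}

#' Score pipeline output against simulator ground truth
#'
#' An event is *recovered* when the xenotypic contigs of its recipient
#' community align to the element (HSP windows at >= `min_id` identity)
#' covering at least `cov_threshold` of its length, and at least one link
#' record of those contigs names the true donor. Precision is the fraction
#' of linked (xenotypic) contig bases matching any true element; recall the
#' fraction of events recovered. With no events and no calls both are `NA`.
#'
#' @param truth the `truth` data.frame from [make_benchmark()].
#' @param links a link data.frame (see [xeno_link()]).
#' @param xenotypic named list (by community id) of [xeno_seqs] of
#'   xenotypic contigs.
#' @param elements an [xeno_seqs] of true element sequences.
#' @param min_id identity threshold for matching contigs to elements.
#' @param cov_threshold fraction of the element that must be covered.
#' @param params an [xeno_params] (k and band for the comparison).
#' @return A list of class `benchmark_score`: `events` (per-event
#'   data.frame with `recovered`, `element_coverage`, `donor_linked`),
#'   `precision`, `recall`.
#' @export
score_benchmark <- function(truth, links, xenotypic, elements,
                            min_id = 0.99, cov_threshold = 0.5,
                            params = xeno_params()) {
  res <- NULL
  for (i in seq_len(nrow(truth))) {
    ev <- truth[i, ]
    contigs <- xenotypic[[ev$recipient]]
    coverage <- 0; donor_ok <- FALSE; hit_ids <- character(0)
    if (!is.null(contigs) && length(contigs$id) > 0) {
      esub <- xeno_seqs(ev$element_id,
                        elements$seq[match(ev$element_id, elements$id)])
      h <- find_hsps(contigs, esub, seed_k = params$k_link,
                     band = params$band, win_id = min_id)
      h <- h[h$win_identity + 1e-12 >= min_id & h$win_len > 0, , drop = FALSE]
      if (nrow(h)) {
        cov <- interval_depth_cpp(as.integer(ev$element_len),
                                  h$win_s_start, h$win_s_end)
        coverage <- mean(cov >= 1)
        hit_ids <- unique(h$qid)
        donor_ok <- any(links$query_id %in% hit_ids &
                        links$donor == ev$donor &
                        links$acceptor == ev$recipient)
      }
    }
    res <- rbind(res, data.frame(
      event_id = ev$event_id, donor = ev$donor, recipient = ev$recipient,
      host_abundance = ev$host_abundance, element_coverage = coverage,
      donor_linked = donor_ok,
      recovered = coverage >= cov_threshold && donor_ok,
      stringsAsFactors = FALSE))
  }
  if (is.null(res))
    res <- data.frame(event_id = character(0), donor = character(0),
                      recipient = character(0), host_abundance = numeric(0),
                      element_coverage = numeric(0), donor_linked = logical(0),
                      recovered = logical(0), stringsAsFactors = FALSE)
  recall <- if (nrow(res)) mean(res$recovered) else NA_real_

  # precision: linked-contig bases matching any true element / linked bases
  linked_bases <- 0; matched_bases <- 0
  eidx <- if (length(elements$id)) build_kmer_index(elements, params$k_link)
          else NULL
  for (cid in sort(names(xenotypic))) {
    contigs <- xenotypic[[cid]]
    if (is.null(contigs) || !length(contigs$id)) next
    linked <- unique(links$query_id[links$acceptor == cid])
    sel <- contigs$id %in% linked
    if (!any(sel)) next
    sub <- xeno_seqs(contigs$id[sel], contigs$seq[sel])
    linked_bases <- linked_bases + sum(nchar(sub$seq))
    if (is.null(eidx)) next
    h <- find_hsps(sub, eidx, band = params$band, win_id = min_id)
    h <- h[h$win_identity + 1e-12 >= min_id & h$win_len > 0, , drop = FALSE]
    for (qq in unique(h$qid)) {
      hq <- h[h$qid == qq, , drop = FALSE]
      qlen <- nchar(sub$seq[match(qq, sub$id)])
      cov <- interval_depth_cpp(as.integer(qlen), hq$win_q_start,
                                hq$win_q_end)
      matched_bases <- matched_bases + sum(cov >= 1)
    }
  }
  precision <- if (linked_bases > 0) matched_bases / linked_bases
               else NA_real_
  structure(list(events = res, precision = precision, recall = recall),
            class = "benchmark_score")
}

#' @export
print.benchmark_score <- function(x, ...) {
  cat(sprintf("benchmark_score: recall=%s precision=%s (%d events)\n",
              format(x$recall, digits = 4),
              format(x$precision, digits = 4), nrow(x$events)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Read and write scenario configuration files
#'
#' Flat key=value schema with one `event.N` line per transfer event
#' (`donor:recipient:mode:element_len:donor_genome:recipient_genome:copy`)
#' and optional `confounder` line
#' (`communities(comma-sep):length:anc_depth:der_depth`).
#'
#' @param path config file path.
#' @param scenario a scenario list.
#' @return `read_scenario` returns a scenario list.
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  sc <- default_scenario()
  sc$events <- sc$events[0, ]
  getv <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  comm <- strsplit(getv("communities", "H1:H,H2:H,V1:V,V2:V"), ",")[[1]]
  cparts <- strsplit(comm, ":", fixed = TRUE)
  sc$communities <- data.frame(
    id = vapply(cparts, `[`, "", 1),
    treatment = vapply(cparts, `[`, "", 2), stringsAsFactors = FALSE)
  for (k in c("n_genomes", "genome_len", "n_pairs", "read_len"))
    sc[[k]] <- as.integer(getv(k, sc[[k]]))
  for (k in c("gc", "skew_r", "insert_mean", "insert_sd", "error_rate"))
    sc[[k]] <- as.numeric(getv(k, sc[[k]]))
  sc$abundance_model <- getv("abundance_model", sc$abundance_model)
  sc$compress <- as.logical(getv("compress", "FALSE"))
  evk <- keys[grepl("^event\\.", keys)]
  if (length(evk)) {
    parts <- strsplit(vals[match(sort(evk), keys)], ":", fixed = TRUE)
    sc$events <- data.frame(
      donor = vapply(parts, `[`, "", 1),
      recipient = vapply(parts, `[`, "", 2),
      mode = vapply(parts, `[`, "", 3),
      element_len = as.integer(vapply(parts, `[`, "", 4)),
      donor_genome = as.integer(vapply(parts, `[`, "", 5)),
      recipient_genome = as.integer(vapply(parts, `[`, "", 6)),
      copy_abundance = as.numeric(vapply(parts, `[`, "", 7)),
      stringsAsFactors = FALSE)
  }
  if ("confounder" %in% keys) {
    p <- strsplit(vals[match("confounder", keys)], ":", fixed = TRUE)[[1]]
    sc$confounder <- list(communities = strsplit(p[1], ",")[[1]],
                          length = as.integer(p[2]),
                          anc_depth = as.numeric(p[3]),
                          der_depth = as.numeric(p[4]))
  }
  sc
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  lines <- c(
    paste0("communities=", paste(scenario$communities$id,
                                 scenario$communities$treatment,
                                 sep = ":", collapse = ",")),
    paste0("n_genomes=", scenario$n_genomes),
    paste0("genome_len=", scenario$genome_len),
    paste0("gc=", scenario$gc),
    paste0("abundance_model=", scenario$abundance_model),
    paste0("skew_r=", scenario$skew_r),
    paste0("n_pairs=", scenario$n_pairs),
    paste0("read_len=", scenario$read_len),
    paste0("insert_mean=", scenario$insert_mean),
    paste0("insert_sd=", scenario$insert_sd),
    paste0("error_rate=", scenario$error_rate),
    paste0("compress=", isTRUE(scenario$compress)))
  ev <- scenario$events
  if (nrow(ev))
    lines <- c(lines, sprintf("event.%d=%s:%s:%s:%d:%d:%d:%g",
                              seq_len(nrow(ev)), ev$donor, ev$recipient,
                              ev$mode, ev$element_len, ev$donor_genome,
                              ev$recipient_genome, ev$copy_abundance))
  if (!is.null(scenario$confounder))
    lines <- c(lines, sprintf("confounder=%s:%d:%g:%g",
                              paste(scenario$confounder$communities,
                                    collapse = ","),
                              scenario$confounder$length,
                              scenario$confounder$anc_depth,
                              scenario$confounder$der_depth))
  writeLines(lines, path)
  invisible(path)
}
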