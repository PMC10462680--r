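test_that("mock genomes are reproducible with the requested composition", {
  g1 <- make_genome(10000, 0.5, seed = 1)
  g2 <- make_genome(10000, 0.5, seed = 1)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, make_genome(10000, 0.5, seed = 2)$seq))

  # GC fraction within 3 binomial sd of nominal
  g <- make_genome(1e5, 0.5, seed = 3)
  gc <- mean(strsplit(g$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))

  expect_error(make_genome(10000, 1.0), "gc")
  expect_error(make_genome(500, 0.5), "length")
})

test_that("community abundance models are normalised as specified", {
  gs <- lapply(1:6, function(i) make_genome(1000, 0.5, i, paste0("g", i)))
  even <- make_community(gs, "even")
  expect_equal(unname(even$abundance), rep(1 / 6, 6))

  skew <- make_community(gs[1:3], "skewed", r = 0.5)
  expect_equal(unname(skew$abundance), c(4, 2, 1) / 7)

  for (r in c(0.1, 0.3, 0.7)) {
    com <- make_community(gs, "skewed", r = r)
    expect_equal(sum(com$abundance), 1)
    expect_true(all(com$abundance > 0))
  }
})

test_that("transfer events splice or attach elements correctly", {
  gs <- lapply(1:2, function(i) make_genome(5000, 0.5, i, paste0("g", i)))
  com <- make_community(gs, "even")
  el <- make_genome(1000, 0.5, 9, "el")$seq

  ev <- make_hgt_event("el", el, "B", "A", "g1", mode = "integrative",
                       position = 2000)
  mod <- apply_hgt(com, ev)
  host <- mod$replicons$seq[1]
  expect_equal(nchar(host), 6000)
  expect_equal(substr(host, 1, 2000), substr(gs[[1]]$seq, 1, 2000))
  expect_equal(substr(host, 2001, 3000), el)
  expect_equal(substr(host, 3001, 6000), substr(gs[[1]]$seq, 2001, 5000))

  ep <- make_hgt_event("el", el, "B", "A", "g2", mode = "episomal",
                       copy_abundance = 0.5)
  mod2 <- apply_hgt(com, ep)
  expect_equal(length(mod2$replicons$id), 3)
  expect_equal(unname(mod2$abundance[["el"]] / mod2$abundance[["g2"]]), 0.5)
  expect_equal(sum(mod2$abundance), 1)

  expect_error(apply_hgt(com, make_hgt_event("el", el, "B", "A", "g1",
                                             mode = "integrative",
                                             position = 99999)),
               "out of range")
  expect_error(apply_hgt(com, make_hgt_event("el", el, "B", "A", "nope")),
               "not in community")
})

test_that("error-free reads are exact substrings; ids audit their origin", {
  gs <- lapply(1:2, function(i) make_genome(5000, 0.5, i, paste0("g", i)))
  com <- make_community(gs, "even")
  rd <- simulate_reads(com, n_pairs = 300, read_len = 80, insert_mean = 200,
                       insert_sd = 20, error_rate = 0, seed = 5)
  expect_equal(length(rd$r1$id), 300)
  expect_identical(rd$r1$id, rd$r2$id)
  src <- setNames(vapply(gs, `[[`, "", "seq"), vapply(gs, `[[`, "", "id"))
  for (i in seq(1, 300, by = 7)) {
    parts <- strsplit(rd$r1$id[i], ":", fixed = TRUE)[[1]]
    gseq <- src[[parts[2]]]
    start <- as.integer(parts[3])
    found <- c(substring(gseq, start + 1, start + 200 + 60),
               revcomp(substring(gseq, start + 1, start + 200 + 60)))
    expect_true(grepl(rd$r1$seq[i], found[1], fixed = TRUE) ||
                grepl(rd$r1$seq[i], found[2], fixed = TRUE))
  }
  # determinism
  rd2 <- simulate_reads(com, n_pairs = 300, read_len = 80, insert_mean = 200,
                        insert_sd = 20, error_rate = 0, seed = 5)
  expect_identical(rd, rd2)
})

test_that("observed error rates match the nominal rate within 3 sd", {
  gs <- lapply(1:2, function(i) make_genome(20000, 0.5, i, paste0("g", i)))
  com <- make_community(gs, "even")
  src <- setNames(vapply(gs, `[[`, "", "seq"), vapply(gs, `[[`, "", "id"))
  # plus-strand R1 reads start exactly at the recorded fragment start, so
  # the mismatch count against the source is exact
  for (rate in c(0.001, 0.01)) {
    rd <- simulate_reads(com, n_pairs = 1000, read_len = 100,
                         insert_mean = 250, insert_sd = 20,
                         error_rate = rate, seed = 11)
    plus <- grepl(":\\+$", rd$r1$id)
    mism <- 0; total <- 0
    for (i in which(plus)) {
      parts <- strsplit(rd$r1$id[i], ":", fixed = TRUE)[[1]]
      start <- as.integer(parts[3])
      truth <- substring(src[[parts[2]]], start + 1, start + 100)
      mism <- mism + sum(strsplit(rd$r1$seq[i], "")[[1]] !=
                         strsplit(truth, "")[[1]])
      total <- total + 100
    }
    obs <- mism / total
    expect_lt(abs(obs - rate), 3 * sqrt(rate * (1 - rate) / total))
  }
})

test_that("read origins follow abundance x length weighting", {
  gs <- lapply(1:2, function(i) make_genome(10000, 0.5, i, paste0("g", i)))
  com <- make_community(gs, abundance = c(0.9, 0.1))
  rd <- simulate_reads(com, n_pairs = 2000, read_len = 100,
                       insert_mean = 300, insert_sd = 30,
                       error_rate = 0, seed = 6)
  n1 <- sum(grepl(":g1:", rd$r1$id))
  expect_lt(abs(n1 - 0.9 * 2000), 3 * sqrt(2000 * 0.9 * 0.1))

  # expected depth: n_pairs * 2 * read_len * w_j / len_j, w_j ~ a_j l_j
  w <- com$abundance * 10000
  w <- w / sum(w)
  exp_depth <- 2000 * 2 * 100 * w / 10000
  obs_bases <- c(g1 = 0, g2 = 0)
  for (g in c("g1", "g2"))
    obs_bases[g] <- 200 * sum(grepl(paste0(":", g, ":"), rd$r1$id))
  expect_lt(abs(obs_bases[["g1"]] / 10000 - exp_depth[1]), 3)
})

test_that("benchmark construction writes a valid, truthful experiment", {
  sc <- default_scenario(n_pairs = 500L, genome_len = 5000L, n_genomes = 2L)
  sc$events$element_len <- c(1500L, 1500L)
  td <- file.path(tempdir(), "bm_construct")
  bm <- make_benchmark(sc, td, seed = 9)
  expect_equal(nrow(bm$manifest), 8)
  expect_equal(nrow(bm$truth), 2)
  expect_setequal(bm$truth$recipient, c("H1", "H2"))
  expect_setequal(bm$truth$donor, c("H2", "H1"))
  expect_equal(nchar(bm$elements$seq), c(1500, 1500))
  # the element is a genuine slice of the donor's ancestral pool: the
  # donor community FASTQ-generating genome contains it
  g <- make_genome(5000, 0.5, xenotrace:::derive_seed(9, "H2_g1"),
                   id = "H2_g1")
  expect_true(grepl(bm$elements$seq[1], g$seq, fixed = TRUE))

  # zero-event scenario: empty truth
  sc0 <- sc; sc0$events <- sc0$events[0, ]
  bm0 <- make_benchmark(sc0, file.path(tempdir(), "bm_zero"), seed = 9)
  expect_equal(nrow(bm0$truth), 0)
  expect_equal(length(bm0$elements$id), 0)
})

test_that("scoring implements the recovery, precision and NA conventions", {
  set.seed(45)
  el <- rseq(2000)
  truth <- data.frame(event_id = c("e1", "e2"), donor = c("B", "B"),
                      recipient = c("A", "A"),
                      recipient_genome = c("A_g1", "A_g1"),
                      mode = "episomal", element_id = c("e1", "e2"),
                      element_len = c(2000L, 2000L),
                      host_abundance = 0.5, stringsAsFactors = FALSE)
  elements <- xeno_seqs(c("e1", "e2"), c(el, rseq(2000)))
  xen <- list(A = xeno_seqs("c1", el))   # covers e1 fully, e2 not at all
  links <- data.frame(query_id = "c1", acceptor = "A", donor = "B",
                      hsp_len = 2000, hsp_identity = 1, n_hsps = 1)
  s <- score_benchmark(truth, links, xen, elements)
  expect_equal(s$recall, 0.5)
  expect_equal(s$precision, 1)
  expect_true(s$events$recovered[1])
  expect_false(s$events$recovered[2])

  # naming the wrong donor blocks recovery
  wrong <- links; wrong$donor <- "C"
  expect_equal(score_benchmark(truth, wrong, xen, elements)$recall, 0)

  # empty conventions
  s0 <- score_benchmark(truth[0, ], links[0, ], list(),
                        xeno_seqs(character(0), character(0)))
  expect_true(is.na(s0$recall))
  expect_true(is.na(s0$precision))
})

test_that("scenario files round-trip through the key=value schema", {
  sc <- hard_scenario()
  sc$confounder <- list(communities = c("H1", "V1"), length = 15000L,
                        anc_depth = 0.05, der_depth = 30)
  f <- tempfile(fileext = ".cfg")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  for (k in c("n_genomes", "genome_len", "gc", "abundance_model", "skew_r",
              "n_pairs", "read_len", "error_rate"))
    expect_equal(sc2[[k]], sc[[k]], ignore_attr = TRUE)
  expect_equal(sc2$communities, sc$communities)
  expect_equal(sc2$events, sc$events)
  expect_equal(sc2$confounder, sc$confounder)
})
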