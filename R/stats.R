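#' Crawford-Howell single-case t-test
#'
#' Compares one case value against a small control sample:
#' \deqn{t = \frac{x^* - \bar{x}}{s \sqrt{(n+1)/n}}, \quad df = n - 1}
#' with the sample standard deviation (n-1 denominator). Unlike a naive
#' z-test, the inflation factor sqrt((n+1)/n) keeps the type-I error
#' calibrated at small control sample sizes.
#'
#' Degenerate controls (sd = 0): when the case equals the control mean the
#' test returns t = 0, p = 1; otherwise p is reported at the machine floor
#' with `degenerate = TRUE`.
#'
#' @param case the single case value.
#' @param controls numeric vector of control values (length >= 2).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A list with `t`, `df`, `p` and `degenerate`.
#' @examples
#' crawford_howell(10, c(1, 2, 3))   # t ~ 6.928, p ~ 0.0202
#' @export
crawford_howell <- function(case, controls,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(controls)
  if (n < 2) stop("crawford_howell requires at least 2 controls")
  m <- mean(controls)
  s <- sd(controls)
  df <- n - 1
  if (s == 0) {
    if (case == m)
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(case - m) * Inf, df = df,
                p = .Machine$double.xmin, degenerate = TRUE))
  }
  t <- (case - m) / (s * sqrt((n + 1) / n))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(t), df),
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df))
  list(t = t, df = df, p = p, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' Validates the inputs and delegates to [stats::p.adjust()]: each p is
#' mapped to `min(1, m * p)` with m = number of tests.
#'
#' @param p numeric vector of p values in (0, 1].
#' @return The adjusted p values.
#' @export
bonferroni <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p values must lie in (0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Sample length-matched control contig sets
#'
#' Formalises "contigs with similar lengths" as log-spaced length-bin
#' matching: the reference lengths are binned into `n_bins` log-spaced
#' bins, and each control set draws, per bin and without replacement, the
#' same number of pool contigs. The sets are mutually disjoint and exclude
#' `exclude_ids` (the xenotypic contigs). A bin with too few pool members
#' borrows from the nearest non-empty bin, flagging the set.
#'
#' @param pool data.frame with columns `id` and `length`: the
#'   community-metagenome contig pool to sample from.
#' @param reference_lengths lengths of the xenotypic (case) contigs.
#' @param n_sets number of control sets.
#' @param n_bins number of log-spaced length bins.
#' @param seed integer seed.
#' @param exclude_ids pool ids never sampled (case contigs).
#' @return A list of control sets, each a list with `ids` and `borrowed`
#'   (TRUE when a bin had to borrow from a neighbour).
#' @export
sample_length_matched_controls <- function(pool, reference_lengths,
                                           n_sets = 4L, n_bins = 10L,
                                           seed = 1L,
                                           exclude_ids = character(0)) {
  stopifnot(all(c("id", "length") %in% names(pool)),
            length(reference_lengths) > 0)
  pool <- pool[!pool$id %in% exclude_ids, , drop = FALSE]
  if (nrow(pool) < length(reference_lengths))
    stop("pool smaller than one full control set (",
         nrow(pool), " < ", length(reference_lengths), ")")
  rng <- range(reference_lengths)
  breaks <- if (rng[1] == rng[2]) c(rng[1] - 0.5, rng[1] + 0.5)
            else exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  ref_bin <- findInterval(reference_lengths, breaks,
                          rightmost.closed = TRUE, all.inside = TRUE)
  need <- tabulate(ref_bin, nbins = length(breaks) - 1)
  pool_bin <- findInterval(pool$length, breaks,
                           rightmost.closed = TRUE, all.inside = TRUE)
  with_seed(seed, {
    avail <- split(pool$id[order(pool$id)],
                   factor(pool_bin[order(pool$id)],
                          levels = seq_along(need)))
    # pre-shuffle each bin once; sets then consume disjoint slices
    avail <- lapply(avail, function(x) if (length(x)) sample(x) else x)
    sets <- vector("list", n_sets)
    for (s in seq_len(n_sets)) {
      ids <- character(0)
      borrowed <- FALSE
      for (b in seq_along(need)) {
        take <- need[b]
        if (take == 0) next
        got <- head(avail[[b]], take)
        avail[[b]] <- avail[[b]][-seq_along(got)]
        short <- take - length(got)
        if (short > 0) {
          borrowed <- TRUE
          others <- order(abs(seq_along(need) - b))
          for (nb in setdiff(others, b)) {
            if (short == 0) break
            extra <- head(avail[[nb]], short)
            if (!length(extra)) next
            avail[[nb]] <- avail[[nb]][-seq_along(extra)]
            got <- c(got, extra)
            short <- short - length(extra)
          }
          if (short > 0)
            stop("pool exhausted while sampling control set ", s)
        }
        ids <- c(ids, got)
      }
      sets[[s]] <- list(ids = sort(ids), borrowed = borrowed)
    }
    sets
  })
}

#' MGE-category enrichment in xenotypic contigs
#'
#' For every annotation category, counts annotations on the xenotypic
#' contig set (the case) and on each length-matched control set, then runs
#' the Crawford-Howell test and a Bonferroni adjustment across categories.
#' Categories are free strings; the conventional preset is phage, plasmid,
#' IS, ICE, integron.
#'
#' @param annotations data.frame with columns `contig_id` and `category`
#'   (one row per annotation; a contig may carry several).
#' @param xenotypic_ids ids of the xenotypic contigs.
#' @param control_sets list of control sets from
#'   [sample_length_matched_controls()] (>= 2), or a list of id vectors.
#' @param alternative passed to [crawford_howell()].
#' @return A data.frame per category: `category`, `case`, `ctrl_mean`,
#'   `t`, `df`, `p`, `p_bonferroni`, `stars` (`*` < 0.05, `**` < 0.01,
#'   `***` < 0.001 on the unadjusted p).
#' @export
enrichment_test <- function(annotations, xenotypic_ids, control_sets,
                            alternative = "two.sided") {
  stopifnot(all(c("contig_id", "category") %in% names(annotations)),
            length(control_sets) >= 2)
  ctrl_ids <- lapply(control_sets, function(s)
    if (is.list(s)) s$ids else s)
  categories <- sort(unique(annotations$category))
  count_in <- function(ids, cat)
    sum(annotations$category == cat & annotations$contig_id %in% ids)
  out <- NULL
  for (cat in categories) {
    case <- count_in(xenotypic_ids, cat)
    ctrl <- vapply(ctrl_ids, count_in, numeric(1), cat = cat)
    if (case == 0 && all(ctrl == 0)) {
      warning("category '", cat, "' absent from case and all control sets; ",
              "skipped")
      next
    }
    ch <- crawford_howell(case, ctrl, alternative = alternative)
    out <- rbind(out, data.frame(
      category = cat, case = case, ctrl_mean = mean(ctrl),
      t = ch$t, df = ch$df, p = ch$p, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(category = character(0), case = numeric(0),
                      ctrl_mean = numeric(0), t = numeric(0), df = numeric(0),
                      p = numeric(0), p_bonferroni = numeric(0),
                      stars = character(0), stringsAsFactors = FALSE))
  out$p_bonferroni <- bonferroni(out$p)
  out$stars <- ifelse(out$p < 0.001, "***",
               ifelse(out$p < 0.01, "**",
               ifelse(out$p < 0.05, "*", "")))
  rownames(out) <- NULL
  out
}
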