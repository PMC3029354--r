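#' Local-alignment scoring scheme
#'
#' Classic DNA local-alignment defaults: match +5, mismatch -4, affine gaps
#' with open -16 and extend -4, where a gap of length k scores
#' `gap_open + (k - 1) * gap_extend` (the opening penalty includes the first
#' gapped position).
#'
#' @param match,mismatch Substitution scores (`match > 0 > mismatch`).
#' @param gap_open,gap_extend Gap scores (`gap_open <= gap_extend <= 0`).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 5L, mismatch = -4L,
                           gap_open = -16L, gap_extend = -4L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= gap_extend, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' @noRd
check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop(what, " must be a single non-empty string")
  if (grepl("[^ACGTN]", x))
    stop(what, " contains symbols outside ACGTN")
  x
}

#' Smith-Waterman local alignment score
#'
#' Maximal local alignment score of two nucleotide sequences under affine
#' gap scoring. `N` scores as a mismatch against every symbol, including
#' itself. A score of 0 means the empty alignment is optimal.
#'
#' @param a,b Uppercase nucleotide strings over ACGTN.
#' @param s A [scoring_scheme()].
#' @return Integer score, >= 0.
#' @examples
#' smith_waterman("ACGTAC", "ACGTAC")  # 30 with the +5 match default
#' @export
smith_waterman <- function(a, b, s = scoring_scheme()) {
  check_dna(a, "a"); check_dna(b, "b")
  .sw_score_cpp(a, b, s$match, s$mismatch, s$gap_open, s$gap_extend)
}

#' Shuffle a nucleotide sequence
#'
#' Mononucleotide shuffling draws a uniform random permutation of the
#' residues; window shuffling permutes residues independently within
#' consecutive windows of `k` positions, preserving local composition.
#'
#' @param x Nucleotide string.
#' @param method `"mono"` (default) or `"window"`.
#' @param k Window width for `method = "window"`.
#' @return Shuffled string. Uses the current RNG state.
#' @export
shuffle_seq <- function(x, method = c("mono", "window"), k = 20L) {
  method <- match.arg(method)
  ch <- strsplit(x, "")[[1L]]
  n <- length(ch)
  if (method == "mono") {
    paste(ch[sample.int(n)], collapse = "")
  } else {
    stopifnot(k >= 2L)
    idx <- seq_len(n)
    for (s in seq(1L, n, by = k)) {
      e <- min(s + k - 1L, n)
      idx[s:e] <- s - 1L + sample.int(e - s + 1L)
    }
    paste(ch[idx], collapse = "")
  }
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits a Gumbel (type-I extreme value, maximum) distribution to a numeric
#' sample by the standard ML fixed-point iteration for the scale, then the
#' closed-form location. Local alignment scores of unrelated sequences are
#' approximately Gumbel, which is what makes the shuffle-based E-value
#' meaningful.
#'
#' @param x Numeric sample (shuffled alignment scores).
#' @param maxit,tol Iteration controls.
#' @return `list(mu, beta)` or `NULL` when the fit fails (degenerate or
#'   non-convergent sample).
#' @export
fit_gumbel <- function(x, maxit = 200L, tol = 1e-9) {
  x <- as.numeric(x)
  if (length(x) < 5L || sd(x) == 0) return(NULL)
  b <- sd(x) * sqrt(6) / pi
  mx <- mean(x)
  for (i in seq_len(maxit)) {
    w <- exp(-(x - mx) / b)            # shifted for numerical stability
    bn <- mx - sum(x * w) / sum(w)
    if (!is.finite(bn) || bn <= 0) return(NULL)
    if (abs(bn - b) < tol * max(b, 1)) { b <- bn; break }
    b <- bn
  }
  if (!is.finite(b) || b <= 0) return(NULL)
  mu <- mx - b * log(mean(exp(-(x - mx) / b)))
  list(mu = mu, beta = b)
}

#' Gumbel upper-tail probability
#' @noRd
gumbel_tail <- function(s, fit) {
  z <- (s - fit$mu) / fit$beta
  -expm1(-exp(-z))
}

#' Shuffle-based significance of a local alignment
#'
#' Scores `a` against `b`, then against `n` random shuffles of the shorter
#' of the two (shuffling the shorter sequence reduces the variance of the
#' null scores). The empirical p-value is `(r + 1) / (n + 1)` where `r`
#' shuffled scores reach the observed score. The E-value is the expected
#' number of the `n` shuffled comparisons attaining at least the observed
#' score under a maximum-likelihood Gumbel fit to the shuffled scores; when
#' the fit fails (e.g. a flat score distribution) the empirical p-value is
#' reported as the E-value.
#'
#' @param a,b Nucleotide strings (uppercase ACGTN).
#' @param s A [scoring_scheme()].
#' @param n Number of shuffles.
#' @param seed Integer seed; the function seeds the RNG itself so results
#'   are reproducible per call.
#' @param shuffle `"mono"` or `"window"`; `window_k` the window width.
#' @return A `similarity_result` list: `score`, `evalue`, `empirical_p`,
#'   `n_shuffles`, `seed`, `gumbel` (fit or NULL).
#' @export
shuffle_significance <- function(a, b, s = scoring_scheme(), n = 200L,
                                 seed = 1L, shuffle = c("mono", "window"),
                                 window_k = 20L) {
  shuffle <- match.arg(shuffle)
  check_dna(a, "a"); check_dna(b, "b")
  stopifnot(n >= 1L)
  if (nchar(b) > nchar(a)) { tmp <- a; a <- b; b <- tmp }  # b is shorter
  obs <- .sw_score_cpp(a, b, s$match, s$mismatch, s$gap_open, s$gap_extend)
  set.seed(seed)
  if (shuffle == "mono") {
    sc <- .sw_shuffle_scores_cpp(a, b, n, s$match, s$mismatch, s$gap_open,
                                 s$gap_extend)
  } else {
    shuf <- vapply(seq_len(n),
                   function(i) shuffle_seq(b, method = shuffle, k = window_k),
                   character(1))
    sc <- .sw_score_many_cpp(a, shuf, s$match, s$mismatch, s$gap_open,
                             s$gap_extend)
  }
  r <- sum(sc >= obs)
  emp <- (r + 1) / (n + 1)
  fit <- fit_gumbel(sc)
  ev <- if (is.null(fit)) emp else n * gumbel_tail(obs, fit)
  structure(list(score = obs, evalue = ev, empirical_p = emp,
                 n_shuffles = as.integer(n), seed = as.integer(seed),
                 gumbel = fit),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> score %d, E = %.3g, empirical p = %.3g (%d shuffles)\n",
              x$score, x$evalue, x$empirical_p, x$n_shuffles))
  invisible(x)
}

#' @noRd
site_lookup <- function(matrices) {
  cells <- do.call(rbind, lapply(matrices, `[[`, "cells"))
  excluded <- unlist(lapply(matrices, `[[`, "excluded"), use.names = FALSE)
  list(site_of = setNames(cells$site_id, cells$intron_id),
       excluded = excluded)
}

#' Find sequence-similar intron pairs
#'
#' Tests every unordered pair of introns by Smith-Waterman local alignment
#' with the shuffle significance test, retains pairs with E-value below the
#' cutoff, and classifies each retained pair by insertion site: same site in
#' the same gene family, different sites in the same family, or different
#' families. Per-pair RNG seeds are derived deterministically from the
#' master seed and the sorted pair of intron ids, so the result is
#' reproducible and independent of pair enumeration order. Pairs involving
#' an intron that could not be projected onto the alignment (stop-codon
#' anchor) are excluded from the output with a warning. No multiple-testing
#' correction is applied across pairs.
#'
#' @param introns Intron table with `intron_id`, `gene_id`, `species`,
#'   `family`, `seq`.
#' @param matrices Named list of `site_matrix` objects covering the introns.
#' @param t A [thresholds()] (uses `n_shuffles` and `evalue_cutoff`).
#' @param s A [scoring_scheme()].
#' @param seed Master seed.
#' @param shuffle,window_k Shuffle options, see [shuffle_significance()].
#' @param verbose Emit progress messages.
#' @return Data frame with one row per retained pair: `intron_a`,
#'   `intron_b`, `species_a`, `species_b`, `family_a`, `family_b`, `site_a`,
#'   `site_b`, `score`, `evalue`, `empirical_p`, `category`, `same_species`.
#' @export
find_similar_pairs <- function(introns, matrices, t = thresholds(),
                               s = scoring_scheme(), seed = 1L,
                               shuffle = "mono", window_k = 20L,
                               verbose = TRUE) {
  stopifnot(!anyNA(introns$seq))
  lk <- site_lookup(matrices)
  drop <- introns$intron_id %in% lk$excluded
  if (any(drop)) {
    msg(sum(drop), " intron(s) without a projected site excluded from ",
        "pair classification", verbose = verbose)
    introns <- introns[!drop, , drop = FALSE]
  }
  n <- nrow(introns)
  if (n < 2L) return(pair_frame())
  introns <- introns[order(introns$intron_id), , drop = FALSE]
  cmb <- combn(n, 2L)
  rows <- vector("list", ncol(cmb))
  kept <- 0L
  for (p in seq_len(ncol(cmb))) {
    i <- cmb[1L, p]; j <- cmb[2L, p]
    key <- pair_key(introns$intron_id[i], introns$intron_id[j])
    res <- shuffle_significance(introns$seq[i], introns$seq[j], s = s,
                                n = t$n_shuffles,
                                seed = hash31(key, seed),
                                shuffle = shuffle, window_k = window_k)
    if (res$evalue >= t$evalue_cutoff) next
    fa <- introns$family[i]; fb <- introns$family[j]
    sa <- unname(lk$site_of[introns$intron_id[i]])
    sb <- unname(lk$site_of[introns$intron_id[j]])
    category <- if (!identical(fa, fb)) "diff_gene"
      else if (identical(sa, sb)) "same_site_same_gene"
      else "diff_site_same_gene"
    kept <- kept + 1L
    rows[[kept]] <- data.frame(
      intron_a = introns$intron_id[i], intron_b = introns$intron_id[j],
      species_a = introns$species[i], species_b = introns$species[j],
      family_a = fa, family_b = fb, site_a = sa, site_b = sb,
      score = res$score, evalue = res$evalue, empirical_p = res$empirical_p,
      category = category,
      same_species = introns$species[i] == introns$species[j],
      stringsAsFactors = FALSE)
  }
  if (kept == 0L) return(pair_frame())
  out <- do.call(rbind, rows[seq_len(kept)])
  rownames(out) <- NULL
  msg("retained ", kept, " of ", ncol(cmb), " intron pairs at E < ",
      t$evalue_cutoff, verbose = verbose)
  out
}

#' @noRd
pair_frame <- function() {
  data.frame(intron_a = character(0), intron_b = character(0),
             species_a = character(0), species_b = character(0),
             family_a = character(0), family_b = character(0),
             site_a = character(0), site_b = character(0),
             score = integer(0), evalue = numeric(0),
             empirical_p = numeric(0), category = character(0),
             same_species = logical(0), stringsAsFactors = FALSE)
}

#' Summarize sequence-similar intron pairs
#'
#' Counts and percentages per category (same site in the same gene family /
#' different site, same family / different families) and per unordered
#' species pair, within-species pairs included. Percentages are displayed at
#' the conventional precision: whole percent at or above 10, one decimal
#' below 10.
#'
#' @param pairs Pair table from [find_similar_pairs()], or any data frame
#'   with `category`, `species_a`, `species_b` columns.
#' @return A `pair_summary`: list with `n_pairs`, `categories` (data frame
#'   `category`, `count`, `percent`, `display`) and `species_pairs` (data
#'   frame `species_a`, `species_b`, `count`, `percent`, `display`, counts
#'   descending).
#' @export
summarize_pairs <- function(pairs) {
  cats <- c("same_site_same_gene", "diff_site_same_gene", "diff_gene")
  n <- nrow(pairs)
  cnt <- vapply(cats, function(cg) sum(pairs$category == cg), integer(1))
  pct <- if (n > 0L) 100 * cnt / n else rep(0, length(cats))
  categories <- data.frame(category = cats, count = as.integer(cnt),
                           percent = round_percent(pct),
                           display = format_percent(pct),
                           stringsAsFactors = FALSE, row.names = NULL)
  if (n > 0L) {
    sa <- pmin(pairs$species_a, pairs$species_b)
    sb <- pmax(pairs$species_a, pairs$species_b)
    key <- paste(sa, sb, sep = "|")
    tab <- table(key)
    parts <- strsplit(names(tab), "|", fixed = TRUE)
    spct <- 100 * as.integer(tab) / n
    species_pairs <- data.frame(
      species_a = vapply(parts, `[`, "", 1L),
      species_b = vapply(parts, `[`, "", 2L),
      count = as.integer(tab),
      percent = round_percent(spct),
      display = format_percent(spct),
      stringsAsFactors = FALSE, row.names = NULL)
    species_pairs <- species_pairs[order(-species_pairs$count,
                                         species_pairs$species_a,
                                         species_pairs$species_b), ]
    rownames(species_pairs) <- NULL
  } else {
    species_pairs <- data.frame(species_a = character(0),
                                species_b = character(0), count = integer(0),
                                percent = numeric(0), display = character(0),
                                stringsAsFactors = FALSE)
  }
  structure(list(n_pairs = n, categories = categories,
                 species_pairs = species_pairs),
            class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat(sprintf("<pair_summary> %d sequence-similar intron pairs\n", x$n_pairs))
  for (k in seq_len(nrow(x$categories)))
    cat(sprintf("  %-22s %4d (%s)\n", x$categories$category[k],
                x$categories$count[k], x$categories$display[k]))
  if (nrow(x$species_pairs) > 0L) {
    cat("  top species pairs:\n")
    top <- utils::head(x$species_pairs, 5L)
    for (k in seq_len(nrow(top)))
      cat(sprintf("    %s / %s: %d (%s)\n", top$species_a[k],
                  top$species_b[k], top$count[k], top$display[k]))
  }
  invisible(x)
}
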