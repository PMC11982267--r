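# Adenylation-level statistics: the count filter, the per-miRNA per-sample
# adenylation level
#
#   level (%) = adenylated / (adenylated + canonical) * 100
#
# and condition comparisons by one-way ANOVA with Fisher's LSD post hoc
# (pairwise t tests on the pooled within-group mean square, unadjusted).

#' Filter miRNAs by adenylated read counts
#'
#' Retains miRNAs whose adenylated counts exceed `threshold` (strict `>`),
#' either summed over all samples (default) or in every sample.
#'
#' @param counts a [count_table].
#' @param threshold count threshold (default 100; strict inequality).
#' @param mode `"sum"`: total adenylated count over samples must exceed the
#'   threshold; `"every"`: each sample's adenylated count must exceed it.
#' @return character vector of retained miRNA ids.
#' @export
filter_mirnas <- function(counts, threshold = 100, mode = c("sum", "every")) {
  mode <- match.arg(mode)
  ade <- counts$adenylated
  keep <- switch(mode,
                 sum = rowSums(ade) > threshold,
                 every = apply(ade > threshold, 1L, all))
  rownames(ade)[keep]
}

#' Adenylation level (%) from adenylated and canonical counts
#'
#' @param adenylated,canonical non-negative counts (vectorized; recycled).
#' @return percentage in [0, 100]. Errors if any pair has zero total counts
#'   (the level is undefined there, never silently 0).
#' @export
adenylation_level <- function(adenylated, canonical) {
  if (any(adenylated < 0) || any(canonical < 0))
    stop("counts must be non-negative")
  tot <- adenylated + canonical
  if (any(tot == 0))
    stop("adenylation level undefined: adenylated + canonical == 0")
  adenylated / tot * 100
}

#' Per-miRNA, per-sample adenylation-level table
#'
#' Applies the count filter and the adenylation-level formula across a count
#' table. Samples where a retained miRNA has zero total (adenylated +
#' canonical) counts get a missing level (NA) rather than an imputed value.
#'
#' @param counts a [count_table].
#' @param threshold,mode passed to [filter_mirnas()].
#' @return numeric matrix (filtered miRNAs x samples) of levels in [0, 100],
#'   with NA for undefined cells; classed `adenylation_table`.
#' @export
adenylation_levels <- function(counts, threshold = 100,
                               mode = c("sum", "every")) {
  keep <- filter_mirnas(counts, threshold, mode)
  ade <- counts$adenylated[keep, , drop = FALSE]
  can <- counts$canonical[keep, , drop = FALSE]
  tot <- ade + can
  lvl <- ifelse(tot > 0, ade / tot * 100, NA_real_)
  structure(lvl, class = c("adenylation_table", class(lvl)))
}

#' One-way ANOVA (classical between/within decomposition)
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @return list with `F`, `p`, `df_between`, `df_within`, `ss_between`,
#'   `ss_within`, `ms_within`, `group_means`, `group_n`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("each group needs >= 2 observations")
  k <- length(groups)
  N <- sum(n_i)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  if (ssw == 0 && ssb == 0)
    stop("degenerate input: zero between- and within-group variance")
  msw <- ssw / dfw
  f <- (ssb / dfb) / msw
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw,
       ss_between = ssb, ss_within = ssw, ms_within = msw,
       group_means = means, group_n = n_i)
}

#' Fisher's LSD post hoc test
#'
#' Pairwise t tests using the pooled within-group mean square and its degrees
#' of freedom from the one-way ANOVA; no multiplicity adjustment (the LSD
#' definition). With two groups the LSD p equals the pooled-variance
#' two-sample t-test p exactly.
#'
#' @param groups list of numeric vectors (as [one_way_anova()]).
#' @param pairs two-column integer matrix of group index pairs to test;
#'   default all pairs.
#' @return data.frame with columns `group1`, `group2`, `mean1`, `mean2`,
#'   `t`, `df`, `p`.
#' @export
fisher_lsd <- function(groups, pairs = NULL) {
  av <- one_way_anova(groups)
  k <- length(av$group_means)
  if (is.null(pairs)) pairs <- t(utils::combn(k, 2L))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  g1 <- pairs[, 1L]; g2 <- pairs[, 2L]
  se <- sqrt(av$ms_within * (1 / av$group_n[g1] + 1 / av$group_n[g2]))
  tval <- (av$group_means[g1] - av$group_means[g2]) / se
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_len(k))
  data.frame(group1 = nms[g1], group2 = nms[g2],
             mean1 = unname(av$group_means[g1]),
             mean2 = unname(av$group_means[g2]),
             t = unname(tval), df = av$df_within,
             p = unname(2 * stats::pt(-abs(tval), av$df_within)),
             stringsAsFactors = FALSE)
}

#' Compare adenylation levels across conditions, per miRNA
#'
#' For each miRNA in an adenylation-level table, runs a one-way ANOVA across
#' the sample groups followed by Fisher's LSD pairwise tests. miRNAs with
#' missing levels are analyzed only if every group retains at least two
#' non-missing replicates; others are skipped with a logged reason.
#'
#' @param levels an `adenylation_table` (miRNA x sample matrix of levels).
#' @param groups named character vector mapping sample id -> group label (or
#'   an unnamed vector aligned with the table's columns).
#' @param alpha significance level for the `significant` flag.
#' @param adjust if TRUE, append a Benjamini-Hochberg adjusted ANOVA p column
#'   across miRNAs (off by default; the LSD procedure itself is unadjusted).
#' @return list with `results` (one row per analyzed miRNA: `mirna_id`, `F`,
#'   `p`, group means, `significant`, and per-pair LSD p columns), `lsd`
#'   (long data.frame of all pairwise tests), and `skipped` (id + reason).
#' @export
compare_adenylation <- function(levels, groups, alpha = 0.05,
                                adjust = FALSE) {
  m <- unclass(levels)
  if (!is.null(names(groups))) {
    missing_s <- setdiff(colnames(m), names(groups))
    if (length(missing_s))
      stop("no group label for sample(s): ", paste(missing_s, collapse = ", "))
    groups <- groups[colnames(m)]
  } else if (length(groups) != ncol(m)) {
    stop("groups length must match sample columns")
  }
  glev <- unique(groups)
  if (length(glev) < 2L) stop("need >= 2 groups")
  res_rows <- list()
  lsd_rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(m))) {
    id <- rownames(m)[i]
    by_grp <- lapply(glev, function(g) {
      v <- m[i, groups == g]
      v[!is.na(v)]
    })
    names(by_grp) <- glev
    if (any(lengths(by_grp) < 2L)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(mirna_id = id, reason = "fewer than 2 non-missing replicates in a group",
                   stringsAsFactors = FALSE)
      next
    }
    av <- tryCatch(one_way_anova(by_grp), error = function(e) e)
    if (inherits(av, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(mirna_id = id, reason = conditionMessage(av),
                   stringsAsFactors = FALSE)
      next
    }
    lsd <- fisher_lsd(by_grp)
    lsd$mirna_id <- id
    lsd_rows[[length(lsd_rows) + 1L]] <- lsd
    row <- data.frame(mirna_id = id, F = av$F, p = av$p,
                      stringsAsFactors = FALSE)
    for (g in glev) row[[paste0("mean.", g)]] <- av$group_means[[g]]
    row$significant <- av$p < alpha
    res_rows[[length(res_rows) + 1L]] <- row
  }
  results <- if (length(res_rows)) do.call(rbind, res_rows) else
    data.frame(mirna_id = character(0), F = numeric(0), p = numeric(0),
               significant = logical(0))
  if (adjust && nrow(results))
    results$p_bh <- stats::p.adjust(results$p, method = "BH")
  list(results = results,
       lsd = if (length(lsd_rows)) do.call(rbind, lsd_rows) else NULL,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
       alpha = alpha)
}
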