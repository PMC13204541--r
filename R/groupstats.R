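# Edgewise and summary statistics for the two-group comparison.
#
# The edgewise pipeline compares streamline counts for every unordered
# region pair: pairs where more than half of the observations are zero are
# excluded, remaining counts are log(x + 1) transformed, compared by pooled
# two-sample t-tests (df = n_WT + n_KO - 2), and the p-values are
# Benjamini-Hochberg adjusted as one family at FDR 5%. Adjusted p-values
# carry an artificial sign (positive where KO > WT) and are assembled into a
# symmetric signed p-value matrix with display bins.

#' Enumerate unordered region pairs
#'
#' @param n_regions Number of regions (at least 2).
#' @return Two-column integer matrix of the `n(n-1)/2` pairs (1-based,
#'   `i < j`), in lexicographic order.
#' @export
enumerate_pairs <- function(n_regions) {
  if (n_regions < 2L) stop("need at least 2 regions")
  idx <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Zero filter for one pair's observations
#'
#' A pair is excluded when strictly more than 50% of its observations are
#' zero; exactly half zero is kept.
#'
#' @param values Nonnegative counts (all animals pooled).
#' @return List with `zero_fraction` and logical `included`.
#' @export
zero_filter <- function(values) {
  if (length(values) == 0L) stop("no observations")
  zf <- mean(values == 0)
  list(zero_fraction = zf, included = zf <= 0.5)
}

#' Log transform with pseudocount
#'
#' Natural log of `x + 1`, so zero counts map to zero. The log base only
#' rescales all values identically and leaves t statistics unchanged.
#'
#' @param counts Nonnegative values.
#' @return `log(counts + 1)`.
#' @export
log_pseudo <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  log(counts + 1)
}

#' Pooled two-sample t-test with direction sign
#'
#' Student's pooled-variance two-sample t (df = `n_wt + n_ko - 2`), two
#' sided, with `t` computed as `(mean(wt) - mean(ko)) / se` and an
#' artificial direction sign: `+1` when the KO mean exceeds the WT mean,
#' `-1` when below, `0` on exact ties (where p is forced to 1). When both
#' groups are constant: equal constants give `p = 1`, different constants
#' give the smallest representable p with `degenerate = TRUE`.
#'
#' @param wt,ko Numeric samples, at least 2 each.
#' @param var_equal Pooled variance (default) or Welch.
#' @return List: `t`, `df`, `p`, `sign`, `degenerate`.
#' @export
pooled_ttest <- function(wt, ko, var_equal = TRUE) {
  n1 <- length(wt)
  n2 <- length(ko)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group")
  m1 <- mean(wt)
  m2 <- mean(ko)
  v1 <- stats::var(wt)
  v2 <- stats::var(ko)
  sgn <- if (m2 > m1) 1L else if (m2 < m1) -1L else 0L
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, sign = 0L,
                  degenerate = FALSE))
    }
    return(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2,
                p = .Machine$double.xmin, sign = sgn, degenerate = TRUE))
  }
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- if (sgn == 0L) 1 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, sign = sgn, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: ranked p-values are scaled by `m/rank`
#' and made monotone from the largest down, capped at 1. A pair is a
#' discovery when its adjusted p is at or below `q`.
#'
#' @param p Raw p-values in `(0, 1]`.
#' @param q Target FDR level.
#' @return List with `p_adj` and logical `discovery`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0L) return(list(p_adj = numeric(0), discovery = logical(0)))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
  list(p_adj = adj, discovery = adj <= q)
}

# Per-animal pair-value matrix (animals x pairs) for a cohort under one
# hemisphere mode. "ipsilateral" averages the L-L and R-R blocks per animal;
# "contralateral" sums the two cross-hemisphere orientations per stem pair;
# "whole" uses the full matrix (any region count).
.pair_values <- function(cohort, mode, table = NULL) {
  conns <- cohort$connectomes
  n <- nrow(conns[[1]]$counts)
  if (mode == "whole") {
    pairs <- enumerate_pairs(n)
    labels <- rownames(conns[[1]]$counts)
    vals <- t(vapply(conns, function(c) c$counts[pairs], numeric(nrow(pairs))))
    pair_names <- paste(labels[pairs[, 1]], labels[pairs[, 2]], sep = "~")
    return(list(values = vals, pairs = pairs, labels = labels,
                pair_names = pair_names))
  }
  if (is.null(table)) table <- load_region_table()
  lt <- table[table$hemisphere == "L", ]
  lt <- lt[order(lt$id), ]
  rt <- table[table$hemisphere == "R", ]
  rt <- rt[order(match(rt$stem, lt$stem)), ]  # align R to L stem order
  nh <- nrow(lt)
  pairs <- enumerate_pairs(nh)
  vals <- t(vapply(conns, function(c) {
    m <- c$counts
    block <- switch(mode,
      "ipsilateral" =
        (m[lt$abbreviation, lt$abbreviation] +
         m[rt$abbreviation, rt$abbreviation]) / 2,
      "ipsilateral-L" = m[lt$abbreviation, lt$abbreviation],
      "ipsilateral-R" = m[rt$abbreviation, rt$abbreviation],
      "contralateral" = {
        lr <- m[lt$abbreviation, rt$abbreviation]
        lr + t(lr)  # L_i-R_j plus L_j-R_i for the unordered stem pair
      },
      stop("unknown mode '", mode, "'"))
    block[pairs]
  }, numeric(nrow(pairs))))
  list(values = vals, pairs = pairs, labels = lt$stem,
       pair_names = paste(lt$stem[pairs[, 1]], lt$stem[pairs[, 2]],
                          sep = "~"))
}

#' Edgewise group comparison with signed FDR matrix
#'
#' Runs the full edgewise pipeline on a cohort: per unordered region pair,
#' the >50%-zero filter, the log(x+1) transform, and a pooled t-test; then
#' one Benjamini-Hochberg family across all included pairs of the chosen
#' view. Returns the per-pair result table and the symmetric signed
#' adjusted-p matrix with display bins (light: 0.01 <= |p| < 0.05; dark:
#' |p| < 0.01 by default, or 0.005 <= |p| < 0.01 under the `"legend"`
#' convention).
#'
#' @param cohort A `cohort_study`.
#' @param mode `"ipsilateral"` (mean of the L-L and R-R blocks per animal),
#'   `"ipsilateral-L"`, `"ipsilateral-R"`, `"contralateral"` (both
#'   cross-hemisphere orientations summed per stem pair), or `"whole"` (all
#'   pairs of the full matrix).
#' @param q FDR level for discoveries.
#' @param table Region table binding the matrices (defaults to the packaged
#'   table; ignored for `mode = "whole"`).
#' @param dark_convention `"text"`: dark bin is |p| < 0.01; `"legend"`:
#'   dark bin is 0.005 <= |p| < 0.01.
#' @param var_equal Pooled (default) or Welch t.
#' @return List with `edges` (per-pair data frame), `signed_p` (symmetric
#'   matrix, NA where filtered), `mode`, `q`, and `n_discoveries`.
#' @export
edgewise_compare <- function(cohort, mode = c("ipsilateral", "contralateral",
                                              "ipsilateral-L",
                                              "ipsilateral-R", "whole"),
                             q = 0.05, table = NULL,
                             dark_convention = c("text", "legend"),
                             var_equal = TRUE) {
  mode <- match.arg(mode)
  dark_convention <- match.arg(dark_convention)
  stopifnot(inherits(cohort, "cohort_study"))
  groups <- vapply(cohort$connectomes, function(c) c$group, character(1))
  if (sum(groups == "WT") < 2L || sum(groups == "KO") < 2L) {
    stop("need at least 2 animals per group")
  }
  pv <- .pair_values(cohort, mode, table)
  vals <- pv$values
  n_pairs <- ncol(vals)

  zero_frac <- colMeans(vals == 0)
  included <- zero_frac <= 0.5
  if (!any(included)) stop("no testable pairs: every pair failed the zero filter")

  lv <- log_pseudo(vals)
  wt <- lv[groups == "WT", , drop = FALSE]
  ko <- lv[groups == "KO", , drop = FALSE]

  res <- data.frame(
    pair = pv$pair_names,
    region_a = pv$labels[pv$pairs[, 1]],
    region_b = pv$labels[pv$pairs[, 2]],
    zero_fraction = zero_frac,
    included = included,
    t = NA_real_, df = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
    sign = NA_integer_, stringsAsFactors = FALSE)

  for (p_idx in which(included)) {
    tt <- pooled_ttest(wt[, p_idx], ko[, p_idx], var_equal = var_equal)
    res$t[p_idx] <- tt$t
    res$df[p_idx] <- tt$df
    res$p_raw[p_idx] <- tt$p
    res$sign[p_idx] <- tt$sign
  }
  bh <- bh_adjust(res$p_raw[included], q = q)
  res$p_adj[included] <- bh$p_adj
  res$discovery <- FALSE
  res$discovery[included] <- bh$discovery
  res$signed_p <- res$p_adj * ifelse(is.na(res$sign) | res$sign == 0,
                                     1, res$sign)
  res$bin <- p_bin(res$p_adj, dark_convention)

  sp <- matrix(NA_real_, length(pv$labels), length(pv$labels),
               dimnames = list(pv$labels, pv$labels))
  sp[pv$pairs[included, , drop = FALSE]] <- res$signed_p[included]
  sp[pv$pairs[included, c(2, 1), drop = FALSE]] <- res$signed_p[included]
  structure(list(edges = res, signed_p = sp, mode = mode, q = q,
                 n_discoveries = sum(res$discovery)),
            class = "edgewise_result")
}

# Display bin of an adjusted |p|: none / light / dark.
p_bin <- function(p_adj, dark_convention = c("text", "legend")) {
  dark_convention <- match.arg(dark_convention)
  ap <- abs(p_adj)
  bin <- rep(NA_character_, length(ap))
  ok <- !is.na(ap)
  bin[ok] <- "none"
  bin[ok & ap < 0.05 & ap >= 0.01] <- "light"
  if (dark_convention == "text") {
    bin[ok & ap < 0.01] <- "dark"
  } else {
    bin[ok & ap < 0.01 & ap >= 0.005] <- "dark"
    bin[ok & ap < 0.005] <- "dark"  # below the legend's lower edge: darkest
  }
  bin
}

#' @export
print.edgewise_result <- function(x, ...) {
  cat(sprintf(
    "edgewise_result (%s): %d pairs, %d included, %d discoveries at FDR %g\n",
    x$mode, nrow(x$edges), sum(x$edges$included), x$n_discoveries, x$q))
  invisible(x)
}

#' Region-level streamline totals comparison
#'
#' Per-animal totals are the row sums of the full count matrix (all
#' streamlines touching the region); group means are compared per region by
#' pooled t-tests with Benjamini-Hochberg adjustment across regions.
#'
#' @param cohort A `cohort_study`.
#' @param q FDR level.
#' @param var_equal Pooled (default) or Welch t.
#' @return Data frame with one row per region: means, `t`, `p_raw`, `p_adj`,
#'   `sign`, `discovery`.
#' @export
region_streamline_compare <- function(cohort, q = 0.05, var_equal = TRUE) {
  stopifnot(inherits(cohort, "cohort_study"))
  groups <- vapply(cohort$connectomes, function(c) c$group, character(1))
  totals <- t(vapply(cohort$connectomes, function(c) rowSums(c$counts),
                     numeric(nrow(cohort$connectomes[[1]]$counts))))
  labels <- colnames(totals)
  wt <- totals[groups == "WT", , drop = FALSE]
  ko <- totals[groups == "KO", , drop = FALSE]
  res <- lapply(seq_along(labels), function(r) {
    tt <- pooled_ttest(wt[, r], ko[, r], var_equal = var_equal)
    data.frame(region = labels[r], mean_wt = mean(wt[, r]),
               mean_ko = mean(ko[, r]), t = tt$t, df = tt$df,
               p_raw = tt$p, sign = tt$sign, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  bh <- bh_adjust(res$p_raw, q = q)
  res$p_adj <- bh$p_adj
  res$discovery <- bh$discovery
  res
}

#' Compare network parameters between groups
#'
#' Pooled two-sample t-test per metric column on a per-animal metric table.
#' No multiplicity correction is applied across metrics (reported as-is in
#' the output metadata). Undefined (NA) metric values are dropped per
#' metric, with the dropped count reported; a metric without at least two
#' defined values per group is marked not testable.
#'
#' @param metrics Data frame with a `group` column (`WT`/`KO`) and numeric
#'   metric columns (one row per animal).
#' @param var_equal Pooled (default) or Welch t.
#' @return Data frame: one row per metric with group means, `t`, `df`, `p`,
#'   `sign`, `n_dropped`, `testable`.
#' @export
compare_network_params <- function(metrics, var_equal = TRUE) {
  stopifnot("group" %in% names(metrics))
  cols <- setdiff(names(metrics), c("group", "animal_id", "provenance"))
  res <- lapply(cols, function(cl) {
    v <- metrics[[cl]]
    ok <- !is.na(v)
    wt <- v[ok & metrics$group == "WT"]
    ko <- v[ok & metrics$group == "KO"]
    if (length(wt) < 2L || length(ko) < 2L) {
      return(data.frame(metric = cl, mean_wt = mean(wt), mean_ko = mean(ko),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        sign = NA_integer_, n_dropped = sum(!ok),
                        testable = FALSE, stringsAsFactors = FALSE))
    }
    tt <- pooled_ttest(wt, ko, var_equal = var_equal)
    data.frame(metric = cl, mean_wt = mean(wt), mean_ko = mean(ko),
               t = tt$t, df = tt$df, p = tt$p, sign = tt$sign,
               n_dropped = sum(!ok), testable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
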