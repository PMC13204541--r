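# Tensor-eigenvalue diffusivity scalars and their region-wise group tests.

#' Diffusivity scalars from tensor eigenvalues
#'
#' Computes the four standard diffusion-tensor scalars from a descending
#' eigenvalue triple: axial diffusivity `ad = lambda1`, radial diffusivity
#' `rd = (lambda2 + lambda3) / 2`, mean diffusivity `md` (the eigenvalue
#' mean), and fractional anisotropy
#' `fa = sqrt(3/2) * ||lambda - md|| / ||lambda||`, which runs from 0 for an
#' isotropic tensor to 1 for a single nonzero eigenvalue. Vectorized over
#' triples.
#'
#' @param lambda1,lambda2,lambda3 Eigenvalues with
#'   `lambda1 >= lambda2 >= lambda3 >= 0`, not all zero (units mm^2/s).
#' @return List with numeric components `fa`, `md`, `ad`, `rd`.
#' @export
diffusivity_scalars <- function(lambda1, lambda2, lambda3) {
  lam <- cbind(lambda1, lambda2, lambda3)
  if (any(lam < 0)) stop("eigenvalues must be nonnegative")
  if (any(lambda1 < lambda2 | lambda2 < lambda3)) {
    stop("eigenvalues must be sorted: lambda1 >= lambda2 >= lambda3")
  }
  norm2 <- rowSums(lam^2)
  if (any(norm2 == 0)) stop("degenerate tensor: all eigenvalues zero")
  md <- rowMeans(lam)
  fa <- sqrt(1.5 * rowSums((lam - md)^2) / norm2)
  # Clip only floating-point overshoot; anything larger is a real error.
  over <- fa > 1
  if (any(fa[over] > 1 + 1e-12)) stop("fa exceeded 1 beyond rounding error")
  fa[over] <- 1
  list(fa = as.numeric(fa), md = as.numeric(md),
       ad = as.numeric(lambda1), rd = as.numeric((lambda2 + lambda3) / 2))
}

#' Region-wise group comparison of a diffusivity scalar
#'
#' For each region, a pooled-variance two-sample t-test compares per-animal
#' values of the chosen scalar between groups; p-values are corrected across
#' regions and carry an artificial sign: positive where the KO mean exceeds
#' the WT mean, negative otherwise. Regions with `|p_adj| < alpha` are
#' flagged.
#'
#' @param records Data frame with columns `animal_id`, `group` (`WT`/`KO`),
#'   `region_id`, and the scalar columns (as from [simulate_diffusivity()]
#'   or a `fa`/`md`/`ad`/`rd` table read from file).
#' @param scalar One of `"FA"`, `"MD"`, `"AD"`, `"RD"`.
#' @param correction `"BH"` (default), `"bonferroni"`, or `"none"`.
#' @param alpha Flagging threshold on the adjusted p-value.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return Data frame with one row per region: group means, `t`, `df`,
#'   `p_raw`, `p_adj`, `sign`, `signed_p`, `flag`, `testable`.
#' @export
compare_regions <- function(records, scalar = c("FA", "MD", "AD", "RD"),
                            correction = c("BH", "bonferroni", "none"),
                            alpha = 0.05, var_equal = TRUE) {
  scalar <- match.arg(scalar)
  correction <- match.arg(correction)
  col <- tolower(scalar)
  if (!col %in% names(records)) stop("records lack a '", col, "' column")
  if (!all(c("group", "region_id") %in% names(records))) {
    stop("records need 'group' and 'region_id' columns")
  }
  regions <- sort(unique(records$region_id))
  res <- lapply(regions, function(r) {
    sub <- records[records$region_id == r, ]
    wt <- sub[[col]][sub$group == "WT"]
    ko <- sub[[col]][sub$group == "KO"]
    if (length(wt) < 2L || length(ko) < 2L) {
      return(data.frame(region_id = r, n_wt = length(wt), n_ko = length(ko),
                        mean_wt = mean(wt), mean_ko = mean(ko),
                        t = NA_real_, df = NA_real_, p_raw = NA_real_,
                        sign = NA_integer_, testable = FALSE))
    }
    tt <- pooled_ttest(wt, ko, var_equal = var_equal)
    data.frame(region_id = r, n_wt = length(wt), n_ko = length(ko),
               mean_wt = mean(wt), mean_ko = mean(ko),
               t = tt$t, df = tt$df, p_raw = tt$p, sign = tt$sign,
               testable = TRUE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  ok <- res$testable
  if (any(ok)) {
    res$p_adj[ok] <- switch(correction,
      BH = bh_adjust(res$p_raw[ok])$p_adj,
      bonferroni = pmin(1, res$p_raw[ok] * sum(ok)),
      none = res$p_raw[ok])
  }
  res$signed_p <- res$p_adj * ifelse(res$sign == 0, 1, res$sign)
  res$flag <- ok & !is.na(res$p_adj) & res$p_adj < alpha & res$sign != 0
  res
}
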