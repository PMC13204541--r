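# Synthetic two-group connectome cohorts.
#
# The generator emulates the statistical structure the downstream comparison
# assumes: per-edge streamline counts are zero-inflated rounded lognormal
# draws, so after the log(x + 1) transform the included edges are close to
# Gaussian and the pooled t-test's assumptions are recoverable by design.
# Structural zeros are drawn once per cohort at the edge level (a missing
# tract is a property of the topology, shared by every animal), and planted
# group effects multiply the lognormal mean of chosen edges in the KO group.

#' Simulation configuration
#'
#' @param n_wt,n_ko Animals per group. Defaults 8 and 12 match the cohort
#'   sizes the analysis is designed around.
#' @param n_regions Even number of regions (half per hemisphere).
#' @param baseline_log_mean,baseline_log_sd Mean and sd of log counts for a
#'   present edge. The default sd of 0.5 is a realistic between-animal
#'   spread for tract counts on the log scale.
#' @param zero_prob Probability that an edge is a structural zero (absent in
#'   every animal of the cohort).
#' @param planted_edges List of `list(pair = c(i, j), effect = x)` entries:
#'   region-id pairs whose KO lognormal mean is multiplied by `effect` (> 0).
#' @param planted_regions List of `list(region_id =, scalar =, effect =)`
#'   entries for [simulate_diffusivity()]: `scalar` is one of `"AD"`, `"RD"`,
#'   `"MD"`, and `effect` multiplies the KO mean of that scalar.
#' @param lambda_base Baseline tensor eigenvalues (mm^2/s), descending.
#'   The default is a mildly anisotropic ex vivo tissue tensor.
#' @param diffusivity_log_sd Log-scale noise sd for eigenvalue draws.
#' @param seed Integer master seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_wt = 8L, n_ko = 12L, n_regions = 72L,
                       baseline_log_mean = 4, baseline_log_sd = 0.5,
                       zero_prob = 0.15,
                       planted_edges = list(), planted_regions = list(),
                       lambda_base = c(1.0e-3, 0.55e-3, 0.45e-3),
                       diffusivity_log_sd = 0.05,
                       seed = 1L) {
  if (n_wt < 1L || n_ko < 1L) stop("need at least one animal per group")
  if (n_regions %% 2L != 0L || n_regions < 2L) {
    stop("n_regions must be a positive even number")
  }
  if (baseline_log_sd <= 0) stop("baseline_log_sd must be positive")
  if (zero_prob < 0 || zero_prob >= 1) stop("zero_prob must be in [0, 1)")
  seen <- character(0)
  for (pe in planted_edges) {
    if (is.null(pe$pair) || length(pe$pair) != 2L || pe$pair[1] == pe$pair[2]) {
      stop("planted edge pairs must be two distinct region ids")
    }
    if (any(pe$pair < 0) || any(pe$pair >= n_regions)) {
      stop("planted edge region ids must be in [0, n_regions)")
    }
    if (is.null(pe$effect) || pe$effect <= 0) {
      stop("planted edge effect must be > 0")
    }
    key <- paste(sort(pe$pair), collapse = "-")
    if (key %in% seen) stop("duplicate planted edge pair ", key)
    seen <- c(seen, key)
  }
  for (pr in planted_regions) {
    if (is.null(pr$region_id) || is.null(pr$scalar) || is.null(pr$effect)) {
      stop("planted regions need region_id, scalar and effect")
    }
    if (!pr$scalar %in% c("AD", "RD", "MD")) {
      stop("planted diffusivity scalar must be one of AD, RD, MD")
    }
    if (pr$effect <= 0) stop("planted diffusivity effect must be > 0")
  }
  structure(list(
    n_wt = as.integer(n_wt), n_ko = as.integer(n_ko),
    n_regions = as.integer(n_regions),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    zero_prob = zero_prob,
    planted_edges = planted_edges,
    planted_regions = planted_regions,
    lambda_base = sort(lambda_base, decreasing = TRUE),
    diffusivity_log_sd = diffusivity_log_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic per-animal substream seed: an LCG step of the master seed
# keyed by the animal index, so each animal's draws are independent of
# iteration order. Kept below 2^31 - 1.
.substream_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) * 48271 + index * 16807 + salt * 69621) %% 2147483647
  as.integer(s)
}

# Region labels for simulated matrices: matches the packaged table when
# n_regions is 72, synthetic stems otherwise (L block first, then R).
.sim_labels <- function(n_regions) {
  if (n_regions == 72L) {
    tab <- load_region_table()
    return(tab$abbreviation[order(tab$id)])
  }
  half <- n_regions %/% 2L
  stems <- sprintf("S%02d", seq_len(half))
  c(paste0("L", stems), paste0("R", stems))
}

#' Simulate a two-group cohort of connectomes
#'
#' Per edge, counts are a cohort-level structural-zero mask times a rounded
#' lognormal draw; planted KO effects multiply the lognormal mean of chosen
#' edges. Matrices are symmetric with zero diagonal. The same configuration
#' (and seed) always reproduces the cohort bit for bit.
#'
#' @param config A [sim_config()].
#' @param diffusivity Also draw per-animal per-region tensor eigenvalues
#'   (see [simulate_diffusivity()])?
#' @return A `cohort_study`: list with `connectomes` (list of `connectome`),
#'   `diffusivity` (data frame or `NULL`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), diffusivity = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions
  labels <- .sim_labels(n)
  ut <- upper.tri(matrix(0, n, n))
  n_edges <- sum(ut)

  # Cohort-level structural-zero mask.
  set.seed(.substream_seed(config$seed, 0L, salt = 1L))
  present <- stats::runif(n_edges) >= config$zero_prob

  # Per-edge KO log-mean offsets for planted effects (ids are 0-based).
  ko_offset <- numeric(n_edges)
  if (length(config$planted_edges) > 0) {
    edge_index <- matrix(0L, n, n)
    edge_index[ut] <- seq_len(n_edges)
    for (pe in config$planted_edges) {
      i <- min(pe$pair) + 1L
      j <- max(pe$pair) + 1L
      ko_offset[edge_index[i, j]] <- log(pe$effect)
    }
  }

  groups <- c(rep("WT", config$n_wt), rep("KO", config$n_ko))
  ids <- sprintf("%s%02d", ifelse(groups == "WT", "wt", "ko"),
                 c(seq_len(config$n_wt), seq_len(config$n_ko)))
  connectomes <- vector("list", length(groups))
  for (a in seq_along(groups)) {
    set.seed(.substream_seed(config$seed, a, salt = 2L))
    meanlog <- config$baseline_log_mean +
      if (groups[a] == "KO") ko_offset else 0
    vals <- round(stats::rlnorm(n_edges, meanlog, config$baseline_log_sd))
    vals[!present] <- 0
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    m[ut] <- vals
    m <- m + t(m)
    connectomes[[a]] <- connectome(m, animal_id = ids[a], group = groups[a])
  }
  diff_tab <- if (diffusivity) simulate_diffusivity(config) else NULL
  structure(list(connectomes = connectomes, diffusivity = diff_tab,
                 config = config),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  grp <- vapply(x$connectomes, function(c) c$group, character(1))
  cat(sprintf("cohort_study: %d WT + %d KO connectomes, %d regions\n",
              sum(grp == "WT"), sum(grp == "KO"), x$config$n_regions))
  if (!is.null(x$diffusivity)) {
    cat(sprintf("  with diffusivity records (%d rows)\n", nrow(x$diffusivity)))
  }
  invisible(x)
}

#' Simulate per-animal per-region tensor eigenvalues
#'
#' Eigenvalues are drawn on the log scale around the configured baseline
#' triple and sorted into descending order, guaranteeing
#' lambda1 >= lambda2 >= lambda3 > 0. Planted KO effects multiply the mean of
#' the targeted scalar: AD scales lambda1, RD scales lambda2 and lambda3, MD
#' scales all three. Derived scalars FA/MD/AD/RD are attached per record.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `animal_id`, `group`, `region_id`,
#'   `lambda1..3`, `fa`, `md`, `ad`, `rd`.
#' @export
simulate_diffusivity <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions
  groups <- c(rep("WT", config$n_wt), rep("KO", config$n_ko))
  ids <- sprintf("%s%02d", ifelse(groups == "WT", "wt", "ko"),
                 c(seq_len(config$n_wt), seq_len(config$n_ko)))

  # Per-region KO multipliers for each eigenvalue.
  mult <- matrix(1, n, 3)
  for (pr in config$planted_regions) {
    r <- pr$region_id + 1L
    cols <- switch(pr$scalar, AD = 1L, RD = 2:3, MD = 1:3)
    mult[r, cols] <- mult[r, cols] * pr$effect
  }

  out <- vector("list", length(groups))
  for (a in seq_along(groups)) {
    set.seed(.substream_seed(config$seed, a, salt = 3L))
    base <- matrix(rep(config$lambda_base, each = n), n, 3)
    if (groups[a] == "KO") base <- base * mult
    lam <- base * exp(matrix(stats::rnorm(n * 3, 0, config$diffusivity_log_sd),
                             n, 3))
    lam <- t(apply(lam, 1L, sort, decreasing = TRUE))
    scal <- diffusivity_scalars(lam[, 1], lam[, 2], lam[, 3])
    out[[a]] <- data.frame(
      animal_id = ids[a], group = groups[a], region_id = seq_len(n) - 1L,
      lambda1 = lam[, 1], lambda2 = lam[, 2], lambda3 = lam[, 3],
      fa = scal$fa, md = scal$md, ad = scal$ad, rd = scal$rd)
  }
  do.call(rbind, out)
}
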