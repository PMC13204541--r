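# Hypothesis-driven comparison of named circuit connections.
#
# A circuit is a small set of composite ROI nodes and an ordered list of
# node pairs; per animal, a pair's connection strength is the summed
# streamline count between the two resolved region sets, either within
# hemispheres (ipsilateral, averaged over L-L and R-R) or across
# hemispheres (contralateral). Pairs are compared by pooled t-tests with
# Benjamini-Hochberg adjustment across that circuit's pairs only.

# Node label -> abbreviation stems. Hipp is the CA1+CA2+CA3+DG union;
# ICtx is the isocortex node.
.circuit_nodes <- list(
  TH = "TH", SS = "SS", ICtx = "ICtx", HY = "HY", COA = "COA", EC = "EC",
  Hipp = c("CA1", "CA2", "CA3", "DG")
)

.builtin_circuits <- list(
  fear = list(
    name = "fear",
    nodes = c("TH", "SS", "ICtx", "HY", "COA"),
    pairs = list(c("ICtx", "TH"), c("COA", "TH"), c("SS", "TH"),
                 c("COA", "HY"), c("COA", "ICtx"), c("SS", "COA"))),
  tle = list(
    name = "tle",
    nodes = c("Hipp", "TH", "ICtx", "COA", "EC"),
    pairs = list(c("Hipp", "TH"), c("COA", "ICtx"), c("EC", "ICtx"),
                 c("Hipp", "ICtx"), c("EC", "COA"), c("Hipp", "COA"),
                 c("Hipp", "EC")))
)

#' Built-in circuit definitions
#'
#' `"fear"` is the fear-conditioning pathway (thalamus, somatosensory
#' cortex, isocortex, hypothalamus, amygdala; six tested pairs). `"tle"` is
#' the temporal-lobe-epilepsy circuitry including the hippocampal-thalamic
#' pathway (seven tested pairs). Pair identity is unordered.
#'
#' @param name `"fear"` or `"tle"`.
#' @return A `circuit_definition`: list with `name`, `nodes`, `pairs`.
#' @export
builtin_circuit <- function(name) {
  if (!name %in% names(.builtin_circuits)) {
    stop("unknown circuit '", name, "'; built-ins: ",
         paste(names(.builtin_circuits), collapse = ", "))
  }
  def <- .builtin_circuits[[name]]
  circuit_definition(def$name, def$nodes, def$pairs)
}

#' Define a circuit
#'
#' @param name Circuit name.
#' @param nodes Character vector of node labels; built-in labels (`TH`,
#'   `SS`, `ICtx`, `HY`, `COA`, `EC`, `Hipp`) resolve to region stems
#'   automatically, other labels must be abbreviation stems.
#' @param pairs List of length-2 character vectors of node labels to test;
#'   pairs must be unique (unordered) and drawn from `nodes`.
#' @return A `circuit_definition`.
#' @export
circuit_definition <- function(name, nodes, pairs) {
  keys <- vapply(pairs, function(p) paste(sort(p), collapse = "~"),
                 character(1))
  if (anyDuplicated(keys)) stop("duplicate circuit pairs")
  bad <- unlist(pairs)[!unlist(pairs) %in% nodes]
  if (length(bad) > 0) {
    stop("pair label(s) not in nodes: ", paste(unique(bad), collapse = ", "))
  }
  structure(list(name = name, nodes = nodes, pairs = pairs),
            class = "circuit_definition")
}

# Region-id sets per node label and hemisphere.
.resolve_node <- function(table, label, hemisphere) {
  stems <- if (label %in% names(.circuit_nodes)) {
    .circuit_nodes[[label]]
  } else {
    label
  }
  resolve_composite(table, composite_roi(label, stems), hemisphere)
}

# Summed counts between two region-id sets (0-based ids).
.set_strength <- function(counts, table, ids_a, ids_b) {
  a <- table$abbreviation[match(ids_a, table$id)]
  b <- table$abbreviation[match(ids_b, table$id)]
  sum(counts[a, b, drop = FALSE])
}

#' Per-animal circuit connection strengths
#'
#' @param cohort A `cohort_study`.
#' @param circuit A `circuit_definition` or built-in name.
#' @param side `"ipsilateral"` (mean of the L-L and R-R set-to-set sums) or
#'   `"contralateral"` (both cross-hemisphere orientations summed).
#' @param table Binding `region_table` (defaults to the packaged table).
#' @return Data frame: `animal_id`, `group`, `pair`, `strength`.
#' @export
circuit_strengths <- function(cohort, circuit,
                              side = c("ipsilateral", "contralateral"),
                              table = NULL) {
  side <- match.arg(side)
  if (is.character(circuit)) circuit <- builtin_circuit(circuit)
  stopifnot(inherits(circuit, "circuit_definition"))
  if (is.null(table)) table <- load_region_table()
  sets <- list(
    L = lapply(stats::setNames(circuit$nodes, circuit$nodes),
               function(nd) .resolve_node(table, nd, "L")),
    R = lapply(stats::setNames(circuit$nodes, circuit$nodes),
               function(nd) .resolve_node(table, nd, "R")))
  rows <- list()
  for (conn in cohort$connectomes) {
    for (pr in circuit$pairs) {
      s <- if (side == "ipsilateral") {
        (.set_strength(conn$counts, table, sets$L[[pr[1]]], sets$L[[pr[2]]]) +
         .set_strength(conn$counts, table, sets$R[[pr[1]]], sets$R[[pr[2]]])) / 2
      } else {
        .set_strength(conn$counts, table, sets$L[[pr[1]]], sets$R[[pr[2]]]) +
        .set_strength(conn$counts, table, sets$L[[pr[2]]], sets$R[[pr[1]]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = conn$animal_id, group = conn$group,
        pair = paste(pr[1], pr[2], sep = "-"), strength = s,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare circuit connections between groups
#'
#' Per circuit pair: pooled t-test on per-animal connection strengths, with
#' Benjamini-Hochberg adjustment across the circuit's pairs only (each
#' circuit is its own family). Pairs with adjusted p at or below `q` are
#' significant; others are reported `"nd"` (no difference).
#'
#' @inheritParams circuit_strengths
#' @param q FDR level within the circuit.
#' @param var_equal Pooled (default) or Welch t.
#' @return Data frame: one row per pair with group means, `t`, `df`,
#'   `p_raw`, `p_adj`, `sign`, `significant`, `label`.
#' @export
circuit_compare <- function(cohort, circuit,
                            side = c("ipsilateral", "contralateral"),
                            q = 0.05, table = NULL, var_equal = TRUE) {
  side <- match.arg(side)
  if (is.character(circuit)) circuit <- builtin_circuit(circuit)
  st <- circuit_strengths(cohort, circuit, side = side, table = table)
  pair_levels <- unique(st$pair)
  res <- lapply(pair_levels, function(pr) {
    sub <- st[st$pair == pr, ]
    wt <- sub$strength[sub$group == "WT"]
    ko <- sub$strength[sub$group == "KO"]
    tt <- pooled_ttest(wt, ko, var_equal = var_equal)
    data.frame(pair = pr, side = side, mean_wt = mean(wt), mean_ko = mean(ko),
               t = tt$t, df = tt$df, p_raw = tt$p, sign = tt$sign,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  bh <- bh_adjust(res$p_raw, q = q)
  res$p_adj <- bh$p_adj
  res$significant <- bh$discovery
  res$label <- ifelse(res$significant, "*", "nd")
  res
}
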