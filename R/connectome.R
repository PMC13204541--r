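# Per-animal adjacency matrices and their derived weight views.
#
# A connectome holds raw symmetric streamline counts over the full bilateral
# parcellation. Graph analysis runs on weight views: a (sub)matrix normalized
# so its maximum is one, with entries below the extraction threshold removed.

#' Construct a connectome
#'
#' @param counts Square numeric matrix of nonnegative streamline counts with
#'   region abbreviations as dimnames. Asymmetric input is symmetrized by the
#'   elementwise maximum (streamline counts from A-to-B vs B-to-A seeding
#'   differ only by seeding; the graphs are undirected), with a warning.
#' @param animal_id Identifier string.
#' @param group `"WT"` or `"KO"`.
#' @return A `connectome` object.
#' @export
connectome <- function(counts, animal_id = "animal", group = c("WT", "KO")) {
  group <- match.arg(group)
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stop("counts must be a square matrix")
  }
  if (any(counts < 0)) stop("negative streamline counts")
  if (!isTRUE(all.equal(counts, t(counts), check.attributes = FALSE))) {
    warning("asymmetric count matrix symmetrized by elementwise maximum")
    counts <- pmax(counts, t(counts))
  }
  diag(counts) <- 0
  structure(list(animal_id = animal_id, group = group, counts = counts),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome '%s' (%s): %d regions, %d nonzero edges\n",
              x$animal_id, x$group, nrow(x$counts),
              sum(x$counts[upper.tri(x$counts)] > 0)))
  invisible(x)
}

#' Read a streamline-count matrix
#'
#' Accepts either a labelled TSV (region abbreviations in the header row and
#' first column) or a bare numeric block whose dimension matches the region
#' table. Labelled input is reordered to the table's region order.
#'
#' @param path TSV file.
#' @param table A `region_table` the matrix must conform to.
#' @inheritParams connectome
#' @return A `connectome`.
#' @export
read_count_matrix <- function(path, table, animal_id = "animal",
                              group = c("WT", "KO")) {
  group <- match.arg(group)
  raw <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  order_abbr <- table$abbreviation[order(table$id)]
  if (!is.numeric(raw[[1]]) || colnames(raw)[1] %in% c("", "X", "region")) {
    labels <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- labels
    unknown <- union(setdiff(rownames(m), order_abbr),
                     setdiff(colnames(m), order_abbr))
    if (length(unknown) > 0) {
      stop("labels not in the region table: ", paste(unknown, collapse = ", "))
    }
    if (nrow(m) != length(order_abbr)) {
      stop(sprintf("matrix is %dx%d but the region table has %d regions",
                   nrow(m), ncol(m), length(order_abbr)))
    }
    m <- m[order_abbr, order_abbr]
  } else {
    m <- as.matrix(raw)
    if (nrow(m) != length(order_abbr) || ncol(m) != length(order_abbr)) {
      stop(sprintf("matrix is %dx%d but the region table has %d regions",
                   nrow(m), ncol(m), length(order_abbr)))
    }
    dimnames(m) <- list(order_abbr, order_abbr)
  }
  storage.mode(m) <- "double"
  connectome(m, animal_id = animal_id, group = group)
}

#' Write a count matrix as labelled TSV
#'
#' @param x A `connectome` or labelled square matrix.
#' @param path Output file.
#' @export
write_count_matrix <- function(x, path) {
  m <- if (inherits(x, "connectome")) x$counts else x
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a weight view
#'
#' @param weights Symmetric matrix with entries in `[0, 1]`, zero diagonal.
#' @param provenance Which slice of the connectome the view is
#'   (`"whole"`, `"ipsilateral-L"`, ..., `"merged"`).
#' @return A `graph_view` object.
#' @export
graph_view <- function(weights, provenance = "whole") {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  diag(weights) <- 0
  structure(list(weights = weights, labels = rownames(weights),
                 provenance = provenance),
            class = "graph_view")
}

#' @export
print.graph_view <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("graph_view (%s): %d nodes, %d edges, max weight %.4g\n",
              x$provenance, nrow(x$weights), sum(w > 0), max(w)))
  invisible(x)
}

#' Normalize a count matrix to maximum one
#'
#' Divides every entry by the matrix maximum so that the largest weight is
#' exactly 1. Idempotent, and invariant to uniform positive scaling of the
#' input counts.
#'
#' @param m Square nonnegative matrix (or a `connectome`, whose counts are
#'   used) with at least one positive entry.
#' @param provenance Provenance tag for the resulting view.
#' @return A `graph_view` with entries in `[0, 1]` and maximum exactly 1.
#' @export
normalize_weights <- function(m, provenance = "whole") {
  if (inherits(m, "connectome")) m <- m$counts
  if (inherits(m, "graph_view")) m <- m$weights
  mx <- max(m)
  if (mx <= 0) stop("empty graph: no positive entries to normalize")
  graph_view(m / mx, provenance = provenance)
}

#' Remove weights below the extraction threshold
#'
#' Entries strictly below `t` are set to zero; entries at or above `t`
#' (including exactly `t`) are kept, so `t = 0` is the identity. The default
#' 0.001 is the extraction threshold applied to normalized weights for both
#' ipsilateral and contralateral analyses.
#'
#' @param view A `graph_view` (or matrix).
#' @param t Threshold in `[0, 1)` on normalized weights.
#' @return A `graph_view` of the same shape.
#' @export
threshold_weights <- function(view, t = 0.001) {
  if (t < 0 || t >= 1) stop("threshold must be in [0, 1)")
  prov <- if (inherits(view, "graph_view")) view$provenance else "whole"
  w <- if (inherits(view, "graph_view")) view$weights else view
  w[w < t] <- 0
  graph_view(w, provenance = prov)
}

#' Hemisphere view of a connectome
#'
#' Slices the within-hemisphere (ipsilateral) or cross-hemisphere
#' (contralateral) 36x36 block of the count matrix, then normalizes to
#' maximum one and applies the extraction threshold. The contralateral LR
#' and RL blocks are transposes of one another for symmetric counts; both
#' are offered for completeness.
#'
#' @param c A `connectome`.
#' @param table The `region_table` binding the matrix rows.
#' @param mode One of `"ipsilateral-L"`, `"ipsilateral-R"`,
#'   `"contralateral-LR"`, `"contralateral-RL"`.
#' @param threshold Extraction threshold (see [threshold_weights()]).
#' @param normalize Normalize and threshold (default)? If `FALSE` the raw
#'   count block is returned as a plain matrix.
#' @return A `graph_view` (or raw matrix when `normalize = FALSE`).
#' @export
hemisphere_view <- function(c, table,
                            mode = c("ipsilateral-L", "ipsilateral-R",
                                     "contralateral-LR", "contralateral-RL"),
                            threshold = 0.001, normalize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(c, "connectome"))
  left <- table$abbreviation[table$hemisphere == "L"][order(table$id[table$hemisphere == "L"])]
  right <- table$abbreviation[table$hemisphere == "R"][order(table$id[table$hemisphere == "R"])]
  block <- switch(mode,
    "ipsilateral-L"    = c$counts[left, left],
    "ipsilateral-R"    = c$counts[right, right],
    "contralateral-LR" = c$counts[left, right],
    "contralateral-RL" = c$counts[right, left])
  if (!normalize) return(block)
  threshold_weights(normalize_weights(block, provenance = mode), threshold)
}

#' Symmetric contralateral count matrix over stems
#'
#' Combines both cross-hemisphere orientations of the contralateral block
#' into one symmetric stem-by-stem matrix: entry (i, j) is
#' `counts(L_i, R_j) + counts(L_j, R_i)`. The homotopic diagonal
#' (`counts(L_i, R_i)`) is zeroed so the result is a valid adjacency matrix.
#'
#' @param c A `connectome`.
#' @param table Binding `region_table`.
#' @return Symmetric numeric matrix labelled by abbreviation stems.
#' @export
contralateral_matrix <- function(c, table) {
  stopifnot(inherits(c, "connectome"))
  lt <- table[table$hemisphere == "L", ]
  lt <- lt[order(lt$id), ]
  rt <- table[table$hemisphere == "R", ]
  rt <- rt[match(lt$stem, rt$stem), ]  # align right block to left stem order
  lr <- c$counts[lt$abbreviation, rt$abbreviation]
  m <- lr + t(lr)
  dimnames(m) <- list(lt$stem, lt$stem)
  diag(m) <- 0
  m
}

#' Merge composite ROIs into single nodes
#'
#' Counts between merged nodes are sums over member-pair counts; counts
#' among the members of one ROI disappear into the (zero) diagonal, so the
#' off-diagonal mass outside the ROIs is conserved. ROIs are resolved and
#' merged within each hemisphere.
#'
#' @param c A `connectome`.
#' @param rois List of `composite_roi` (or predetermined ROI labels). Member
#'   sets must be disjoint.
#' @param table The binding `region_table`.
#' @return A `connectome` over the merged node set.
#' @export
merge_rois <- function(c, rois, table) {
  stopifnot(inherits(c, "connectome"))
  rois <- lapply(rois, function(r) if (is.character(r)) roi_definition(r) else r)
  members <- unlist(lapply(rois, function(r) r$members))
  if (anyDuplicated(members)) {
    stop("overlapping composite ROIs: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  tab <- table[order(table$id), ]
  # Group assignment per region: merged ROI label (per hemisphere) or itself.
  node <- tab$abbreviation
  for (r in rois) {
    for (h in c("L", "R")) {
      hit <- tab$hemisphere == h & tab$stem %in% r$members
      node[hit] <- paste0(h, "_", r$label)
    }
  }
  new_labels <- unique(node)
  agg <- matrix(0, length(new_labels), length(new_labels),
                dimnames = list(new_labels, new_labels))
  f <- factor(node, levels = new_labels)
  # Sum member-pair counts into merged cells.
  agg <- rowsum(t(rowsum(c$counts[tab$abbreviation, tab$abbreviation],
                         f, reorder = FALSE)), f, reorder = FALSE)
  agg <- as.matrix(agg)
  dimnames(agg) <- list(new_labels, new_labels)
  diag(agg) <- 0  # within-ROI member-to-member counts are dropped
  connectome(agg, animal_id = c$animal_id, group = c$group)
}

#' Chord (connectogram) edge table
#'
#' One row per unordered connected region pair, with the view's weight; the
#' table feeds circular chord-diagram renderers where ribbon widths are to
#' scale with connection strength.
#'
#' @param view A `graph_view`.
#' @return Data frame with columns `from`, `to`, `value` (weight > 0 only).
#' @export
chord_table <- function(view) {
  stopifnot(inherits(view, "graph_view"))
  w <- view$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  labels <- if (is.null(rownames(w))) as.character(seq_len(nrow(w))) else rownames(w)
  data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
             value = w[idx], stringsAsFactors = FALSE)
}
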