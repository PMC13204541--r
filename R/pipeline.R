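# File I/O and the end-to-end pipeline.
#
# The pipeline ties the stages together: simulate (or load) a cohort, write
# per-animal adjacency matrices and chord tables, per-animal network
# metrics for the whole brain and hemisphere views, the edgewise signed-p
# comparisons, region totals, and the built-in circuit comparisons, plus a
# run manifest with the resolved configuration and seeds. Reruns with an
# identical configuration are byte-identical. Missing values are written as
# "NA" in every TSV.

#' Read an animal manifest
#'
#' @param path TSV with columns `animal_id`, `group`, `matrix_path`, and
#'   optionally `diffusivity_path`. Relative paths resolve against the
#'   manifest's directory.
#' @return Data frame; errors on duplicate animal ids or unknown groups.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "matrix_path")
  missing <- setdiff(need, names(man))
  if (length(missing) > 0) {
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(man$animal_id)) stop("duplicate animal ids in manifest")
  if (!all(man$group %in% c("WT", "KO"))) {
    stop("manifest groups must be WT or KO")
  }
  base <- dirname(path)
  man$matrix_path <- ifelse(file.exists(man$matrix_path), man$matrix_path,
                            file.path(base, man$matrix_path))
  man
}

#' Load a cohort from a manifest
#'
#' @param manifest Data frame from [read_manifest()] (or its path).
#' @param table Binding `region_table`.
#' @return A `cohort_study` (without a simulation config).
#' @export
load_cohort <- function(manifest, table = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(table)) table <- load_region_table()
  if (length(unique(manifest$group)) < 2L) {
    stop("manifest must contain both WT and KO animals")
  }
  conns <- lapply(seq_len(nrow(manifest)), function(i) {
    read_count_matrix(manifest$matrix_path[i], table,
                      animal_id = manifest$animal_id[i],
                      group = manifest$group[i])
  })
  structure(list(connectomes = conns, diffusivity = NULL, config = NULL),
            class = "cohort_study")
}

#' Read a circuit definition file
#'
#' YAML-style file with keys `name`, `nodes` (list), `pairs` (list of
#' two-element lists).
#'
#' @param path File path.
#' @return A `circuit_definition`.
#' @export
read_circuit_file <- function(path) {
  def <- yaml::read_yaml(path)
  if (is.null(def$name) || is.null(def$nodes) || is.null(def$pairs)) {
    stop("circuit file needs name, nodes and pairs")
  }
  circuit_definition(def$name, unlist(def$nodes),
                     lapply(def$pairs, unlist))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort from `config` (or loads one from `manifest`), then
#' writes under `out_dir`: per-animal adjacency TSVs and whole-brain chord
#' tables, per-animal network metrics for the whole, ipsilateral and
#' contralateral views, metric group comparisons, edgewise signed-p results
#' and matrices (ipsilateral and contralateral families, adjusted
#' separately), region streamline totals comparison, diffusivity region
#' comparisons (simulated cohorts), built-in circuit comparisons, and
#' `run_manifest.tsv` with the resolved configuration. All randomness flows
#' from the config seed, so identical configuration gives byte-identical
#' output.
#'
#' @param config A [sim_config()] (ignored when `manifest` is given).
#' @param out_dir Output directory.
#' @param manifest Optional manifest path or data frame of real matrices.
#' @param table Binding `region_table`.
#' @param threshold Extraction threshold for weight views.
#' @param n_null,swaps_per_edge Null-model configuration for
#'   small-worldness.
#' @param force Overwrite an existing non-empty output directory?
#' @return Invisibly, a list of the main result objects.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, manifest = NULL,
                         table = NULL, threshold = 0.001, n_null = 50L,
                         swaps_per_edge = 10L, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory ", out_dir,
         " is not empty; use force = TRUE to overwrite")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(table)) table <- load_region_table()

  cohort <- if (is.null(manifest)) {
    simulate_cohort(config, diffusivity = TRUE)
  } else {
    load_cohort(manifest, table)
  }
  seed <- if (is.null(cohort$config)) 1L else cohort$config$seed

  adj_dir <- file.path(out_dir, "adjacency")
  dir.create(adj_dir, showWarnings = FALSE)
  chord_dir <- file.path(out_dir, "chord")
  dir.create(chord_dir, showWarnings = FALSE)

  metric_rows <- list()
  for (conn in cohort$connectomes) {
    write_count_matrix(conn, file.path(adj_dir, paste0(conn$animal_id, ".tsv")))
    whole <- threshold_weights(normalize_weights(conn$counts), threshold)
    utils::write.table(chord_table(whole),
                       file.path(chord_dir, paste0(conn$animal_id, ".csv")),
                       sep = ",", quote = FALSE, row.names = FALSE)
    views <- list(
      whole = whole,
      `ipsilateral-L` = hemisphere_view(conn, table, "ipsilateral-L",
                                        threshold = threshold),
      `ipsilateral-R` = hemisphere_view(conn, table, "ipsilateral-R",
                                        threshold = threshold),
      # Graph measures need a symmetric matrix: both cross-hemisphere
      # orientations of the contralateral block are combined per stem pair.
      contralateral = threshold_weights(
        normalize_weights(contralateral_matrix(conn, table),
                          provenance = "contralateral"),
        threshold))
    for (nm in names(views)) {
      m <- network_metrics(views[[nm]], sigma = TRUE, n_null = n_null,
                           swaps_per_edge = swaps_per_edge, seed = seed)
      m <- cbind(data.frame(animal_id = conn$animal_id, group = conn$group,
                            provenance = nm, stringsAsFactors = FALSE), m)
      metric_rows[[length(metric_rows) + 1L]] <- m
    }
  }
  metrics <- do.call(rbind, metric_rows)
  .write_tsv(metrics, file.path(out_dir, "network_metrics.tsv"))

  param_tests <- do.call(rbind, lapply(split(metrics, metrics$provenance),
    function(sub) cbind(provenance = sub$provenance[1],
                        compare_network_params(sub))))
  .write_tsv(param_tests, file.path(out_dir, "network_param_tests.tsv"))

  results <- list(metrics = metrics, param_tests = param_tests)
  for (mode in c("ipsilateral", "contralateral")) {
    ew <- edgewise_compare(cohort, mode = mode, table = table)
    .write_tsv(ew$edges, file.path(out_dir, paste0("edgewise_", mode, ".tsv")))
    sp <- data.frame(region = rownames(ew$signed_p), ew$signed_p,
                     check.names = FALSE)
    .write_tsv(sp, file.path(out_dir, paste0("signed_p_", mode, ".tsv")))
    results[[paste0("edgewise_", mode)]] <- ew
  }

  regions <- region_streamline_compare(cohort)
  .write_tsv(regions, file.path(out_dir, "region_totals.tsv"))
  results$region_totals <- regions

  if (!is.null(cohort$diffusivity)) {
    diff_rows <- do.call(rbind, lapply(c("FA", "MD", "AD", "RD"), function(s) {
      cbind(scalar = s, compare_regions(cohort$diffusivity, s))
    }))
    .write_tsv(diff_rows, file.path(out_dir, "diffusivity_tests.tsv"))
    results$diffusivity_tests <- diff_rows
  }

  # Built-in circuits need their node stems in the table; a custom
  # parcellation without them simply skips this stage.
  circuit_stems <- unique(unlist(.circuit_nodes))
  if (all(circuit_stems %in% table$stem)) {
    circ_rows <- do.call(rbind, lapply(c("fear", "tle"), function(nm) {
      do.call(rbind, lapply(c("ipsilateral", "contralateral"), function(sd) {
        cbind(circuit = nm, circuit_compare(cohort, nm, side = sd,
                                            table = table))
      }))
    }))
    .write_tsv(circ_rows, file.path(out_dir, "circuit_tests.tsv"))
    results$circuits <- circ_rows
  } else {
    message("built-in circuit nodes absent from the region table; ",
            "skipping circuit comparisons")
  }

  run_info <- data.frame(
    key = c("package_version", "seed", "threshold", "n_null",
            "swaps_per_edge", "n_wt", "n_ko", "n_regions"),
    value = c(as.character(utils::packageVersion("hdbn")), seed, threshold,
              n_null, swaps_per_edge,
              sum(vapply(cohort$connectomes, function(c) c$group,
                         character(1)) == "WT"),
              sum(vapply(cohort$connectomes, function(c) c$group,
                         character(1)) == "KO"),
              nrow(cohort$connectomes[[1]]$counts)))
  .write_tsv(run_info, file.path(out_dir, "run_manifest.tsv"))

  invisible(results)
}
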