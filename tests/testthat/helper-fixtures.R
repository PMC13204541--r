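# Small fixtures built in code.

# A bilateral region table with `half` regions per hemisphere, written to a
# temp TSV and loaded through the package reader.
tiny_region_table <- function(half = 6L) {
  stems <- sprintf("S%02d", seq_len(half))
  df <- data.frame(
    id = 0:(2L * half - 1L),
    abbreviation = c(paste0("L", stems), paste0("R", stems)),
    name = c(paste("left region", seq_len(half)),
             paste("right region", seq_len(half))),
    hemisphere = rep(c("L", "R"), each = half))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressWarnings(load_region_table(path))
}

# Labelled symmetric count matrix for a region table.
labelled_counts <- function(table, fill = 0) {
  abbr <- table$abbreviation[order(table$id)]
  m <- matrix(fill, length(abbr), length(abbr), dimnames = list(abbr, abbr))
  diag(m) <- 0
  m
}

unit_triangle <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w[1, 3] <- w[3, 1] <- w[2, 3] <- w[3, 2] <- 1
  w
}

unit_path3 <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w[2, 3] <- w[3, 2] <- 1
  w
}

unit_star <- function(n) {
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 1
  w
}

unit_complete <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  w
}
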