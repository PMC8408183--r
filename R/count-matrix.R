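#' Barcode count tables
#'
#' Barcode-count trajectories are plain tibbles in wide form: a character
#' `barcode` column followed by one nonnegative integer column per sampled
#' timepoint, named `gen_<G>` with `<G>` the generation label (`gen_0`,
#' `gen_8`, ...). All trajectory functions take and return this shape, so they
#' compose with dplyr verbs and the pipe.
#'
#' `count_generations()` parses the generation grid from the column names,
#' `count_depths()` returns per-timepoint total reads, and
#' `count_frequencies()` converts counts to within-timepoint frequencies.
#'
#' @param counts A barcode-count tibble.
#' @return `count_generations()`: integer vector; `count_depths()`: named
#'   numeric vector; `count_frequencies()`: numeric matrix (barcode x
#'   timepoint) with unit column sums.
#' @name count-tables
NULL

gen_cols <- function(counts) {
  grep("^gen_\\d+$", names(counts), value = TRUE)
}

#' @rdname count-tables
#' @export
count_generations <- function(counts) {
  as.integer(sub("^gen_", "", gen_cols(counts)))
}

#' @rdname count-tables
#' @export
count_depths <- function(counts) {
  cols <- gen_cols(counts)
  vapply(counts[cols], sum, numeric(1))
}

#' @rdname count-tables
#' @export
count_frequencies <- function(counts) {
  m <- as.matrix(counts[gen_cols(counts)])
  rownames(m) <- counts$barcode
  sweep(m, 2, colSums(m), "/")
}

validate_counts <- function(counts, file = NULL) {
  where <- if (is.null(file)) "count table" else paste0("'", file, "'")
  if (!"barcode" %in% names(counts)) {
    stop_lineagedfe(paste0(where, ": missing `barcode` column"),
                    class = "lineagedfe_parse_error")
  }
  cols <- gen_cols(counts)
  if (length(cols) == 0L) {
    stop_lineagedfe(paste0(where, ": no `gen_<G>` count columns found"),
                    class = "lineagedfe_parse_error")
  }
  gens <- as.integer(sub("^gen_", "", cols))
  if (is.unsorted(gens, strictly = TRUE)) {
    stop_lineagedfe(paste0(where, ": generation columns must be strictly increasing"),
                    class = "lineagedfe_parse_error")
  }
  m <- as.matrix(counts[cols])
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_lineagedfe(sprintf("%s: negative count at row %d (barcode '%s', column %s)",
                            where, bad[1, 1], counts$barcode[bad[1, 1]], cols[bad[1, 2]]),
                    class = "lineagedfe_parse_error")
  }
  dup <- counts$barcode[duplicated(counts$barcode)]
  if (length(dup) > 0L) {
    stop_lineagedfe(sprintf("%s: duplicate barcode id '%s'", where, dup[1]),
                    class = "lineagedfe_parse_error")
  }
  invisible(counts)
}

#' Read and write barcode-count tables
#'
#' Counts are stored as TSV with a `barcode` column and `gen_<G>` integer
#' columns. `write_counts()` optionally writes a YAML sidecar
#' (`<path>.yml`) with metadata (replicate, genotype, depths, seed);
#' `read_counts()` restores it as the `"meta"` attribute when present.
#' A round trip `read_counts(write_counts(x, path))` reproduces `x`.
#'
#' @param path File path of the TSV.
#' @param counts Barcode-count tibble.
#' @param meta Optional named list of metadata for the YAML sidecar.
#' @return `read_counts()` returns the validated tibble; `write_counts()`
#'   returns `counts` invisibly.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  counts <- as_tibble(counts)
  if ("barcode" %in% names(counts)) counts$barcode <- as.character(counts$barcode)
  validate_counts(counts, file = path)
  side <- paste0(path, ".yml")
  if (file.exists(side)) {
    attr(counts, "meta") <- yaml::read_yaml(side)
  }
  counts
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path, meta = NULL) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  if (!is.null(meta)) {
    yaml::write_yaml(meta, paste0(path, ".yml"))
  }
  invisible(counts)
}

#' Filter lineage trajectories
#'
#' Applies, in order, the exclusion rules used before fitness inference:
#' timepoints with total depth below `min_timepoint_depth` are dropped
#' (`low_coverage` rule); barcodes with nonzero counts in at most one
#' (replicate, timepoint) combination across the replicate pair are dropped
#' (`single_timepoint` rule); and barcodes with zero reads at generation 0 of
#' a replicate are dropped from that replicate (`zero_at_t0` rule). Each
#' removed barcode is reported once, with the first rule that triggered.
#'
#' @param matrices A list of per-replicate barcode-count tibbles (typically
#'   two). Barcodes are matched across replicates by identifier; a barcode
#'   absent from a replicate is evaluated within the replicates that carry it.
#' @param min_timepoint_depth Minimum total reads for a timepoint to be kept.
#'   The default (1e5) is well below typical per-timepoint depths of ~3e6.
#' @return A list with `matrices` (filtered tibbles, same order),
#'   `excluded_barcodes` (tibble: barcode, replicate, rule) and
#'   `excluded_timepoints` (tibble: replicate, generation, depth).
#' @export
filter_lineages <- function(matrices, min_timepoint_depth = 1e5) {
  if (is.data.frame(matrices)) matrices <- list(matrices)
  purrr::walk(matrices, validate_counts)

  excluded_tp <- tibble(replicate = integer(), generation = integer(), depth = double())
  for (r in seq_along(matrices)) {
    depths <- count_depths(matrices[[r]])
    gens <- count_generations(matrices[[r]])
    low <- depths < min_timepoint_depth
    if (all(low)) {
      stop_lineagedfe("all timepoints fall below `min_timepoint_depth`",
                      class = "lineagedfe_filter_error")
    }
    if (any(low)) {
      excluded_tp <- bind_rows(excluded_tp, tibble(
        replicate = r, generation = gens[low], depth = unname(depths[low])))
      matrices[[r]] <- matrices[[r]][c("barcode", gen_cols(matrices[[r]])[!low])]
    }
  }

  # nonzero (replicate, timepoint) observations per barcode, across replicates
  all_bc <- unique(unlist(lapply(matrices, function(m) m$barcode)))
  nonzero <- setNames(numeric(length(all_bc)), all_bc)
  for (m in matrices) {
    cm <- as.matrix(m[gen_cols(m)])
    nonzero[m$barcode] <- nonzero[m$barcode] + rowSums(cm > 0)
  }
  single_tp <- names(nonzero)[nonzero <= 1]

  excl <- list()
  for (r in seq_along(matrices)) {
    m <- matrices[[r]]
    is_single <- m$barcode %in% single_tp
    zero_t0 <- m[[gen_cols(m)[1]]] == 0 & !is_single
    if (any(is_single)) {
      excl[[length(excl) + 1L]] <- tibble(barcode = m$barcode[is_single],
                                          replicate = r, rule = "single_timepoint")
    }
    if (any(zero_t0)) {
      excl[[length(excl) + 1L]] <- tibble(barcode = m$barcode[zero_t0],
                                          replicate = r, rule = "zero_at_t0")
    }
    matrices[[r]] <- m[!is_single & !zero_t0, , drop = FALSE]
  }

  list(
    matrices = matrices,
    excluded_barcodes = if (length(excl)) bind_rows(excl) else
      tibble(barcode = character(), replicate = integer(), rule = character()),
    excluded_timepoints = excluded_tp
  )
}

# multivariate hypergeometric draw: `target` reads sampled without replacement
# from integer vector `counts`
rmvhyper_counts <- function(counts, target) {
  total <- sum(counts)
  if (target == total) return(counts)
  picks <- sort(sample.int(total, target))
  edges <- cumsum(counts)
  drawn <- findInterval(picks - 1L, c(0, edges), rightmost.closed = FALSE)
  tabulate(drawn, nbins = length(counts))
}

#' Down-sample counts to target depths
#'
#' Reads are subsampled without replacement (multivariate hypergeometric) per
#' timepoint, so a draw at the current depth is the identity and zero entries
#' stay zero. The defaults mirror the depths used to put deeply sequenced
#' first-step evolutions on the footing of the second-step data: 2e7 reads at
#' generation 0 and 3e6 at every later timepoint.
#'
#' @param counts Barcode-count tibble.
#' @param targets Per-timepoint target depths, recycled; each must not exceed
#'   the current depth of its timepoint.
#' @param seed Optional integer seed.
#' @return Down-sampled tibble of identical shape.
#' @export
downsample_counts <- function(counts, targets = c(2e7, rep(3e6, length(gen_cols(counts)) - 1L)),
                              seed = NULL) {
  validate_counts(counts)
  if (!is.null(seed)) withr::local_seed(seed)
  cols <- gen_cols(counts)
  targets <- rep_len(targets, length(cols))
  depths <- count_depths(counts)
  if (any(targets > depths)) {
    bad <- which(targets > depths)[1]
    stop_lineagedfe(sprintf("target depth %g exceeds current depth %g at %s",
                            targets[bad], depths[bad], cols[bad]),
                    class = "lineagedfe_downsample_error")
  }
  out <- counts
  for (j in seq_along(cols)) {
    out[[cols[j]]] <- rmvhyper_counts(counts[[cols[j]]], targets[j])
  }
  out
}
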