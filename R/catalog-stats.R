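#' Filter a variant-call catalog
#'
#' Applies, in order, the false-positive filters used for clone sequencing
#' data. (1) All calls from clones with mean genome-wide coverage below
#' `min_coverage` are dropped. (2) Mitochondrial variants are dropped.
#' (3) Variants in `FLO1`/`FLO9` are dropped (poor alignment in those loci).
#' (4) Variants present in more than `max_clones` clones and in at least
#' `min_backgrounds` of the adapted backgrounds (`cyr1`, `gpb2`, `tor1`) are
#' dropped as ancestral. (5) Variants with quality below `min_quality` that
#' occur in exactly one clone are dropped. Each removed call is attributed to
#' the first rule that triggered; manual alignment-inspection rescues are out
#' of scope.
#'
#' Variants are identified for recurrence purposes by `gene` plus, when
#' present, a `variant_id` column.
#'
#' @param calls Tibble with columns `clone`, `background`, `gene`, `effect`,
#'   `quality`, `coverage`, `chrom` (and optionally `variant_id`).
#' @param min_coverage,min_quality,max_clones,min_backgrounds Rule thresholds
#'   (defaults 10, 150, 5, 2).
#' @param mito_chrom Chromosome label(s) treated as mitochondrial.
#' @param blacklist_genes Genes dropped by rule 3.
#' @return A list: `calls` (surviving rows), `excluded` (tibble with a `rule`
#'   column), `rule_counts` (named exclusion tally in rule order).
#' @export
filter_variants <- function(calls,
                            min_coverage = 10, min_quality = 150,
                            max_clones = 5, min_backgrounds = 2,
                            mito_chrom = c("chrM", "chrMito", "MT"),
                            blacklist_genes = c("FLO1", "FLO9")) {
  req <- c("clone", "background", "gene", "effect", "quality", "coverage", "chrom")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols) > 0L) {
    stop_lineagedfe(paste0("missing required columns: ",
                           paste(missing_cols, collapse = ", ")))
  }
  vid <- if ("variant_id" %in% names(calls)) {
    paste(calls$gene, calls$variant_id)
  } else calls$gene

  adapted <- c("cyr1", "gpb2", "tor1")
  n_clones <- tapply(calls$clone, vid, function(x) length(unique(x)))
  n_bg <- tapply(ifelse(calls$background %in% adapted, calls$background, NA),
                 vid, function(x) length(unique(x[!is.na(x)])))

  rule <- rep(NA_character_, nrow(calls))
  r1 <- calls$coverage < min_coverage
  r2 <- calls$chrom %in% mito_chrom
  r3 <- calls$gene %in% blacklist_genes
  r4 <- n_clones[vid] > max_clones & n_bg[vid] >= min_backgrounds
  r5 <- calls$quality < min_quality & n_clones[vid] == 1
  rule[is.na(rule) & r1] <- "low_coverage_clone"
  rule[is.na(rule) & r2] <- "mitochondrial"
  rule[is.na(rule) & r3] <- "blacklisted_gene"
  rule[is.na(rule) & r4] <- "ancestral_recurrent"
  rule[is.na(rule) & r5] <- "low_quality_singleton"

  excluded <- calls[!is.na(rule), , drop = FALSE]
  excluded$rule <- rule[!is.na(rule)]
  rules <- c("low_coverage_clone", "mitochondrial", "blacklisted_gene",
             "ancestral_recurrent", "low_quality_singleton")
  counts <- vapply(rules, function(r) sum(excluded$rule == r, na.rm = TRUE),
                   integer(1))
  list(calls = calls[is.na(rule), , drop = FALSE],
       excluded = as_tibble(excluded),
       rule_counts = counts)
}

#' Multi-hit gene tallies and cross-background overlaps
#'
#' Counts calls per (gene, background) — a gene hit independently in several
#' adapted clones is evidence of selection — and reports the genes and
#' pathways shared between each pair of backgrounds.
#'
#' @param calls Mutation-call tibble with `gene`, `background` and optionally
#'   `pathway` columns.
#' @return A list: `table` (tibble gene x background counts, wide),
#'   `gene_overlaps` and `pathway_overlaps` (tibbles: pair, shared).
#' @export
multi_hit_table <- function(calls) {
  if (nrow(calls) == 0L) {
    return(list(table = tibble(gene = character()),
                gene_overlaps = tibble(pair = character(), shared = list()),
                pathway_overlaps = tibble(pair = character(), shared = list())))
  }
  tab <- calls |>
    count(.data$gene, .data$background) |>
    tidyr::pivot_wider(names_from = "background", values_from = "n",
                       values_fill = 0L) |>
    arrange(.data$gene)

  overlaps <- function(col) {
    sets <- split(calls[[col]], calls$background)
    sets <- lapply(sets, unique)
    bgs <- names(sets)
    if (length(bgs) < 2) {
      return(tibble(pair = character(), shared = list()))
    }
    pairs <- utils::combn(bgs, 2, simplify = FALSE)
    tibble(
      pair = vapply(pairs, paste, character(1), collapse = ":"),
      shared = lapply(pairs, function(p) sort(intersect(sets[[p[1]]], sets[[p[2]]])))
    )
  }
  list(table = tab,
       gene_overlaps = overlaps("gene"),
       pathway_overlaps = if ("pathway" %in% names(calls)) overlaps("pathway")
                          else tibble(pair = character(), shared = list()))
}

#' Loss-of-function contingency between adaptation steps
#'
#' Builds the 2x2 table of mutation step (first vs second) against mutation
#' class (disruptive — nonsense or frameshift, i.e. loss of function — vs
#' other) and tests for a difference in proportions with a chi-square test,
#' by default with Yates' continuity correction. On the observed causative
#' counts (53/95 disruptive first-step vs 14/55 second-step) the corrected
#' test gives p ~ 6e-4.
#'
#' @param catalog Mutation-call tibble with `step` (`"first"`/`"second"`) and
#'   `effect` columns.
#' @param lof_effects Effects counted as loss of function.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return A list: `table` (2x2 matrix, rows first/second, columns LOF/other),
#'   `statistic`, `p_value`, `fisher_p` (exact-test cross-check).
#' @export
lof_contingency <- function(catalog, lof_effects = c("nonsense", "frameshift"),
                            correct = TRUE) {
  tab <- lof_contingency_table(
    n_lof_first = sum(catalog$step == "first" & catalog$effect %in% lof_effects),
    n_other_first = sum(catalog$step == "first" & !catalog$effect %in% lof_effects),
    n_lof_second = sum(catalog$step == "second" & catalog$effect %in% lof_effects),
    n_other_second = sum(catalog$step == "second" & !catalog$effect %in% lof_effects),
    correct = correct)
  tab
}

#' @rdname lof_contingency
#' @param n_lof_first,n_other_first,n_lof_second,n_other_second Cell counts,
#'   for testing a printed table directly.
#' @export
lof_contingency_table <- function(n_lof_first, n_other_first,
                                  n_lof_second, n_other_second,
                                  correct = TRUE) {
  tab <- matrix(c(n_lof_first, n_other_first, n_lof_second, n_other_second),
                nrow = 2, byrow = TRUE,
                dimnames = list(step = c("first", "second"),
                                class = c("lof", "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_lineagedfe("contingency table has an empty margin",
                    class = "lineagedfe_stats_error")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(table = tab,
       statistic = unname(ct$statistic),
       p_value = ct$p.value,
       fisher_p = fisher.test(tab)$p.value)
}

#' Additive expectation for double-mutant fitness
#'
#' Under additivity of selection coefficients (log fitness), the expected
#' fitness of a double mutant is the sum of the mean single-mutant fitness of
#' the two genes, with a normal confidence interval propagated from the two
#' standard errors of the means (`sem = sd/sqrt(n)`, zero for a single
#' value). The observed double-mutant mean is called `negative` below the
#' interval, `positive` above it, and `additive_consistent` inside.
#'
#' @param fitness_gene_a,fitness_gene_b Single-mutant fitness values (per
#'   generation) for each gene.
#' @param doubles Fitness values of genotypes carrying both mutations
#'   (optional; without them the expectation is still returned).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `expected`, `ci_lo`, `ci_hi`, `observed_mean`,
#'   `verdict` (`NA` when `doubles` is empty).
#' @export
additive_expectation <- function(fitness_gene_a, fitness_gene_b,
                                 doubles = numeric(0), conf_level = 0.95) {
  if (length(fitness_gene_a) < 1 || length(fitness_gene_b) < 1) {
    stop_lineagedfe("need at least one fitness value per gene")
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  expected <- mean(fitness_gene_a) + mean(fitness_gene_b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(sem(fitness_gene_a)^2 + sem(fitness_gene_b)^2)
  obs <- if (length(doubles)) mean(doubles) else NA_real_
  verdict <- if (is.na(obs)) NA_character_
    else if (obs < expected - half) "negative"
    else if (obs > expected + half) "positive"
    else "additive_consistent"
  tibble(expected = expected, ci_lo = expected - half, ci_hi = expected + half,
         observed_mean = obs, verdict = verdict)
}

#' Correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] returning a tidy one-row tibble;
#' Spearman p-values for small samples (n <= 8, no ties) use the exact
#' permutation distribution.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble `estimate`, `p_value`, `method`, `n`.
#' @export
correlate_values <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    stop_lineagedfe("`x` and `y` must have equal length >= 3")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method,
                                  exact = if (method == "spearman") length(x) <= 8 else NULL))
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         method = method, n = length(x))
}
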