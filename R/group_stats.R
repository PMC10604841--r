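# Gated statistical pipeline: Shapiro-Wilk normality gate, Student's t or
# Mann-Whitney U for two-group comparisons, repeated-measures ANOVA with
# Bonferroni post hoc or Friedman for within-genotype quartile blocks.

#' Normality gate (Shapiro-Wilk)
#'
#' @param values numeric vector, 3 to 5000 finite values.
#' @param alpha significance level of the gate; `p >= alpha` is declared
#'   normal.
#' @return list with `is_normal`, `p` (`NA` for a degenerate input), and
#'   `degenerate` (`TRUE` for a constant vector, on which the test is
#'   undefined; treated as non-normal).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("normality gate requires 3 <= n <= 5000")
  if (diff(range(values)) == 0)
    return(list(is_normal = FALSE, p = NA_real_, degenerate = TRUE))
  p <- shapiro.test(values)$p.value
  list(is_normal = p >= alpha, p = p, degenerate = FALSE)
}

#' Gated two-group comparison (Student's t vs Mann-Whitney U)
#'
#' Both groups pass the Shapiro-Wilk gate: two-sample Student's t test
#' (classical equal-variance form by default; Welch selectable).
#' Otherwise: Mann-Whitney U (Wilcoxon rank-sum; exact for small
#' tie-free samples, normal approximation with continuity correction
#' otherwise). Two-sided throughout.
#'
#' @param a,b numeric vectors, at least 3 values each.
#' @param welch use the Welch (unequal-variance) t statistic when the
#'   parametric branch is taken.
#' @param alpha_norm significance level of the normality gate.
#' @return object of class `group_comparison`: list with `test_used`
#'   (`"student_t"` or `"mann_whitney"`), `statistic`, `p_value`,
#'   `normality_p` (per group), `degenerate` flags, `effect`
#'   (`mean(b) - mean(a)`), `n` per group.
#' @export
compare_groups <- function(a, b, welch = FALSE, alpha_norm = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 values per group")
  ga <- normality_gate(a, alpha = alpha_norm)
  gb <- normality_gate(b, alpha = alpha_norm)
  if (ga$is_normal && gb$is_normal) {
    ht <- t.test(a, b, var.equal = !welch)
    test_used <- "student_t"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    test_used <- "mann_whitney"
  }
  structure(
    list(test_used = test_used,
         statistic = unname(ht$statistic),
         p_value = ht$p.value,
         normality_p = c(a = ga$p, b = gb$p),
         degenerate = c(a = ga$degenerate, b = gb$degenerate),
         effect = mean(b) - mean(a),
         n = c(a = length(a), b = length(b))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test_used,
      sprintf(": statistic = %.4g, p = %.4g, effect (b - a) = %.4g\n",
              x$statistic, x$p_value, x$effect), sep = "")
  invisible(x)
}

#' Within-genotype quartile block test
#'
#' Compares the four quartile columns measured on the same subjects. When
#' every column passes the Shapiro-Wilk gate, a repeated-measures one-way
#' ANOVA (subject as a blocking factor) with Bonferroni-adjusted pairwise
#' paired t tests is used; otherwise the Friedman test with
#' Bonferroni-adjusted pairwise paired Wilcoxon signed-rank tests.
#' A plain (non-repeated) one-way variant is available for designs where
#' rows are not the same subjects.
#'
#' @param block numeric matrix or data.frame, subjects in rows and exactly
#'   4 quartile columns (Q1-Q4), no missing cells, at least 3 subjects.
#' @param repeated treat rows as repeated measures (default). With
#'   `repeated = FALSE` the parametric branch is a plain one-way ANOVA
#'   with unpaired pairwise t tests, the nonparametric branch
#'   Kruskal-Wallis with unpaired Wilcoxon pairs.
#' @param alpha_norm significance level of the per-column normality gate.
#' @return object of class `quartile_block_result`: list with `test_used`,
#'   `statistic`, `p_value` (omnibus), `pairwise` (data.frame of the 6
#'   pairs with raw and Bonferroni-adjusted p values,
#'   `p_adj = min(1, 6 p)`), `normality_p` per column.
#' @export
quartile_block_test <- function(block, repeated = TRUE, alpha_norm = 0.05) {
  block <- as.matrix(block)
  if (ncol(block) != 4L) stop("block must have exactly 4 quartile columns")
  if (nrow(block) < 3L) stop("need at least 3 subjects")
  if (any(!is.finite(block))) stop("missing or non-finite cells in block")
  if (is.null(colnames(block))) colnames(block) <- paste0("Q", 1:4)

  gates <- apply(block, 2, normality_gate, alpha = alpha_norm)
  norm_p <- vapply(gates, `[[`, numeric(1), "p")
  all_normal <- all(vapply(gates, `[[`, logical(1), "is_normal"))

  pairs <- utils::combn(colnames(block), 2)
  n_pairs <- ncol(pairs)

  if (all_normal) {
    long <- data.frame(
      value = as.vector(block),
      quartile = factor(rep(colnames(block), each = nrow(block))),
      subject = factor(rep(seq_len(nrow(block)), times = ncol(block))))
    if (repeated) {
      fit <- lm(value ~ quartile + subject, data = long)
      test_used <- "rm_anova_bonferroni"
    } else {
      fit <- lm(value ~ quartile, data = long)
      test_used <- "oneway_anova_bonferroni"
    }
    an <- anova(fit)
    statistic <- an["quartile", "F value"]
    p_value <- an["quartile", "Pr(>F)"]
    p_raw <- vapply(seq_len(n_pairs), function(i)
      t.test(block[, pairs[1, i]], block[, pairs[2, i]],
             paired = repeated, var.equal = !repeated)$p.value,
      numeric(1))
  } else {
    if (repeated) {
      ht <- friedman.test(block)
      test_used <- "friedman"
    } else {
      ht <- kruskal.test(split(as.vector(block),
                               rep(colnames(block), each = nrow(block))))
      test_used <- "kruskal"
    }
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
    p_raw <- vapply(seq_len(n_pairs), function(i)
      suppressWarnings(
        wilcox.test(block[, pairs[1, i]], block[, pairs[2, i]],
                    paired = repeated, exact = FALSE))$p.value,
      numeric(1))
  }

  structure(
    list(test_used = test_used, statistic = statistic, p_value = p_value,
         pairwise = data.frame(
           pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
           p_raw = p_raw,
           p_adj = pmin(1, n_pairs * p_raw)),
         normality_p = norm_p,
         n_subjects = nrow(block)),
    class = "quartile_block_result")
}

#' @export
print.quartile_block_result <- function(x, ...) {
  cat("<quartile_block_result> ", x$test_used,
      sprintf(": omnibus statistic = %.4g, p = %.4g (n = %d)\n",
              x$statistic, x$p_value, x$n_subjects), sep = "")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Run the full genotype comparison over a study's endpoints
#'
#' Orchestrates the gated comparisons for a whole study: one
#' [compare_groups()] per scalar endpoint, one per (modality, ROI,
#' quartile) cell of the quartile table, and one [quartile_block_test()]
#' per (genotype, modality, ROI). No correction is applied across
#' endpoints; Bonferroni adjustment applies only to the within-block
#' pairwise comparisons.
#'
#' @param endpoints data.frame with columns `animal_id`, `genotype`
#'   (`"wt"` / `"trj"`), `endpoint`, `value` (long format, e.g. from
#'   [generate_behavior_table()]); may be `NULL` or empty.
#' @param quartile_values optional data.frame with columns `animal_id`,
#'   `genotype`, `modality`, `roi`, `quartile`, `value`.
#' @param alpha significance level recorded in the report.
#' @param welch,repeated,alpha_norm test variants, passed to
#'   [compare_groups()] and [quartile_block_test()].
#' @return object of class `study_comparison`: list of data.frames
#'   `endpoint_report`, `quartile_report`, `block_report`.
#' @export
run_full_comparison <- function(endpoints = NULL, quartile_values = NULL,
                                alpha = 0.05, welch = FALSE, repeated = TRUE,
                                alpha_norm = 0.05) {
  empty_ep <- data.frame(endpoint = character(0), test_used = character(0),
                         statistic = numeric(0), p_value = numeric(0),
                         effect = numeric(0), significant = logical(0),
                         n_wt = integer(0), n_trj = integer(0))
  endpoint_report <- empty_ep
  if (!is.null(endpoints) && nrow(endpoints) > 0) {
    stopifnot(all(c("animal_id", "genotype", "endpoint", "value") %in%
                    names(endpoints)))
    if (anyDuplicated(endpoints[, c("animal_id", "endpoint")]))
      stop("duplicated (animal_id, endpoint) rows")
    endpoint_report <- do.call(rbind, lapply(
      unique(endpoints$endpoint), function(e) {
        d <- endpoints[endpoints$endpoint == e, ]
        r <- compare_groups(d$value[d$genotype == "wt"],
                            d$value[d$genotype == "trj"],
                            welch = welch, alpha_norm = alpha_norm)
        data.frame(endpoint = e, test_used = r$test_used,
                   statistic = r$statistic, p_value = r$p_value,
                   effect = r$effect, significant = r$p_value < alpha,
                   n_wt = r$n["a"], n_trj = r$n["b"],
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
  }

  empty_q <- data.frame(modality = character(0), roi = character(0),
                        quartile = character(0), test_used = character(0),
                        statistic = numeric(0), p_value = numeric(0),
                        effect = numeric(0), significant = logical(0))
  quartile_report <- empty_q
  block_report <- data.frame(genotype = character(0), modality = character(0),
                             roi = character(0), test_used = character(0),
                             statistic = numeric(0), p_value = numeric(0))
  if (!is.null(quartile_values) && nrow(quartile_values) > 0) {
    stopifnot(all(c("animal_id", "genotype", "modality", "roi", "quartile",
                    "value") %in% names(quartile_values)))
    key <- quartile_values[, c("animal_id", "modality", "roi", "quartile")]
    if (anyDuplicated(key))
      stop("duplicated (animal_id, modality, roi, quartile) rows")
    cells <- unique(quartile_values[, c("modality", "roi", "quartile")])
    quartile_report <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      cl <- cells[i, ]
      d <- quartile_values[quartile_values$modality == cl$modality &
                             quartile_values$roi == cl$roi &
                             quartile_values$quartile == cl$quartile, ]
      r <- compare_groups(d$value[d$genotype == "wt"],
                          d$value[d$genotype == "trj"],
                          welch = welch, alpha_norm = alpha_norm)
      data.frame(modality = cl$modality, roi = cl$roi, quartile = cl$quartile,
                 test_used = r$test_used, statistic = r$statistic,
                 p_value = r$p_value, effect = r$effect,
                 significant = r$p_value < alpha,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    groups <- unique(quartile_values[, c("genotype", "modality", "roi")])
    block_report <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      gr <- groups[i, ]
      d <- quartile_values[quartile_values$genotype == gr$genotype &
                             quartile_values$modality == gr$modality &
                             quartile_values$roi == gr$roi, ]
      wide <- reshape_block(d)
      r <- quartile_block_test(wide, repeated = repeated, alpha_norm = alpha_norm)
      data.frame(genotype = gr$genotype, modality = gr$modality,
                 roi = gr$roi, test_used = r$test_used,
                 statistic = r$statistic, p_value = r$p_value,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }

  structure(list(endpoint_report = endpoint_report,
                 quartile_report = quartile_report,
                 block_report = block_report, alpha = alpha),
            class = "study_comparison")
}

# animals x quartiles matrix from a long per-quartile data.frame
reshape_block <- function(d) {
  ids <- unique(d$animal_id)
  qs <- paste0("Q", 1:4)
  m <- matrix(NA_real_, length(ids), 4L, dimnames = list(ids, qs))
  for (i in seq_len(nrow(d)))
    m[d$animal_id[i], d$quartile[i]] <- d$value[i]
  m
}

#' @export
print.study_comparison <- function(x, ...) {
  cat("<study_comparison> alpha =", x$alpha, "\n")
  if (nrow(x$endpoint_report)) {
    cat("\nEndpoints:\n")
    print(x$endpoint_report, row.names = FALSE, digits = 4)
  }
  if (nrow(x$quartile_report)) {
    cat("\nGenotype comparison per quartile:\n")
    print(x$quartile_report, row.names = FALSE, digits = 4)
  }
  if (nrow(x$block_report)) {
    cat("\nWithin-genotype quartile blocks:\n")
    print(x$block_report, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
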