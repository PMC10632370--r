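# External-validation statistics: gene-set enrichment by consensus-score
# bin, constraint-score group comparisons, drug-target analyses, and
# multiple-testing correction.

#' Gene-set annotation
#'
#' A membership set (e.g. genes whose mouse knockouts show a relevant
#' phenotype, differentially expressed genes, drug targets) within a
#' background set; membership is harmonized to the background.
#'
#' @param membership integer positions (or identifiers) of member genes.
#' @param background integer positions of the background universe.
#' @param name annotation label.
#' @return object of class `geneset_annotation`.
#' @export
geneset_annotation <- function(membership, background, name = "annotation") {
  membership <- unique(membership)
  background <- unique(background)
  membership <- intersect(membership, background)
  structure(list(membership = membership, background = background, name = name),
            class = "geneset_annotation")
}

#' Fisher's exact enrichment of a gene set
#'
#' Removes `exclusions` (e.g. known positive labels) from both the test
#' set and the background, builds the 2x2 table of membership x test-set
#' status, and reports the sample (cross-product) odds ratio with Haldane
#' 0.5 correction when any cell is empty, plus the two-sided exact p-value
#' from the conditional (hypergeometric) distribution.
#'
#' @param test_set integer positions of the test genes.
#' @param annotation a [geneset_annotation()].
#' @param exclusions gene positions removed before testing.
#' @return one-row data.frame (class `enrichment_result`): a, b, c, d,
#'   odds_ratio, p, corrected (Haldane flag).
#' @export
fisher_enrichment <- function(test_set, annotation, exclusions = integer(0)) {
  stopifnot(inherits(annotation, "geneset_annotation"))
  bg <- setdiff(annotation$background, exclusions)
  test <- intersect(setdiff(test_set, exclusions), bg)
  if (length(test) == 0L) stop("test set is empty after exclusions")
  mem <- intersect(annotation$membership, bg)
  a <- length(intersect(test, mem))
  b <- length(test) - a
  c_ <- length(mem) - a
  d <- length(bg) - a - b - c_
  corrected <- any(c(a, b, c_, d) == 0L)
  h <- if (corrected) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
  out <- data.frame(a = a, b = b, c = c_, d = d, odds_ratio = or, p = p,
                    corrected = corrected)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment by consensus-score bin
#'
#' For each bin `k = 1..m`, tests the genes with `CS >= k` for annotation
#' enrichment against the non-positive genes with `CS < k` (cumulative
#' bins; at `k = m` the test set is exactly the top bin). Known positives
#' are excluded throughout; p-values are Benjamini-Hochberg corrected
#' across the m bins.
#'
#' @param consensus a `consensus_result` (see [consensus_score()]) or an
#'   integer CS vector with `NA` at known positives.
#' @param annotation a [geneset_annotation()].
#' @param known_positives positions of known positives (only needed when
#'   `consensus` is a bare vector).
#' @param fdr_level significance flag cutoff (default 0.05).
#' @return data.frame: bin, counts, odds_ratio, p, fdr, significant.
#' @export
enrichment_by_cs_bin <- function(consensus, annotation, known_positives = integer(0),
                                 fdr_level = 0.05) {
  if (inherits(consensus, "consensus_result")) {
    cs <- consensus$cs
    m <- consensus$m
    known_positives <- which(consensus$flag == "positive-label")
  } else {
    cs <- consensus
    m <- max(cs, na.rm = TRUE)
    if (m < 1L) stop("no candidate has CS >= 1; nothing to test")
  }
  rows <- NULL
  for (k in seq_len(m)) {
    test <- setdiff(which(!is.na(cs) & cs >= k), known_positives)
    lower <- setdiff(which(!is.na(cs) & cs < k), known_positives)
    if (length(test) == 0L) {
      rows <- rbind(rows, data.frame(bin = k, a = NA, b = NA, c = NA, d = NA,
                                     odds_ratio = NA, p = NA, corrected = NA))
      next
    }
    ann <- geneset_annotation(annotation$membership, c(test, lower), annotation$name)
    e <- fisher_enrichment(test, ann)
    rows <- rbind(rows, cbind(bin = k, as.data.frame(e)))
  }
  rows$fdr <- adjust_fdr(rows$p)
  rows$significant <- !is.na(rows$fdr) & rows$fdr < fdr_level
  rows
}

#' Tukey HSD comparison of score distributions across gene groups
#'
#' All pairwise group-mean comparisons of a per-gene score (e.g.
#' loss-of-function or missense intolerance Z) with studentized-range
#' adjustment and simultaneous confidence intervals.
#'
#' @param values numeric per-gene scores.
#' @param grouping factor of the same length (e.g. positives / candidates /
#'   non-candidates).
#' @param conf_level simultaneous confidence level (default 0.95).
#' @return data.frame: comparison, diff, lwr, upr, p_adj, plus attribute
#'   `group_means`.
#' @export
tukey_groups <- function(values, grouping, conf_level = 0.95) {
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) < 2L) stop("need >= 2 groups")
  if (any(table(grouping) < 2L)) stop("every group needs >= 2 values")
  fit <- stats::aov(values ~ grouping)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$grouping
  out <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
                    row.names = NULL)
  attr(out, "group_means") <- tapply(values, grouping, mean)
  out
}

#' Rank-sum comparison of drug-targeting degrees
#'
#' Pairwise Wilcoxon rank-sum tests of per-gene drug-interaction counts
#' between groups, restricted to genes with at least one interaction.
#' Reports the fold increase of the median count relative to the
#' reference group (xDC) and Benjamini-Hochberg corrected p-values.
#'
#' @param counts numeric per-gene drug-interaction counts.
#' @param grouping factor of gene groups.
#' @param reference reference group for the median ratio (default
#'   `"non-candidate"` if present, else the last level).
#' @return data.frame: group1, group2, median1, median2, xdc, p, fdr;
#'   groups with no eligible gene are skipped with a warning.
#' @export
drug_degree_ranksum <- function(counts, grouping, reference = NULL) {
  grouping <- droplevels(as.factor(grouping))
  lv0 <- levels(grouping)
  keep <- !is.na(counts) & counts >= 1
  counts <- counts[keep]; grouping <- droplevels(grouping[keep])
  lv <- levels(grouping)
  if (length(setdiff(lv0, lv)) > 0L) {
    warning("group(s) without eligible genes skipped: ", paste(setdiff(lv0, lv), collapse = ", "))
  }
  if (length(lv) < 2L) stop("fewer than two groups have genes with drug interactions")
  if (is.null(reference)) reference <- if ("non-candidate" %in% lv) "non-candidate" else lv[length(lv)]
  pairs <- utils::combn(lv, 2L)
  rows <- NULL
  for (q in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, q]; g2 <- pairs[2L, q]
    x1 <- counts[grouping == g1]; x2 <- counts[grouping == g2]
    p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
    rows <- rbind(rows, data.frame(group1 = g1, group2 = g2,
                                   median1 = stats::median(x1), median2 = stats::median(x2),
                                   xdc = stats::median(x1) / stats::median(x2), p = p))
  }
  rows$fdr <- adjust_fdr(rows$p)
  attr(rows, "reference") <- reference
  rows
}

#' Druggability enrichment excluding current drug targets
#'
#' Removes genes already targeted by a drug from both the test set and the
#' background, then tests the remaining genes for enrichment of druggable
#' proteins (the untargeted-but-druggable analysis).
#'
#' @param druggable positions of genes encoding druggable proteins.
#' @param targets positions of current drug-target genes.
#' @param test_set positions of the candidate set.
#' @param background positions of the background universe.
#' @return an `enrichment_result` row, see [fisher_enrichment()].
#' @export
druggable_excluding_targets <- function(druggable, targets, test_set, background) {
  ann <- geneset_annotation(druggable, setdiff(background, targets), "druggable")
  fisher_enrichment(setdiff(test_set, targets), ann)
}

#' Two-proportion z-test
#'
#' Pooled-variance z statistic for comparing two validation rates, e.g.
#' a candidate set's knockout-phenotype rate against the known-positive
#' benchmark.
#'
#' @param k1,n1 successes and trials of the first group.
#' @param k2,n2 successes and trials of the second group.
#' @return list with `z`, `p` (two-sided) and the two proportions.
#' @export
compare_rates_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("both groups need trials > 0")
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment across a family of p-values; `NA`s are preserved.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @return adjusted values, capped at 1.
#' @export
adjust_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}
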