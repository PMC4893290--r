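# Concordance statistics. Cohen's kappa corrects observed agreement for
# chance agreement under marginal independence:
#   kappa = (p_o - p_e) / (1 - p_e),
# with p_o the fraction of concordant samples and p_e the chance agreement
# from the table margins. When p_e = 1 (both assignments constant and equal)
# kappa is undefined; such results are flagged degenerate and excluded (but
# counted) by the aggregation step.

#' Qualitative agreement band for a kappa value
#'
#' Maps kappa to the conventional qualitative bands: 0-0.2 slight, 0.21-0.4
#' fair, 0.41-0.6 moderate, 0.61-0.8 substantial, 0.81-1 almost perfect.
#' Interval endpoints belong to the lower band (kappa = 0.4 is fair);
#' negative kappa is slight.
#'
#' @param kappa numeric kappa value(s).
#' @return Character vector of bands.
#' @export
#' @examples
#' kappaBand(c(0.467, 0.85))
kappaBand <- function(kappa) {
  cut(kappa, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("slight", "fair", "moderate", "substantial",
                 "almost_perfect"),
      right = TRUE) |> as.character()
}

.kappaFromTable <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4)
    return(list(kappa = NA_real_, cc = 100 * po, degenerate = TRUE))
  list(kappa = (po - pe) / (1 - pe), cc = 100 * po, degenerate = FALSE)
}

.alignAssignments <- function(a, b) {
  if (!setequal(sampleIds(a), sampleIds(b))) {
    d <- union(setdiff(sampleIds(a), sampleIds(b)),
               setdiff(sampleIds(b), sampleIds(a)))
    stop("assignments cover different samples; symmetric difference: ",
         paste(head(d, 10L), collapse = ", "),
         if (length(d) > 10L) ", ...")
  }
  idx <- match(sampleIds(a), sampleIds(b))
  list(la = subtypes(a), lb = subtypes(b)[idx])
}

#' Cohen's kappa between two subtype assignments
#'
#' Builds the contingency table over the canonical subtype order
#' (zero-padded, square), computes the percentage of concordant samples,
#' overall kappa with its qualitative band, and the subtype-specific
#' (one-vs-rest) kappa for every subtype.
#'
#' @param a,b [SubtypeAssignment-class] objects over the same samples.
#' @return A [KappaResult-class].
#' @export
cohensKappa <- function(a, b) {
  al <- .alignAssignments(a, b)
  n <- length(al$la)
  if (n < 1L) stop("at least one sample required")
  tab <- table(al$la, al$lb)
  tab <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  k <- .kappaFromTable(tab)
  per <- vapply(subtypeLevels(), function(s)
    .binaryKappa(al$la, al$lb, s)$kappa, numeric(1))
  new("KappaResult", table = tab, kappa = k$kappa, cc = k$cc,
      perSubtypeKappa = per,
      band = if (k$degenerate) NA_character_ else kappaBand(k$kappa),
      n = as.integer(n), degenerate = k$degenerate)
}

.binaryKappa <- function(la, lb, s) {
  fa <- factor(la == s, levels = c(FALSE, TRUE))
  fb <- factor(lb == s, levels = c(FALSE, TRUE))
  .kappaFromTable(table(fa, fb))
}

#' Subtype-specific kappa
#'
#' Binarizes both assignments to `s` vs not-`s` and returns the kappa of the
#' resulting 2 x 2 table. `NA` when the binarized table is degenerate (e.g.
#' the subtype is absent from both assignments).
#'
#' @param a,b [SubtypeAssignment-class] objects over the same samples.
#' @param s a subtype label from [subtypeLevels()].
#' @return Numeric kappa (possibly `NA`).
#' @export
subtypeKappa <- function(a, b, s) {
  s <- match.arg(s, subtypeLevels())
  al <- .alignAssignments(a, b)
  .binaryKappa(al$la, al$lb, s)$kappa
}

.comparisonGroup <- function(typeA, typeB, glA, glB, csA, csB) {
  ifelse(typeA != typeB, "inter_type",
    ifelse(glA != glB & csA != csB, "both_differ",
      ifelse(glA != glB, "gene_list_differs",
        ifelse(csA != csB, "cs_differs", "identical"))))
}

#' Aggregate concordance results over a comparison design
#'
#' Partitions pairwise predictor comparisons into the groups
#' `both_differ` (gene list and consensus set both change),
#' `gene_list_differs`, `cs_differs` and `inter_type` (different predictor
#' types), and summarizes kappa and the concordant percentage per group
#' (and per subtype) by median, min and max. Comparisons whose validation
#' dataset equals either predictor's training set are excluded, as are
#' degenerate kappa results; both exclusions are counted.
#'
#' @param designs data.frame with one row per comparison and columns
#'   `type_a`, `type_b`, `gene_list_a`, `gene_list_b`, `cs_a`, `cs_b`,
#'   `validation_dataset`.
#' @param results list of [KappaResult-class] objects, parallel to the rows
#'   of `designs`.
#' @return A list with `summary` (data.frame: group, subtype, n, median, min,
#'   max of kappa and cc), `n_excluded_overlap` and `n_excluded_degenerate`.
#' @export
aggregateConcordance <- function(designs, results) {
  stopifnot(nrow(designs) == length(results), nrow(designs) > 0L)
  overlap <- designs$validation_dataset == designs$cs_a |
    designs$validation_dataset == designs$cs_b
  degen <- vapply(results, isDegenerate, logical(1))
  keep <- !overlap & !degen
  if (!any(keep))
    stop("all comparisons excluded (training/validation overlap or degenerate)")
  group <- .comparisonGroup(designs$type_a, designs$type_b,
                            designs$gene_list_a, designs$gene_list_b,
                            designs$cs_a, designs$cs_b)
  kap <- vapply(results, kappaValue, numeric(1))
  cc <- vapply(results, concordantPercent, numeric(1))
  per <- t(vapply(results, perSubtypeKappa, numeric(4)))
  rows <- list()
  for (g in unique(group[keep])) {
    sel <- keep & group == g
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, subtype = "ALL", n = sum(sel),
      median_kappa = median(kap[sel]), min_kappa = min(kap[sel]),
      max_kappa = max(kap[sel]), median_cc = median(cc[sel]),
      min_cc = min(cc[sel]), max_cc = max(cc[sel]))
    for (s in subtypeLevels()) {
      v <- per[sel, s]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, subtype = s, n = length(v),
        median_kappa = median(v), min_kappa = min(v), max_kappa = max(v),
        median_cc = NA_real_, min_cc = NA_real_, max_cc = NA_real_)
    }
  }
  list(summary = do.call(rbind, rows),
       n_excluded_overlap = sum(overlap),
       n_excluded_degenerate = sum(degen & !overlap))
}
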