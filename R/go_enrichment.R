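#' Define test and background protein sets for enrichment
#'
#' Background: all phosphoproteins (every protein carrying at least one
#' site in `sites`). Test: the subset whose sites qualify under the Met
#' filter — either any site with a Met in the flanking window
#' (`met_filter = "any_met_in_window"`) or, when conservation records
#' are supplied, any site whose Met reaches a conservation level of at
#' least `min_level` (`met_filter = "conservation"`). Proteins are
#' deduplicated: many qualifying sites still count once.
#'
#' @param sites Validated site data frame.
#' @param proteome A [proteome].
#' @param met_filter `"any_met_in_window"` or `"conservation"`.
#' @param half_width,discount_nterm Window parameters, as elsewhere.
#' @param conservation_records [conservation_table()] output (needed
#'   for the conservation filter).
#' @param min_level Minimum conservation level for the filter.
#' @return List with character vectors `test` and `background`
#'   (`test` is always a subset of `background`).
#' @export
define_sets <- function(sites, proteome,
                        met_filter = c("any_met_in_window", "conservation"),
                        half_width = 6L, discount_nterm = TRUE,
                        conservation_records = NULL, min_level = 6L) {
  met_filter <- match.arg(met_filter)
  background <- unique(sites$protein_id)
  if (length(background) == 0L) stop("empty background: no phosphoproteins")
  if (met_filter == "any_met_in_window") {
    hm <- sites_with_met(proteome, sites, half_width, discount_nterm)
    test <- unique(sites$protein_id[hm])
  } else {
    if (is.null(conservation_records))
      stop("conservation filter requires conservation_records")
    keep <- conservation_records$level >= min_level
    prot <- sub(":[0-9]+$", "", conservation_records$family_id[keep])
    test <- unique(prot[prot %in% background])
    if (length(test) == 0L)
      warning("no proteins reach conservation level ", min_level,
              "; test set is empty")
  }
  list(test = test, background = background)
}

#' Hypergeometric GO-term enrichment with Bonferroni correction
#'
#' For each term annotated to at least one test-set protein: the exact
#' upper-tail hypergeometric p-value of observing that many annotated
#' proteins in a test set of size n drawn from the background of size
#' N, Bonferroni-corrected over the number of terms tested (all
#' namespaces jointly), plus the log2 ratio of test to background term
#' proportion and a two-proportion z-score. Annotations are used as
#' given (no ontology-graph propagation).
#'
#' @param test,background Character vectors of protein ids
#'   (`test` must be a subset of `background`).
#' @param annotations Data frame `protein_id`, `term_id`, `namespace`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m_mode Bonferroni denominator: `"tested"` (terms with at
#'   least one test-set protein; default) or `"all"` (every term
#'   annotated in the background).
#' @return Data frame of class `enrichment_result`, one row per tested
#'   term, sorted by adjusted p then term id: `term_id`, `namespace`,
#'   `k`, `n`, `K`, `N`, `p_raw`, `p_bonferroni`, `z`, `log2_ratio`,
#'   `significant`.
#' @export
run_enrichment <- function(test, background, annotations, alpha = 0.05,
                           m_mode = c("tested", "all")) {
  m_mode <- match.arg(m_mode)
  if (!all(test %in% background)) stop("test set must be a subset of background")
  ann <- unique(annotations[annotations$protein_id %in% background,
                            c("protein_id", "term_id", "namespace")])
  N <- length(unique(background))
  n <- length(unique(test))
  K_all <- table(ann$term_id)
  in_test <- ann$protein_id %in% test
  k_all <- table(factor(ann$term_id[in_test], levels = names(K_all)))
  tested <- names(K_all)[k_all >= 1L]
  m <- if (m_mode == "tested") length(tested) else length(K_all)
  ns <- ann$namespace[match(tested, ann$term_id)]
  if (length(tested) == 0L) {
    out <- data.frame(term_id = character(), namespace = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_raw = numeric(),
                      p_bonferroni = numeric(), z = numeric(),
                      log2_ratio = numeric(), significant = logical())
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  k <- as.integer(k_all[tested])
  K <- as.integer(K_all[tested])
  p_raw <- mapply(hypergeometric_upper, k = k, K = K,
                  MoreArgs = list(n = n, N = N))
  z <- vapply(seq_along(tested),
              function(i) two_proportion_z(k[i], n, K[i], N)$z, 0)
  lr <- log2((k / n) / (K / N))
  out <- data.frame(term_id = tested, namespace = ns, k = k, n = n,
                    K = K, N = N, p_raw = p_raw,
                    p_bonferroni = bonferroni(p_raw, m), z = z,
                    log2_ratio = lr, stringsAsFactors = FALSE)
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p_bonferroni, out$term_id), ]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}
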