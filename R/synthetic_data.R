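# Default residue frequencies for simulated proteomes: qualitatively
# proteome-like (Ser/Leu/Ala high; Met, Cys, His, Trp, Tyr low; Met at
# 2.4% of residues). Synthetic values, not measurements.
default_aa_frequencies <- c(
  A = 0.076, C = 0.015, D = 0.054, E = 0.063, F = 0.040, G = 0.070,
  H = 0.023, I = 0.055, K = 0.060, L = 0.090, M = 0.024, N = 0.042,
  P = 0.048, Q = 0.039, R = 0.055, S = 0.083, T = 0.055, V = 0.068,
  W = 0.011, Y = 0.029
)

#' Configuration for the synthetic-data generators
#'
#' Bundles and validates every knob of the simulation: proteome size
#' and composition, phosphosite count and the target probability that
#' a site's flanking window contains a Met, the cross-taxa
#' Met-conservation level distribution, and the GO annotation model
#' with planted enriched terms. The seed is mandatory: there is no
#' silent nondeterminism.
#'
#' @param seed Integer RNG seed (required).
#' @param n_proteins Number of proteins to simulate.
#' @param length_mean,length_dispersion Mean and negative-binomial
#'   dispersion (size) of protein lengths; lengths are floored at 30.
#' @param composition Named frequency vector over the 20 standard
#'   residues (normalised internally).
#' @param n_phosphosites Number of phosphosites to plant.
#' @param p_met_in_window Target probability that a planted site has at
#'   least one countable Met within the flanking window.
#' @param half_width Window half-width used when planting (default 6).
#' @param conservation_level_distribution Named numeric weights over
#'   levels 1..8 for the number of taxa carrying the Met (query
#'   included); default uniform.
#' @param vilf_substitution_fraction Probability that a member taxon
#'   lacking the Met carries V/I/L/F there instead.
#' @param site_conservation_prob Probability a member window keeps an
#'   S/T/Y at the centre.
#' @param member_mutation_rate Per-position substitution rate applied
#'   to member windows away from the centre and Met offsets.
#' @param taxon_labels Labels of the 7 member taxa.
#' @param n_go_terms Number of GO terms in the annotation model.
#' @param go_background_freq Background annotation probability per term
#'   (scalar, or vector of length `n_go_terms`).
#' @param planted_terms Named numeric vector of fold factors (>= 1)
#'   multiplying the annotation probability of those terms in the
#'   designated test subpopulation.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_proteins = 300L,
                             length_mean = 350,
                             length_dispersion = 4,
                             composition = default_aa_frequencies,
                             n_phosphosites = 1000L,
                             p_met_in_window = 0.14,
                             half_width = 6L,
                             conservation_level_distribution =
                               setNames(rep(1 / 8, 8), 1:8),
                             vilf_substitution_fraction = 0.5,
                             site_conservation_prob = 0.9,
                             member_mutation_rate = 0.1,
                             taxon_labels = sprintf("taxon_%d", 2:8),
                             n_go_terms = 20L,
                             go_background_freq = 0.1,
                             planted_terms = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!setequal(names(composition), AA_STANDARD))
    stop("composition must name all 20 standard residues")
  if (any(composition < 0)) stop("composition frequencies must be nonnegative")
  composition <- composition[AA_STANDARD] / sum(composition)
  probs <- c(p_met_in_window, vilf_substitution_fraction,
             site_conservation_prob, member_mutation_rate, go_background_freq)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(conservation_level_distribution < 0) ||
      sum(conservation_level_distribution) <= 0)
    stop("conservation_level_distribution must be nonnegative, nonzero weights")
  lv <- as.integer(names(conservation_level_distribution))
  if (anyNA(lv) || any(lv < 0L | lv > 8L))
    stop("conservation levels must be named 0..8")
  if (!is.null(planted_terms) &&
      (is.null(names(planted_terms)) || any(planted_terms < 1)))
    stop("planted_terms must be a named vector of fold factors >= 1")
  if (length(taxon_labels) != 7L || anyDuplicated(taxon_labels))
    stop("need 7 distinct member taxon labels")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_mean = length_mean,
                 length_dispersion = length_dispersion,
                 composition = composition,
                 n_phosphosites = as.integer(n_phosphosites),
                 p_met_in_window = p_met_in_window,
                 half_width = as.integer(half_width),
                 conservation_level_distribution =
                   conservation_level_distribution /
                     sum(conservation_level_distribution),
                 vilf_substitution_fraction = vilf_substitution_fraction,
                 site_conservation_prob = site_conservation_prob,
                 member_mutation_rate = member_mutation_rate,
                 taxon_labels = taxon_labels,
                 n_go_terms = as.integer(n_go_terms),
                 go_background_freq = go_background_freq,
                 planted_terms = planted_terms),
            class = "synthetic_config")
}

draw_residues <- function(n, composition, exclude = NULL) {
  if (!is.null(exclude)) {
    composition <- composition[setdiff(names(composition), exclude)]
    composition <- composition / sum(composition)
  }
  sample(names(composition), n, replace = TRUE, prob = composition)
}

#' Simulate a proteome
#'
#' Sequences are drawn i.i.d. from the configured residue composition;
#' every sequence begins with Met (the translated-protein convention),
#' and lengths follow a negative-binomial distribution floored at 30.
#' Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @param taxon_label,kingdom_group Passed to [proteome()].
#' @return A [proteome] of `config$n_proteins` sequences.
#' @export
generate_proteome <- function(config, taxon_label = "synthetic",
                              kingdom_group = NA_character_) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lens <- pmax(30L, rnbinom(config$n_proteins, mu = config$length_mean,
                            size = config$length_dispersion))
  seqs <- vapply(lens, function(L)
    paste0("M", paste(draw_residues(L - 1L, config$composition), collapse = "")),
    "")
  names(seqs) <- sprintf("prot%05d", seq_len(config$n_proteins))
  proteome(seqs, taxon_label = taxon_label, kingdom_group = kingdom_group)
}

#' Plant phosphosites with a controlled Met-in-window probability
#'
#' Samples `n_phosphosites` Ser/Thr/Tyr positions whose windows do not
#' overlap (edit collisions are impossible by construction; candidate
#' sites whose window would overlap an already accepted one are
#' skipped), then edits each flank so that the realised fraction of
#' Met-containing windows is Binomial(n, `p_met_in_window`): a window
#' drawn to carry Met gets one random flank position set to M if none
#' is present; a window drawn not to carry Met has all countable flank
#' Ms replaced by composition-weighted non-Met draws. Edits never touch
#' site centres or sequence position 1.
#'
#' @param proteome A [proteome] (typically from [generate_proteome()]).
#' @param config A [synthetic_config()].
#' @return List with the edited `proteome` and the site table `sites`
#'   (evidence `"experimental"`).
#' @export
plant_phosphosites <- function(proteome, config) {
  stopifnot(inherits(proteome, "proteome"), inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  k <- config$half_width
  sty <- enumerate_all_sty(proteome)
  if (nrow(sty) < config$n_phosphosites)
    stop("proteome has only ", nrow(sty), " S/T/Y positions; ",
         config$n_phosphosites, " requested")
  ord <- sample.int(nrow(sty))
  chosen <- integer(0)
  taken <- split(integer(0), character(0))  # protein -> accepted positions
  n_skipped <- 0L
  for (i in ord) {
    pid <- sty$protein_id[i]; pos <- sty$position[i]
    prev <- taken[[pid]]
    if (!is.null(prev) && any(abs(prev - pos) <= 2L * k)) {
      n_skipped <- n_skipped + 1L
      next
    }
    taken[[pid]] <- c(prev, pos)
    chosen <- c(chosen, i)
    if (length(chosen) == config$n_phosphosites) break
  }
  if (length(chosen) < config$n_phosphosites)
    stop("could not place ", config$n_phosphosites,
         " non-overlapping site windows")
  sites <- sty[chosen, , drop = FALSE]
  sites <- sites[order(sites$protein_id, sites$position), ]
  rownames(sites) <- NULL
  sites$evidence <- "experimental"
  seqs <- proteome$sequences
  want_met <- runif(nrow(sites)) < config$p_met_in_window
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]; pos <- sites$position[i]
    len <- nchar(seqs[[pid]])
    flank <- setdiff((pos - k):(pos + k), pos)
    flank <- flank[flank >= 2L & flank <= len]       # position 1 never edited
    flank <- setdiff(flank, taken[[pid]])            # never touch a site centre
    ch <- vapply(flank, function(p) substring(seqs[[pid]], p, p), "")
    mets <- flank[ch == "M"]
    if (want_met[i]) {
      if (length(mets) == 0L) {
        if (length(flank) == 0L)
          stop("site ", pid, ":", pos, " has no editable flank position")
        slot <- if (length(flank) == 1L) flank else sample(flank, 1L)
        substring(seqs[[pid]], slot, slot) <- "M"
      }
    } else if (length(mets) > 0L) {
      repl <- draw_residues(length(mets), config$composition, exclude = "M")
      for (j in seq_along(mets))
        substring(seqs[[pid]], mets[j], mets[j]) <- repl[j]
    }
  }
  edited <- proteome
  edited$sequences <- seqs
  if (n_skipped > 0L)
    message(n_skipped, " candidate site(s) skipped to avoid window overlap")
  list(proteome = edited, sites = sites)
}

#' Simulate homolog window mappings with planted Met conservation
#'
#' For each Met-containing site window, 7 member-taxon windows are
#' derived from the query: for each Met offset of the query window a
#' conservation level L (taxa carrying the Met, query included) is
#' drawn independently from the configured level distribution;
#' members lacking the Met there carry V/I/L/F with the configured
#' probability (a composition-weighted non-Met, non-VILF residue
#' otherwise). Centres stay S/T/Y with probability
#' `site_conservation_prob`; remaining positions mutate at
#' `member_mutation_rate` (never to Met).
#'
#' @param proteome The (edited) query [proteome].
#' @param sites Site table from [plant_phosphosites()].
#' @param config A [synthetic_config()].
#' @return List with the mapping data frame `mapping` (columns as in
#'   [read_homolog_table()]) and `levels`, a data frame of the drawn
#'   level per (family, offset).
#' @export
generate_homolog_families <- function(proteome, sites, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  hm <- sites_with_met(proteome, sites, 6L, discount_nterm = TRUE)
  met_sites <- sites[hm, , drop = FALSE]
  lv_vals <- as.integer(names(config$conservation_level_distribution))
  rows <- vector("list", nrow(met_sites))
  drawn <- vector("list", nrow(met_sites))
  for (i in seq_len(nrow(met_sites))) {
    pid <- met_sites$protein_id[i]; pos <- met_sites$position[i]
    w <- extract_window(proteome, pid, pos, 6L)
    qwin <- window_string(proteome, pid, pos, 6L)
    met_off <- w$offsets[!is.na(w$flank) & w$flank == "M" & w$abs_pos != 1L]
    members <- matrix(rep(strsplit(qwin, "")[[1L]], 7L), nrow = 7L,
                      byrow = TRUE)
    # background divergence away from the centre and the Met offsets
    free_cols <- setdiff(1:13, c(7L, met_off + 7L))
    for (col in free_cols) {
      mut <- runif(7L) < config$member_mutation_rate
      if (any(mut) && members[1L, col] != "-")
        members[mut, col] <- draw_residues(sum(mut), config$composition,
                                           exclude = "M")
    }
    keep_center <- runif(7L) < config$site_conservation_prob
    if (any(!keep_center))
      members[!keep_center, 7L] <-
        draw_residues(sum(!keep_center), config$composition,
                      exclude = c("M", "S", "T", "Y"))
    lv_o <- integer(length(met_off))
    for (oi in seq_along(met_off)) {
      o <- met_off[oi]
      col <- o + 7L
      # the query itself always carries the Met, so the realised level
      # is at least 1
      L <- max(1L, min(8L, lv_vals[sample.int(length(lv_vals), 1L,
                 prob = config$conservation_level_distribution)]))
      lv_o[oi] <- L
      carriers <- if (L - 1L > 0L) sample.int(7L, L - 1L) else integer(0)
      members[, col] <- "M"
      non <- setdiff(1:7, carriers)
      vilf <- runif(length(non)) < config$vilf_substitution_fraction
      sub <- character(length(non))
      sub[vilf] <- sample(AA_VILF, sum(vilf), replace = TRUE)
      if (any(!vilf))
        sub[!vilf] <- draw_residues(sum(!vilf), config$composition,
                                    exclude = c("M", AA_VILF))
      members[non, col] <- sub
    }
    drawn[[i]] <- data.frame(family_id = paste0(pid, ":", pos),
                             offset = as.integer(met_off), level = lv_o,
                             stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(query_protein_id = pid, query_position = pos,
                            taxon_label = config$taxon_labels,
                            aligned_window = apply(members, 1L, paste,
                                                   collapse = ""),
                            stringsAsFactors = FALSE)
  }
  mapping <- do.call(rbind, rows)
  if (is.null(mapping))
    mapping <- data.frame(query_protein_id = character(),
                          query_position = integer(),
                          taxon_label = character(),
                          aligned_window = character())
  rownames(mapping) <- NULL
  levels_df <- do.call(rbind, drawn)
  if (is.null(levels_df))
    levels_df <- data.frame(family_id = character(), offset = integer(),
                            level = integer())
  rownames(levels_df) <- NULL
  list(mapping = mapping, levels = levels_df)
}

#' Simulate GO annotations with planted enriched terms
#'
#' Every term is assigned to every protein by an independent coin flip
#' at its background frequency; for proteins in the designated test
#' subpopulation, planted terms have their probability multiplied by
#' the configured fold factor (capped at 1). Namespaces cycle through
#' BP/MF/CC.
#'
#' @param proteome A [proteome] (defines the protein universe).
#' @param config A [synthetic_config()].
#' @param test_proteins Character vector of protein ids forming the
#'   subpopulation in which planted terms are enriched.
#' @return Annotation data frame `protein_id`, `term_id`, `namespace`.
#' @export
generate_go_annotations <- function(proteome, config, test_proteins = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 3L)
  ids <- names(proteome$sequences)
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  ns <- rep_len(c("BP", "MF", "CC"), config$n_go_terms)
  freq <- rep_len(config$go_background_freq, config$n_go_terms)
  in_test <- ids %in% test_proteins
  out <- vector("list", config$n_go_terms)
  for (t in seq_len(config$n_go_terms)) {
    p <- rep(freq[t], length(ids))
    if (!is.null(config$planted_terms) && terms[t] %in% names(config$planted_terms))
      p[in_test] <- pmin(1, freq[t] * config$planted_terms[[terms[t]]])
    hit <- runif(length(ids)) < p
    if (any(hit))
      out[[t]] <- data.frame(protein_id = ids[hit], term_id = terms[t],
                             namespace = ns[t], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein_id = character(), term_id = character(),
                      namespace = character())
  rownames(res) <- NULL
  res
}
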