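#' 13-character window string for a site
#'
#' Centre-aligned window including the site residue at position 7;
#' positions beyond the protein termini are padded with `-`.
#'
#' @inheritParams extract_window
#' @return Character scalar of length `2 * half_width + 1`.
#' @export
window_string <- function(proteome, protein_id, position, half_width = 6L) {
  w <- extract_window(proteome, protein_id, position, half_width)
  ch <- ifelse(is.na(w$flank), "-", w$flank)
  paste0(paste(ch[w$offsets < 0], collapse = ""), w$residue,
         paste(ch[w$offsets > 0], collapse = ""))
}

#' Build homolog families for Met-containing phosphosite windows
#'
#' One family per query site whose 13-residue window holds at least one
#' Met in the flank; the query's own taxon counts as one member taxon,
#' and rows of the mapping table contribute the others. Mapping rows
#' with a window that is not 13 characters are rejected with a message;
#' multiple rows per (site, taxon) keep only the first.
#'
#' @param proteome Query [proteome].
#' @param sites Validated site data frame.
#' @param mapping Homolog mapping data frame
#'   (see [read_homolog_table()]); may have zero rows.
#' @return List of class `homolog_families`; each element has
#'   `family_id` ("protein:position"), `protein_id`, `position`,
#'   `met_offsets` (offsets in -6..+6 where the query flank holds M)
#'   and `members` (named character vector taxon -> 13-char window,
#'   query taxon first).
#' @export
build_families <- function(proteome, sites, mapping = NULL) {
  stopifnot(inherits(proteome, "proteome"))
  if (is.null(mapping))
    mapping <- data.frame(query_protein_id = character(),
                          query_position = integer(),
                          taxon_label = character(),
                          aligned_window = character())
  bad <- nchar(mapping$aligned_window) != 13L
  if (any(bad)) {
    message(sum(bad), " mapping row(s) rejected: window not 13 characters")
    mapping <- mapping[!bad, , drop = FALSE]
  }
  key <- paste(mapping$query_protein_id, mapping$query_position,
               mapping$taxon_label, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate (site, taxon) mapping row(s) dropped")
    mapping <- mapping[!dup, , drop = FALSE]
  }
  map_key <- paste(mapping$query_protein_id, mapping$query_position, sep = "\r")
  fams <- list()
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]; pos <- sites$position[i]
    w <- extract_window(proteome, pid, pos, 6L)
    countable <- !is.na(w$flank) & w$flank == "M" & w$abs_pos != 1L
    mo <- w$offsets[countable]
    if (length(mo) == 0L) next
    qwin <- window_string(proteome, pid, pos, 6L)
    rows <- mapping[map_key == paste(pid, pos, sep = "\r"), , drop = FALSE]
    members <- c(setNames(qwin, proteome$taxon_label),
                 setNames(rows$aligned_window, rows$taxon_label))
    fams[[paste0(pid, ":", pos)]] <-
      list(family_id = paste0(pid, ":", pos), protein_id = pid,
           position = as.integer(pos), met_offsets = as.integer(mo),
           members = members)
  }
  structure(fams, class = "homolog_families")
}

#' @export
print.homolog_families <- function(x, ...) {
  cat(sprintf("homolog_families: %d families, %s member taxa per family\n",
              length(x),
              if (length(x)) paste(range(lengths(lapply(x, `[[`, "members"))),
                                   collapse = "-") else "0"))
  invisible(x)
}

#' Met-conservation level of one family at one offset
#'
#' Counts the taxa (query included) whose aligned window holds `M` at
#' the given offset; among the taxa lacking Met there, the fraction
#' holding one of the hydrophobic substitutes Val/Ile/Leu/Phe. Gaps
#' (`-`) count as neither Met nor VILF.
#'
#' @param family One element of a [build_families()] result.
#' @param offset Signed offset in -6..+6; must be one of the family's
#'   `met_offsets`.
#' @return One-row data frame `family_id`, `offset`, `n_taxa`, `level`,
#'   `vilf_fraction` (`NA` when all taxa hold Met).
#' @export
conservation_level <- function(family, offset) {
  if (!offset %in% family$met_offsets)
    stop("offset ", offset, " is not a Met offset of the query window")
  ch <- substring(family$members, offset + 7L, offset + 7L)
  level <- sum(ch == "M")
  non_met <- ch[ch != "M"]
  vilf <- if (length(non_met) == 0L) NA_real_ else mean(non_met %in% AA_VILF)
  data.frame(family_id = family$family_id, offset = as.integer(offset),
             n_taxa = length(ch), level = as.integer(level),
             vilf_fraction = vilf, stringsAsFactors = FALSE)
}

#' Conservation records for every Met offset of every family
#'
#' @param families A [build_families()] result.
#' @return Data frame of [conservation_level()] rows.
#' @export
conservation_table <- function(families) {
  rows <- lapply(unclass(families), function(f)
    do.call(rbind, lapply(f$met_offsets, function(o) conservation_level(f, o))))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family_id = character(), offset = integer(),
                      n_taxa = integer(), level = integer(),
                      vilf_fraction = numeric())
  rownames(out) <- NULL
  out
}

#' Conservation-level summary (heat-map table)
#'
#' Proportion of conservation records at each Met-conservation level,
#' with the mean VILF-substitution fraction per level as companion.
#'
#' @param records A [conservation_table()] result.
#' @param max_level Highest level to tabulate (default 8 taxa).
#' @return Data frame `level`, `n`, `proportion`, `mean_vilf_fraction`;
#'   proportions sum to 1 over levels (zero rows for absent levels).
#'   Empty input gives a zero-row data frame.
#' @export
conservation_heatmap <- function(records, max_level = 8L) {
  if (nrow(records) == 0L)
    return(data.frame(level = integer(), n = integer(),
                      proportion = numeric(), mean_vilf_fraction = numeric()))
  lev <- factor(records$level, levels = 0:max_level)
  n <- as.integer(table(lev))
  vilf <- suppressWarnings(
    tapply(records$vilf_fraction, lev, mean, na.rm = TRUE))
  out <- data.frame(level = 0:max_level, n = n,
                    proportion = n / sum(n),
                    mean_vilf_fraction = as.numeric(vilf))
  out$mean_vilf_fraction[is.nan(out$mean_vilf_fraction)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Classify a Met-adjacent phosphosite into a crosstalk scenario
#'
#' Applies the conservation logic for candidate phosphorylation /
#' Met-oxidation crosstalk: a Met conserved across taxa next to a
#' conserved phosphosite is a regulatory candidate; a Met replaced by
#' other hydrophobics (V/I/L/F) next to a conserved site is likely a
#' structural hydrophobic placeholder; otherwise the site, the Met, or
#' both are not conserved and crosstalk is unlikely.
#'
#' @param family One element of a [build_families()] result.
#' @param offset A Met offset of the family.
#' @param high_threshold Minimum number of taxa (default 6 of 8)
#'   counting as conserved, for both the Met and the phosphosite.
#' @return One-row data frame with `family_id`, `offset`, `level`,
#'   `n_taxa`, `site_conserved_count`, `scenario` (one of
#'   `regulatory_candidate`, `structural_hydrophobic`,
#'   `site_not_conserved`, `met_not_conserved`, `neither_conserved`).
#' @export
classify_scenario <- function(family, offset, high_threshold = 6L) {
  rec <- conservation_level(family, offset)
  ch <- substring(family$members, offset + 7L, offset + 7L)
  centers <- substring(family$members, 7L, 7L)
  site_cons <- sum(centers %in% c("S", "T", "Y"))
  n_vilf <- sum(ch != "M" & ch %in% AA_VILF)
  met_ok <- rec$level >= high_threshold
  hydrophobic_ok <- (rec$level + n_vilf) >= high_threshold
  site_ok <- site_cons >= high_threshold
  scenario <-
    if (met_ok && site_ok) "regulatory_candidate"
    else if (hydrophobic_ok && site_ok) "structural_hydrophobic"
    else if (!site_ok && (met_ok || hydrophobic_ok)) "site_not_conserved"
    else if (site_ok) "met_not_conserved"
    else "neither_conserved"
  data.frame(family_id = family$family_id, offset = as.integer(offset),
             level = rec$level, n_taxa = rec$n_taxa,
             site_conserved_count = as.integer(site_cons),
             scenario = scenario, stringsAsFactors = FALSE)
}

#' Classify all families at all Met offsets
#'
#' @param families A [build_families()] result.
#' @inheritParams classify_scenario
#' @return Data frame of [classify_scenario()] rows.
#' @export
classify_scenarios <- function(families, high_threshold = 6L) {
  rows <- lapply(unclass(families), function(f)
    do.call(rbind, lapply(f$met_offsets, function(o)
      classify_scenario(f, o, high_threshold))))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family_id = character(), offset = integer(),
                      level = integer(), n_taxa = integer(),
                      site_conserved_count = integer(), scenario = character())
  rownames(out) <- NULL
  out
}

#' Toy best-hit homolog matcher
#'
#' A deliberately simple stand-in for a profile search, used by tests
#' and the synthetic pipeline only: for each query site it scans every
#' ungapped 13-mer of the subject proteome and returns the best match
#' (identity over 13 positions, centre-aligned to the site) with
#' identity at or above `min_identity`. Ties resolve to the first hit
#' in (protein id, position) order. Query windows are padded with `-`
#' at the termini; pad positions never match.
#'
#' @param proteome Query [proteome].
#' @param sites Validated site data frame.
#' @param subject_proteome Subject [proteome] to search.
#' @param min_identity Minimum fractional identity in \[0, 1\].
#' @return Mapping data frame (`query_protein_id`, `query_position`,
#'   `taxon_label`, `aligned_window`, `identity`); zero rows when
#'   nothing reaches `min_identity`.
#' @export
toy_homolog_matcher <- function(proteome, sites, subject_proteome,
                                min_identity = 0.5) {
  stopifnot(inherits(subject_proteome, "proteome"))
  subj_ids <- sort(names(subject_proteome$sequences))
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    qwin <- window_string(proteome, sites$protein_id[i], sites$position[i], 6L)
    qch <- strsplit(qwin, "")[[1L]]
    best <- list(identity = -1)
    for (sid in subj_ids) {
      sseq <- subject_proteome$sequences[[sid]]
      L <- nchar(sseq)
      if (L < 13L) next
      sch <- strsplit(sseq, "")[[1L]]
      n_win <- L - 12L
      matches <- integer(n_win)
      for (j in 1:13) {
        if (qch[j] == "-") next
        matches <- matches + (sch[j:(j + n_win - 1L)] == qch[j])
      }
      top <- which.max(matches)  # earliest position wins ties
      ident <- matches[top] / 13
      if (ident > best$identity) {
        best <- list(identity = ident,
                     window = substring(sseq, top, top + 12L))
      }
    }
    if (best$identity >= min_identity)
      out[[i]] <- data.frame(query_protein_id = sites$protein_id[i],
                             query_position = sites$position[i],
                             taxon_label = subject_proteome$taxon_label,
                             aligned_window = best$window,
                             identity = best$identity,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(query_protein_id = character(),
                      query_position = integer(), taxon_label = character(),
                      aligned_window = character(), identity = numeric())
  rownames(res) <- NULL
  res
}
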