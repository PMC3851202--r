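#' Extract the flanking window around a site
#'
#' Returns the 2k flank residues at offsets -k..-1, +1..+k around a
#' site. Offsets that fall outside the protein are marked missing
#' (`NA`); offset 0, the site itself, is never part of the flank.
#'
#' @param proteome A [proteome].
#' @param protein_id Protein identifier.
#' @param position 1-based site position.
#' @param half_width Integer k, 0..10 (default 6, the 13-residue window).
#' @return An object of class `site_window`: list with `protein_id`,
#'   `position`, `residue`, `half_width`, `offsets`, `flank` (character,
#'   `NA` where beyond a terminus) and `abs_pos` (absolute sequence
#'   position of each flank slot).
#' @export
extract_window <- function(proteome, protein_id, position, half_width = 6L) {
  stopifnot(inherits(proteome, "proteome"))
  if (half_width < 0L || half_width > 10L) stop("half_width must be in 0..10")
  seq <- proteome$sequences[[protein_id]]
  if (is.null(seq)) stop("unknown protein: ", protein_id)
  len <- nchar(seq)
  if (position < 1L || position > len)
    stop("position ", position, " outside protein ", protein_id)
  offsets <- setdiff(seq_len(2L * half_width + 1L) - half_width - 1L, 0L)
  abs_pos <- position + offsets
  flank <- rep(NA_character_, length(offsets))
  inside <- abs_pos >= 1L & abs_pos <= len
  flank[inside] <- vapply(abs_pos[inside],
                          function(p) substring(seq, p, p), "")
  structure(list(protein_id = protein_id, position = as.integer(position),
                 residue = substring(seq, position, position),
                 half_width = as.integer(half_width),
                 offsets = as.integer(offsets), flank = flank,
                 abs_pos = as.integer(abs_pos)),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  shown <- ifelse(is.na(x$flank), ".", x$flank)
  left <- paste(shown[x$offsets < 0], collapse = "")
  right <- paste(shown[x$offsets > 0], collapse = "")
  cat(sprintf("site_window %s:%d  %s[%s]%s\n", x$protein_id, x$position,
              left, x$residue, right))
  invisible(x)
}

#' Does a window contain a methionine?
#'
#' TRUE iff at least one non-missing flank slot holds `M`. With
#' `discount_nterm` (the default) a slot whose absolute sequence
#' position is 1 — the initiator Met of a translated protein — is
#' ignored.
#'
#' @param window A [extract_window()] result.
#' @param discount_nterm Ignore Met at sequence position 1?
#' @return Logical scalar.
#' @export
has_met <- function(window, discount_nterm = TRUE) {
  stopifnot(inherits(window, "site_window"))
  is_m <- !is.na(window$flank) & window$flank == "M"
  if (discount_nterm) is_m <- is_m & window$abs_pos != 1L
  any(is_m)
}

# Character matrix of flank residues for many sites at once:
# one row per site, one column per offset (-k..k excluding 0), NA beyond
# the termini. Backbone of all window counting.
window_matrix <- function(proteome, sites, half_width = 6L) {
  seqs <- proteome$sequences[sites$protein_id]
  if (anyNA(names(seqs) != sites$protein_id) || any(is.na(seqs)))
    stop("site table references unknown protein id(s)")
  lens <- nchar(seqs)
  offsets <- setdiff(-half_width:half_width, 0L)
  m <- matrix(NA_character_, nrow = nrow(sites), ncol = length(offsets),
              dimnames = list(NULL, as.character(offsets)))
  for (j in seq_along(offsets)) {
    p <- sites$position + offsets[j]
    inside <- p >= 1L & p <= lens
    ch <- substring(seqs[inside], p[inside], p[inside])
    m[inside, j] <- ch
  }
  attr(m, "offsets") <- offsets
  m
}

# Logical vector: which sites have >= 1 countable Met in their flank.
sites_with_met <- function(proteome, sites, half_width = 6L,
                           discount_nterm = TRUE) {
  if (nrow(sites) == 0L) return(logical())
  m <- window_matrix(proteome, sites, half_width)
  offsets <- attr(m, "offsets")
  is_m <- !is.na(m) & m == "M"
  if (discount_nterm)
    for (j in seq_along(offsets))
      is_m[sites$position + offsets[j] == 1L, j] <- FALSE
  rowSums(is_m) > 0L
}

#' Met-proximity proportions per residue type and evidence group
#'
#' For each combination of site residue (S/T/Y) and evidence group
#' present in `sites`, the number and percentage of sites with at
#' least one Met within the +/- `half_width` flanking window.
#'
#' @param proteome A [proteome].
#' @param sites Validated site data frame.
#' @param half_width Window half-width (default 6).
#' @param discount_nterm Ignore Met at sequence position 1 (default TRUE).
#' @return Data frame with columns `residue`, `evidence`, `n_sites`,
#'   `n_with_met`, `proportion` (percent), of class `met_proximity`.
#' @export
met_proximity_table <- function(proteome, sites, half_width = 6L,
                                discount_nterm = TRUE) {
  if (nrow(sites) == 0L) {
    out <- data.frame(residue = character(), evidence = character(),
                      n_sites = integer(), n_with_met = integer(),
                      proportion = numeric())
    class(out) <- c("met_proximity", "data.frame")
    return(out)
  }
  hm <- sites_with_met(proteome, sites, half_width, discount_nterm)
  grp <- interaction(sites$residue, sites$evidence, drop = TRUE, sep = "\r")
  n <- as.integer(table(grp))
  k <- as.integer(tapply(hm, grp, sum))
  parts <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  out <- data.frame(residue = parts[, 1L], evidence = parts[, 2L],
                    n_sites = n, n_with_met = k,
                    proportion = 100 * k / n, stringsAsFactors = FALSE)
  out <- out[order(out$residue, out$evidence), ]
  rownames(out) <- NULL
  class(out) <- c("met_proximity", "data.frame")
  out
}

#' Positional distribution of a residue class around sites
#'
#' Per-offset occurrence percentages of a residue class (Met, or any
#' subset of the hydrophobic group V/I/L/F, pooled) across the flanking
#' windows of a site set. The denominator at offset d is the number of
#' sites whose position + d lies inside the protein; for class `"M"`
#' the amino-terminal Met discount applies to the numerator.
#'
#' @inheritParams met_proximity_table
#' @param residue_class `"M"` (default), `"VILF"` (pooled), or a
#'   character vector of residue letters.
#' @return Data frame `offset`, `count`, `denominator`, `percent`
#'   (NaN where the denominator is 0), of class
#'   `positional_distribution`.
#' @export
positional_distribution <- function(proteome, sites, residue_class = "M",
                                    half_width = 6L, discount_nterm = TRUE) {
  letters_in_class <- if (identical(residue_class, "VILF")) AA_VILF
    else unique(toupper(residue_class))
  stopifnot(all(letters_in_class %in% AA_STANDARD))
  offsets <- setdiff(-half_width:half_width, 0L)
  if (nrow(sites) == 0L) {
    out <- data.frame(offset = offsets, count = 0L, denominator = 0L,
                      percent = NaN)
  } else {
    m <- window_matrix(proteome, sites, half_width)
    hit <- !is.na(m) & matrix(m %in% letters_in_class, nrow = nrow(m))
    if (discount_nterm && "M" %in% letters_in_class)
      for (j in seq_along(offsets))
        hit[sites$position + offsets[j] == 1L & m[, j] %in% "M", j] <- FALSE
    denom <- colSums(!is.na(m))
    count <- colSums(hit)
    out <- data.frame(offset = offsets, count = as.integer(count),
                      denominator = as.integer(denom),
                      percent = 100 * count / denom)
  }
  attr(out, "residue_class") <- paste(letters_in_class, collapse = "")
  class(out) <- c("positional_distribution", "data.frame")
  out
}

#' Amino-acid composition of a proteome
#'
#' Percentages of the 20 standard residues across all sequences.
#' With `discount_nterm` (default) an amino-terminal Met is excluded
#' from both numerator and denominator, reflecting that the initiator
#' Met of a translated protein is not informative about internal Met
#' availability. Ambiguity codes (B/Z/X/U) are excluded from the
#' denominator.
#'
#' @inheritParams met_proximity_table
#' @return Data frame `residue`, `count`, `percent` over the 20
#'   standard residues (percent sums to 100), of class
#'   `composition_table`.
#' @export
composition <- function(proteome, discount_nterm = TRUE) {
  stopifnot(inherits(proteome, "proteome"))
  seqs <- proteome$sequences
  if (discount_nterm) {
    leading_m <- substring(seqs, 1L, 1L) == "M"
    seqs[leading_m] <- substring(seqs[leading_m], 2L)
    seqs <- seqs[nchar(seqs) > 0L]
  }
  counts <- colSums(Biostrings::letterFrequency(Biostrings::AAStringSet(seqs),
                                                letters = AA_STANDARD))
  total <- sum(counts)
  if (total == 0L) stop("no standard residues to count")
  out <- data.frame(residue = AA_STANDARD, count = as.integer(counts),
                    percent = 100 * counts / total, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Kyte-Doolittle hydropathy score of a site window
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over the
#' non-missing, non-ambiguous flank residues; the phosphosite itself
#' (offset 0) is excluded. The mean (rather than the sum) keeps scores
#' comparable between full and terminus-truncated windows.
#'
#' @param window A [extract_window()] result.
#' @return Numeric score, or `NA` when no scorable flank residue exists.
#' @export
hydropathy_score <- function(window) {
  stopifnot(inherits(window, "site_window"))
  vals <- kyte_doolittle[window$flank]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Hydropathy scores for a site table
#'
#' @inheritParams met_proximity_table
#' @return `sites` with an added numeric `hydropathy` column.
#' @export
hydropathy_table <- function(proteome, sites, half_width = 6L) {
  if (nrow(sites) == 0L) {
    sites$hydropathy <- numeric()
    return(sites)
  }
  m <- window_matrix(proteome, sites, half_width)
  v <- matrix(kyte_doolittle[m], nrow = nrow(m))
  sites$hydropathy <- rowMeans(v, na.rm = TRUE)
  sites$hydropathy[is.nan(sites$hydropathy)] <- NA_real_
  sites
}

#' Met-proximity proportions across window sizes
#'
#' Recomputes the Met-proximity table for each half-width, showing how
#' the proportion of Met-containing windows grows with window length;
#' for a fixed site set the proportion is non-decreasing in the
#' half-width (larger windows are supersets).
#'
#' @inheritParams met_proximity_table
#' @param half_widths Integer vector of half-widths (default 1..10).
#' @return Row-bound [met_proximity_table()] results with an extra
#'   leading `half_width` column.
#' @export
window_size_scan <- function(proteome, sites, half_widths = 1:10,
                             discount_nterm = TRUE) {
  parts <- lapply(half_widths, function(k) {
    tab <- met_proximity_table(proteome, sites, k, discount_nterm)
    if (nrow(tab) == 0L) return(NULL)
    cbind(half_width = k, as.data.frame(tab))
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(half_width = integer(), residue = character(),
                      evidence = character(), n_sites = integer(),
                      n_with_met = integer(), proportion = numeric())
  rownames(out) <- NULL
  out
}
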