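#' Construct a proteome object
#'
#' A proteome is the universe for all counting in the package: a set of
#' uniquely identified amino-acid sequences plus a taxon label and a
#' kingdom group used when results from several proteomes are combined.
#'
#' @param sequences Named character vector of uppercase amino-acid
#'   sequences; names are protein identifiers and must be unique.
#' @param taxon_label Free-text taxon name.
#' @param kingdom_group One of `"plant"`, `"yeast"`, `"animal"`,
#'   `"bacteria"`, `"archaea"`, or `NA`.
#' @return An object of class `proteome`.
#' @export
proteome <- function(sequences, taxon_label = "unknown",
                     kingdom_group = NA_character_) {
  if (length(sequences) == 0L) stop("proteome must contain at least one sequence")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must carry a non-empty protein id")
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sequences <- toupper(gsub("[[:space:]]", "", sequences))
  if (any(nchar(sequences) < 1L)) stop("zero-length sequence present")
  bad <- grepl(sprintf("[^%s]", paste(c(AA_STANDARD, AA_AMBIGUOUS), collapse = "")),
               sequences)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  if (!is.na(kingdom_group))
    kingdom_group <- match.arg(kingdom_group,
                               c("plant", "yeast", "animal", "bacteria", "archaea"))
  structure(list(taxon_label = taxon_label,
                 kingdom_group = kingdom_group,
                 sequences = sequences),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("proteome '%s' (%s): %d proteins, %d residues\n",
              x$taxon_label,
              ifelse(is.na(x$kingdom_group), "kingdom unspecified", x$kingdom_group),
              length(x$sequences), sum(nchar(x$sequences))))
  invisible(x)
}

#' @export
length.proteome <- function(x) length(x$sequences)

#' Read a proteome from a FASTA file
#'
#' The header token before the first whitespace becomes the protein id.
#' Sequences are uppercased; a single trailing stop codon `*` is
#' stripped with a warning. Duplicate ids, empty files and characters
#' outside the 20-letter alphabet plus B/Z/X/U are hard errors.
#'
#' @param path Path to a FASTA file.
#' @inheritParams proteome
#' @return A [proteome] object.
#' @export
read_fasta <- function(path, taxon_label = "unknown",
                       kingdom_group = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-amino-acid characters in FASTA file: ", path, call. = FALSE)
    })
  if (length(aas) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- sub("\\s.*$", "", names(aas))
  stopped <- grepl("\\*$", seqs)
  if (any(stopped)) {
    warning(sum(stopped), " sequence(s) had a trailing '*' stop codon; stripped")
    seqs[stopped] <- sub("\\*$", "", seqs[stopped])
  }
  if (any(grepl("\\*", seqs)))
    stop("internal '*' characters in: ",
         paste(names(seqs)[grepl("\\*", seqs)], collapse = ", "))
  proteome(seqs, taxon_label = taxon_label, kingdom_group = kingdom_group)
}

#' Write a proteome to a FASTA file
#'
#' @param x A [proteome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "proteome"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x$sequences), path)
  invisible(path)
}

#' Read and validate a phosphosite table
#'
#' Expects a tab-separated file with header columns `protein_id`,
#' `position` (1-based), `residue` (S/T/Y) and `evidence`
#' (`experimental` or `predicted`). Each row is checked against the
#' proteome: unknown proteins, out-of-range positions and residue
#' mismatches are rejected (and counted); only valid rows are returned.
#'
#' @param path Path to the TSV site table.
#' @param proteome A [proteome] the sites refer to.
#' @return A data frame of valid sites with columns `protein_id`,
#'   `position`, `residue`, `evidence`; the number of rejected rows is
#'   attached as attribute `n_rejected`.
#' @export
read_site_table <- function(path, proteome) {
  stopifnot(inherits(proteome, "proteome"))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "evidence")
  if (!all(need %in% names(tab)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$position))
  if (anyNA(pos)) stop("malformed (non-integer) position in site table")
  tab$position <- pos
  validate_sites(tab[need], proteome)
}

validate_sites <- function(sites, proteome) {
  known <- sites$protein_id %in% names(proteome$sequences)
  lens <- rep(NA_integer_, nrow(sites))
  lens[known] <- nchar(proteome$sequences[sites$protein_id[known]])
  in_range <- known & sites$position >= 1L & sites$position <= lens
  actual <- rep(NA_character_, nrow(sites))
  ok_idx <- which(in_range)
  actual[ok_idx] <- substring(proteome$sequences[sites$protein_id[ok_idx]],
                              sites$position[ok_idx], sites$position[ok_idx])
  valid <- in_range & !is.na(actual) & actual == sites$residue &
    sites$residue %in% c("S", "T", "Y")
  n_rej <- sum(!valid)
  if (n_rej > 0L)
    message(n_rej, " site row(s) rejected (unknown protein, position out of ",
            "range, or residue mismatch); ", sum(valid), " retained")
  out <- sites[valid, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rej
  out
}

#' Enumerate every Ser/Thr/Tyr position in a proteome
#'
#' Produces the proteome-wide background site set: one record per S, T
#' or Y occurrence in every sequence, with evidence class `all_sty`.
#'
#' @param proteome A [proteome].
#' @return Data frame with columns `protein_id`, `position`, `residue`,
#'   `evidence` (all `"all_sty"`).
#' @export
enumerate_all_sty <- function(proteome) {
  stopifnot(inherits(proteome, "proteome"))
  hits <- gregexpr("[STY]", proteome$sequences)
  n_per <- vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), 0L)
  pos <- unlist(lapply(hits, function(h) if (h[1L] == -1L) integer() else as.integer(h)),
                use.names = FALSE)
  ids <- rep(names(proteome$sequences), n_per)
  res <- substring(proteome$sequences[ids], pos, pos)
  data.frame(protein_id = ids, position = pos, residue = unname(res),
             evidence = rep_len("all_sty", length(pos)),
             stringsAsFactors = FALSE)
}

#' Read a GO annotation table
#'
#' Three tab-separated columns with header: `protein_id`, `term_id`,
#' `namespace` (BP/MF/CC). Duplicate (protein, term) pairs collapse to
#' one. Annotations are used exactly as given; no ontology-graph
#' ancestor propagation is performed, so pre-propagated tables should
#' be supplied where that behaviour is wanted.
#'
#' @param path Path to the TSV file.
#' @return Data frame `protein_id`, `term_id`, `namespace`.
#' @export
read_go_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "term_id", "namespace")
  if (!all(need %in% names(tab)))
    stop("GO annotation table must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$namespace %in% c("BP", "MF", "CC")))
    stop("namespace must be one of BP, MF, CC")
  unique(tab[need])
}

#' Read a homolog window-mapping table
#'
#' Four tab-separated columns with header: `query_protein_id`,
#' `query_position`, `taxon_label`, `aligned_window`. Each row gives,
#' for one query phosphosite and one taxon, the 13-character window of
#' the homologous sequence aligned so that its centre matches the query
#' site; `-` marks alignment gaps. Rows whose window is not exactly 13
#' characters are rejected with a message; when several rows exist for
#' one (site, taxon) pair only the first is kept.
#'
#' @param path Path to the TSV file.
#' @return Data frame of valid mapping rows.
#' @export
read_homolog_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("query_protein_id", "query_position", "taxon_label", "aligned_window")
  if (!all(need %in% names(tab)))
    stop("homolog table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[need]
  bad <- nchar(tab$aligned_window) != 13L
  if (any(bad)) {
    message(sum(bad), " homolog row(s) rejected: aligned_window not 13 characters")
    tab <- tab[!bad, , drop = FALSE]
  }
  key <- paste(tab$query_protein_id, tab$query_position, tab$taxon_label, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate (site, taxon) homolog row(s) dropped; first kept")
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}
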