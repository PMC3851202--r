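# Independent brute-force oracles, written as plain loops over
# characters so they share no code path with the package internals.

brute_window_chars <- function(seq, pos, k) {
  out <- character(0)
  for (d in setdiff(-k:k, 0)) {
    p <- pos + d
    out <- c(out, if (p < 1 || p > nchar(seq)) NA_character_
                  else substr(seq, p, p))
  }
  out
}

brute_has_met <- function(seq, pos, k, discount = TRUE) {
  for (d in setdiff(-k:k, 0)) {
    p <- pos + d
    if (p < 1 || p > nchar(seq)) next
    if (discount && p == 1) next
    if (substr(seq, p, p) == "M") return(TRUE)
  }
  FALSE
}

brute_met_count <- function(seqs, sites, k, discount = TRUE) {
  n <- 0L
  for (i in seq_len(nrow(sites))) {
    if (brute_has_met(seqs[[sites$protein_id[i]]], sites$position[i], k,
                      discount))
      n <- n + 1L
  }
  n
}

brute_composition_counts <- function(seqs, discount = TRUE) {
  counts <- setNames(integer(20),
                     strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    if (discount && chars[1] == "M") chars <- chars[-1]
    for (ch in chars)
      if (ch %in% names(counts)) counts[ch] <- counts[ch] + 1L
  }
  counts
}

brute_positional_count <- function(seqs, sites, offset, letters,
                                   discount = TRUE) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(sites))) {
    seq <- seqs[[sites$protein_id[i]]]
    p <- sites$position[i] + offset
    if (p < 1 || p > nchar(seq)) next
    den <- den + 1L
    ch <- substr(seq, p, p)
    if (ch %in% letters && !(discount && p == 1 && ch == "M"))
      num <- num + 1L
  }
  c(count = num, denominator = den)
}

# Exact hypergeometric upper tail by direct ratio-of-binomials summation
# (plain choose(), no log space).
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# A deterministic random proteome for property tests (independent of the
# package's generator).
random_test_proteome <- function(n = 5, len = 60, seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("q", seq_len(n))
  proteome(seqs, taxon_label = "test")
}

tiny_family <- function(members, met_offsets = -1L,
                        id = "fam:1") {
  list(family_id = id, protein_id = sub(":.*", "", id),
       position = 1L, met_offsets = as.integer(met_offsets),
       members = members)
}
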