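# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (per-read loops, all-pairs comparisons) so they share no
# code path with the package implementation they check.

# Hamming distance; NA when lengths differ.
oracle_hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Naive 3' adapter trim: try every cut position left to right, take the first
# whose adapter prefix (length >= min_overlap) matches within max_mismatch.
oracle_trim <- function(read, adapter, max_mismatch = 0, min_overlap = 3) {
  L <- nchar(read)
  alen <- nchar(adapter)
  for (pos in seq_len(L)) {
    k <- min(alen, L - pos + 1)
    if (k < min_overlap) break
    d <- oracle_hamming(substr(read, pos, pos + k - 1), substr(adapter, 1, k))
    if (!is.na(d) && d <= max_mismatch)
      return(list(read = substr(read, 1, pos - 1), trimmed = TRUE))
  }
  list(read = read, trimmed = FALSE)
}

# Naive read assignment: compare the read against every canonical and every
# adenylated sequence; classify by the same published rules.
oracle_assign <- function(read, refset, max_mismatch = 0) {
  can_hits <- character(0)
  ade_hits <- character(0)
  for (i in seq_len(nrow(refset$canonical))) {
    d <- oracle_hamming(read, refset$canonical$sequence[i])
    if (!is.na(d) && d <= max_mismatch)
      can_hits <- c(can_hits, refset$canonical$mirna_id[i])
    d <- oracle_hamming(read, refset$adenylated$sequence[i])
    if (!is.na(d) && d <= max_mismatch)
      ade_hits <- c(ade_hits, refset$adenylated$mirna_id[i])
  }
  n <- length(can_hits) + length(ade_hits)
  if (n == 0) return(list(status = "unassigned", mirna_id = NA_character_))
  if (n > 1) return(list(status = "ambiguous", mirna_id = NA_character_))
  if (length(can_hits) == 1)
    list(status = "canonical", mirna_id = can_hits)
  else
    list(status = "adenylated", mirna_id = ade_hits)
}

# Naive per-sample counting over a list of read vectors.
oracle_count <- function(libraries, refset, max_mismatch = 0, adapter = "",
                         adapter_max_mismatch = 0) {
  ids <- refset$canonical$mirna_id
  can <- matrix(0L, length(ids), length(libraries),
                dimnames = list(ids, names(libraries)))
  ade <- can
  totals <- data.frame(sample = names(libraries), assigned = 0L,
                       ambiguous = 0L, unassigned = 0L)
  for (s in seq_along(libraries)) {
    for (read in libraries[[s]]) {
      if (nzchar(adapter))
        read <- oracle_trim(read, adapter, adapter_max_mismatch)$read
      a <- oracle_assign(read, refset, max_mismatch)
      if (a$status == "canonical") {
        can[a$mirna_id, s] <- can[a$mirna_id, s] + 1L
        totals$assigned[s] <- totals$assigned[s] + 1L
      } else if (a$status == "adenylated") {
        ade[a$mirna_id, s] <- ade[a$mirna_id, s] + 1L
        totals$assigned[s] <- totals$assigned[s] + 1L
      } else if (a$status == "ambiguous") {
        totals$ambiguous[s] <- totals$ambiguous[s] + 1L
      } else {
        totals$unassigned[s] <- totals$unassigned[s] + 1L
      }
    }
  }
  list(canonical = can, adenylated = ade, totals = totals)
}

# Write a small FASTA fixture and return its path.
write_fasta_fixture <- function(records, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  path <- file.path(dir, "ref.fa")
  writeLines(c(rbind(paste0(">", names(records)), unname(records))), path)
  path
}

# A tiny two-condition sample sheet.
sample_sheet <- function(reads = 1000L, reps = 2L,
                         conditions = c("ctrl", "dis")) {
  data.frame(
    sample_id = paste0(rep(conditions, each = reps), "_", seq_len(reps)),
    condition = rep(conditions, each = reps),
    reads = reads, stringsAsFactors = FALSE)
}
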