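# Dual-reference counting: every trimmed read is compared full-length
# (equal length, Hamming distance <= max_mismatch, default 0) against the
# canonical mature sequences and against a custom reference in which each
# mature sequence carries one extra 3' A. A read matching exactly one
# reference sequence is a canonical or adenylated count for that miRNA; reads
# hitting both references or several miRNAs are ambiguous; everything else is
# unassigned.

#' Construct a paired canonical / "+A" reference set
#'
#' @param canonical data.frame with columns `mirna_id`, `sequence` (DNA
#'   alphabet, unique ids).
#' @return object of class `reference_set`: `canonical`, `adenylated` (each
#'   canonical sequence plus one terminal A), and `collisions`, a data.frame
#'   of sequence clashes (`id1`, `id2`, `kind` with kind one of `duplicate`
#'   — two canonical sequences identical — or `canonical_equals_adenylated`
#'   — one canonical sequence equals another plus "A", so a mono-adenylated
#'   read of id2 is indistinguishable from a canonical read of id1).
#' @export
reference_set <- function(canonical) {
  stopifnot(is.data.frame(canonical),
            all(c("mirna_id", "sequence") %in% names(canonical)))
  if (nrow(canonical) == 0L) stop("empty reference")
  if (anyDuplicated(canonical$mirna_id))
    stop("duplicate miRNA ids in reference")
  if (any(!nzchar(canonical$sequence))) stop("empty sequence in reference")
  .check_dna(canonical$sequence, "reference")
  adenylated <- canonical
  adenylated$sequence <- paste0(canonical$sequence, "A")
  collisions <- .detect_collisions(canonical$mirna_id, canonical$sequence)
  structure(list(canonical = canonical, adenylated = adenylated,
                 collisions = collisions),
            class = "reference_set")
}

.detect_collisions <- function(ids, seqs) {
  out <- list()
  # duplicate canonical sequences
  dup_groups <- split(seq_along(seqs), seqs)
  for (g in dup_groups) {
    if (length(g) > 1L) {
      pairs <- utils::combn(g, 2L)
      for (j in seq_len(ncol(pairs)))
        out[[length(out) + 1L]] <-
          data.frame(id1 = ids[pairs[1L, j]], id2 = ids[pairs[2L, j]],
                     kind = "duplicate", stringsAsFactors = FALSE)
    }
  }
  # canonical(id1) == canonical(id2) + "A"
  plus_a <- paste0(seqs, "A")
  hit <- match(seqs, plus_a)
  for (i in which(!is.na(hit))) {
    out[[length(out) + 1L]] <-
      data.frame(id1 = ids[i], id2 = ids[hit[i]],
                 kind = "canonical_equals_adenylated",
                 stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(id1 = character(0), id2 = character(0),
                  kind = character(0), stringsAsFactors = FALSE)
}

#' Build the canonical and "+A" references from a mature miRNA FASTA
#'
#' @param mature_fasta path to the mature miRNA FASTA (RNA or DNA alphabet).
#' @param u_to_t convert U to T on input.
#' @return a [reference_set] with collisions annotated.
#' @export
build_references <- function(mature_fasta, u_to_t = TRUE) {
  reference_set(read_mirna_fasta(mature_fasta, u_to_t = u_to_t))
}

# Split a character vector of equal-alphabet strings, grouped by length, into
# a list of length -> list(idx = positions, mat = nchar x n character matrix).
.char_matrix_by_length <- function(x) {
  lens <- nchar(x)
  out <- list()
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    mat <- matrix(unlist(strsplit(x[idx], "", fixed = TRUE),
                         use.names = FALSE), nrow = L)
    out[[as.character(L)]] <- list(idx = idx, mat = mat)
  }
  out
}

#' Trim a 3' sequencing adapter from reads
#'
#' Scans each read 3'-ward for the leftmost occurrence of an adapter prefix of
#' length at least `min_overlap`, allowing up to `max_mismatch` substitutions,
#' and removes it together with everything downstream. Reads without a hit
#' are returned unchanged and flagged untrimmed (a status, not an error).
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param max_mismatch maximum Hamming distance of the matched adapter prefix.
#' @param min_overlap minimum adapter prefix length eligible for a hit.
#' @return list with `trimmed` (character vector) and `untrimmed` (logical).
#' @export
trim_adapter <- function(reads, adapter, max_mismatch = 0L, min_overlap = 3L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty when trimming")
  .check_dna(adapter, "adapter")
  achars <- strsplit(adapter, "", fixed = TRUE)[[1L]]
  alen <- length(achars)
  uniq <- unique(reads)
  cut_at <- rep.int(NA_integer_, length(uniq))   # leftmost hit position
  by_len <- .char_matrix_by_length(uniq)
  for (grp in by_len) {
    L <- nrow(grp$mat)
    pending <- seq_along(grp$idx)
    pos <- 1L
    while (length(pending) && pos <= L - min_overlap + 1L) {
      k <- min(alen, L - pos + 1L)
      mm <- colSums(grp$mat[pos:(pos + k - 1L), pending, drop = FALSE] !=
                      achars[seq_len(k)])
      hit <- mm <= max_mismatch
      if (any(hit)) {
        cut_at[grp$idx[pending[hit]]] <- pos
        pending <- pending[!hit]
      }
      pos <- pos + 1L
    }
  }
  trimmed_uniq <- ifelse(is.na(cut_at), uniq,
                         substr(uniq, 1L, cut_at - 1L))
  m <- match(reads, uniq)
  list(trimmed = trimmed_uniq[m], untrimmed = is.na(cut_at)[m])
}

#' Assign reads to canonical or adenylated reference sequences
#'
#' Each read is compared full-length (equal length only, Hamming distance
#' <= `max_mismatch`) against both references. Exactly one hit gives status
#' `canonical` or `adenylated` with the matched miRNA; hits in both sets or
#' to multiple miRNAs give `ambiguous` (with `priority = "canonical"`, a
#' single canonical hit beats adenylated hits); no hit gives `unassigned`.
#'
#' @param reads character vector of (trimmed) read sequences.
#' @param refset a [reference_set].
#' @param max_mismatch maximum Hamming distance (default 0, exact match).
#' @param priority `"none"` (ambiguous-discard, default) or `"canonical"`
#'   (canonical wins a canonical-vs-adenylated overlap).
#' @return data.frame with one row per read: `status` (canonical /
#'   adenylated / ambiguous / unassigned), `mirna_id` (NA unless assigned),
#'   `mismatches` (NA unless assigned), and `n_hits`.
#' @export
assign_reads <- function(reads, refset, max_mismatch = 0L,
                         priority = c("none", "canonical")) {
  stopifnot(inherits(refset, "reference_set"))
  priority <- match.arg(priority)
  uniq <- unique(reads)
  res <- .assign_unique(uniq, refset, max_mismatch, priority)
  m <- match(reads, uniq)
  out <- res[m, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Core assignment on unique read sequences.
.assign_unique <- function(uniq, refset, max_mismatch, priority) {
  n <- length(uniq)
  status <- rep.int("unassigned", n)
  mirna <- rep.int(NA_character_, n)
  mism <- rep.int(NA_integer_, n)
  nhits <- integer(n)
  ref_seq <- c(refset$canonical$sequence, refset$adenylated$sequence)
  ref_id <- c(refset$canonical$mirna_id, refset$adenylated$mirna_id)
  ref_status <- rep(c("canonical", "adenylated"),
                    times = c(nrow(refset$canonical), nrow(refset$adenylated)))
  if (max_mismatch == 0L) {
    # hash path: one lookup per set; multiplicity from duplicated sequences
    hits_of <- function(seqs, ids) {
      tab <- split(ids, seqs)
      tab[match(uniq, names(tab))]
    }
    can_hits <- hits_of(refset$canonical$sequence, refset$canonical$mirna_id)
    ade_hits <- hits_of(refset$adenylated$sequence, refset$adenylated$mirna_id)
    for (i in seq_len(n)) {
      ch <- can_hits[[i]]
      ah <- ade_hits[[i]]
      k <- length(ch) + length(ah)
      nhits[i] <- k
      if (k == 0L) next
      if (length(ch) == 1L && (length(ah) == 0L || priority == "canonical")) {
        status[i] <- "canonical"; mirna[i] <- ch; mism[i] <- 0L
      } else if (length(ch) == 0L && length(ah) == 1L) {
        status[i] <- "adenylated"; mirna[i] <- ah; mism[i] <- 0L
      } else {
        status[i] <- "ambiguous"
      }
    }
  } else {
    read_lens <- nchar(uniq)
    ref_by_len <- split(seq_along(ref_seq), nchar(ref_seq))
    by_len <- .char_matrix_by_length(uniq)
    for (grp in by_len) {
      L <- nrow(grp$mat)
      cand <- ref_by_len[[as.character(L)]]
      if (is.null(cand)) next
      hit_list <- vector("list", length(grp$idx))
      mm_list <- vector("list", length(grp$idx))
      for (r in cand) {
        rchars <- strsplit(ref_seq[r], "", fixed = TRUE)[[1L]]
        mm <- colSums(grp$mat != rchars)
        ok <- which(mm <= max_mismatch)
        for (j in ok) {
          hit_list[[j]] <- c(hit_list[[j]], r)
          mm_list[[j]] <- c(mm_list[[j]], mm[j])
        }
      }
      for (j in seq_along(grp$idx)) {
        i <- grp$idx[j]
        hits <- hit_list[[j]]
        nhits[i] <- length(hits)
        if (length(hits) == 0L) next
        st <- ref_status[hits]
        ids <- ref_id[hits]
        if (priority == "canonical" && sum(st == "canonical") == 1L) {
          w <- which(st == "canonical")
          status[i] <- "canonical"; mirna[i] <- ids[w]
          mism[i] <- as.integer(mm_list[[j]][w])
        } else if (length(hits) == 1L) {
          status[i] <- st; mirna[i] <- ids
          mism[i] <- as.integer(mm_list[[j]])
        } else {
          status[i] <- "ambiguous"
        }
      }
    }
  }
  data.frame(status = status, mirna_id = mirna, mismatches = mism,
             n_hits = nhits, stringsAsFactors = FALSE)
}

#' Assign a single read
#'
#' Scalar convenience wrapper around [assign_reads()].
#'
#' @inheritParams assign_reads
#' @param read a single read sequence.
#' @return one-row data.frame (see [assign_reads()]).
#' @export
assign_read <- function(read, refset, max_mismatch = 0L,
                        priority = c("none", "canonical")) {
  stopifnot(length(read) == 1L)
  assign_reads(read, refset, max_mismatch, priority)
}

#' Count canonical and adenylated reads per miRNA per sample
#'
#' Runs optional 3' adapter trimming and then [assign_reads()] over every
#' library, tallying canonical and adenylated counts per miRNA. The
#' conservation invariant assigned + ambiguous + unassigned = total reads
#' holds per sample (fractionally assigned reads count as assigned).
#'
#' @param libraries either a named list of character vectors of reads (one
#'   per sample), a named character vector of FASTQ paths, or a
#'   `smallrna_sim` object from [simulate_reads()].
#' @param refset a [reference_set].
#' @param max_mismatch maximum Hamming distance for assignment.
#' @param adapter 3' adapter to trim before assignment ("" = no trimming).
#' @param adapter_max_mismatch mismatches tolerated in the adapter match.
#' @param priority overlap policy passed to [assign_reads()].
#' @param multi `"discard"` (default): reads hitting several miRNAs are
#'   ambiguous; `"fractional"`: such reads contribute 1/k to each of the k
#'   hit miRNAs (counts become fractional).
#' @return object of class `count_table`: integer (or fractional) matrices
#'   `canonical` and `adenylated` (miRNA x sample) and a `totals` data.frame
#'   with per-sample `assigned`, `ambiguous`, `unassigned`, `untrimmed`,
#'   `total`.
#' @export
count_reads <- function(libraries, refset, max_mismatch = 0L, adapter = "",
                        adapter_max_mismatch = 0L,
                        priority = c("none", "canonical"),
                        multi = c("discard", "fractional")) {
  stopifnot(inherits(refset, "reference_set"))
  priority <- match.arg(priority)
  multi <- match.arg(multi)
  if (inherits(libraries, "smallrna_sim")) libraries <- libraries$reads
  if (is.character(libraries)) {
    paths <- libraries
    if (is.null(names(paths)))
      names(paths) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(paths))
    libraries <- lapply(paths, function(p) unname(read_fastq(p)))
  }
  if (is.null(names(libraries)) || any(!nzchar(names(libraries))))
    stop("libraries must be named by sample")
  ids <- refset$canonical$mirna_id
  samples <- names(libraries)
  can <- matrix(0, length(ids), length(samples),
                dimnames = list(ids, samples))
  ade <- can
  totals <- data.frame(sample = samples, assigned = 0, ambiguous = 0,
                       unassigned = 0, untrimmed = 0,
                       total = 0, stringsAsFactors = FALSE)
  for (s in seq_along(samples)) {
    reads <- libraries[[s]]
    totals$total[s] <- length(reads)
    if (length(reads) == 0L) next
    if (nzchar(adapter)) {
      tr <- trim_adapter(reads, adapter, adapter_max_mismatch)
      reads <- tr$trimmed
      totals$untrimmed[s] <- sum(tr$untrimmed)
    }
    uniq_tab <- table(reads)
    uniq <- names(uniq_tab)
    wts <- as.numeric(uniq_tab)
    res <- .assign_unique(uniq, refset, max_mismatch, priority)
    is_can <- res$status == "canonical"
    is_ade <- res$status == "adenylated"
    if (any(is_can)) {
      agg <- rowsum(wts[is_can], res$mirna_id[is_can])
      can[rownames(agg), s] <- can[rownames(agg), s] + agg[, 1L]
    }
    if (any(is_ade)) {
      agg <- rowsum(wts[is_ade], res$mirna_id[is_ade])
      ade[rownames(agg), s] <- ade[rownames(agg), s] + agg[, 1L]
    }
    amb <- res$status == "ambiguous"
    n_amb <- sum(wts[amb])
    if (multi == "fractional" && any(amb)) {
      frac <- .fractional_assign(uniq[amb], wts[amb], refset, max_mismatch)
      can[, s] <- can[, s] + frac$canonical
      ade[, s] <- ade[, s] + frac$adenylated
      totals$assigned[s] <- sum(wts[is_can | is_ade]) + n_amb
      n_amb <- 0
    } else {
      totals$assigned[s] <- sum(wts[is_can | is_ade])
    }
    totals$ambiguous[s] <- n_amb
    totals$unassigned[s] <- sum(wts[res$status == "unassigned"])
  }
  if (multi == "discard") {
    storage.mode(can) <- "integer"
    storage.mode(ade) <- "integer"
  }
  structure(list(canonical = can, adenylated = ade, totals = totals),
            class = "count_table")
}

# Split each multi-hit read's weight equally across all its hits.
.fractional_assign <- function(uniq, wts, refset, max_mismatch) {
  ids <- refset$canonical$mirna_id
  can <- stats::setNames(numeric(length(ids)), ids)
  ade <- can
  ref_seq <- c(refset$canonical$sequence, refset$adenylated$sequence)
  ref_id <- c(refset$canonical$mirna_id, refset$adenylated$mirna_id)
  ref_st <- rep(c("canonical", "adenylated"),
                times = c(nrow(refset$canonical), nrow(refset$adenylated)))
  for (i in seq_along(uniq)) {
    d <- .hamming_vs_refs(uniq[i], ref_seq)
    hits <- which(!is.na(d) & d <= max_mismatch)
    if (!length(hits)) next
    share <- wts[i] / length(hits)
    for (h in hits) {
      if (ref_st[h] == "canonical") can[ref_id[h]] <- can[ref_id[h]] + share
      else ade[ref_id[h]] <- ade[ref_id[h]] + share
    }
  }
  list(canonical = can, adenylated = ade)
}

# Hamming distance of one read against each reference sequence; NA when
# lengths differ.
.hamming_vs_refs <- function(read, ref_seq) {
  L <- nchar(read)
  d <- rep.int(NA_real_, length(ref_seq))
  same <- which(nchar(ref_seq) == L)
  if (!length(same)) return(d)
  rchars <- strsplit(read, "", fixed = TRUE)[[1L]]
  for (j in same) {
    d[j] <- sum(strsplit(ref_seq[j], "", fixed = TRUE)[[1L]] != rchars)
  }
  d
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d miRNAs x %d samples\n",
              nrow(x$canonical), ncol(x$canonical)))
  if (!is.null(x$totals)) {
    cat("per-sample totals:\n")
    print(x$totals, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d miRNAs (+A counterparts), %d collision(s)\n",
              nrow(x$canonical), nrow(x$collisions)))
  invisible(x)
}
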