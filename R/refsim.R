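#' Simulation configuration for synthetic small RNA-seq experiments
#'
#' Bundles and validates every knob of the ground-truth simulator: the sample
#' sheet, per-miRNA/per-condition mono-adenylation probabilities, abundance
#' weights, the 3' sequencing adapter, the per-base substitution error rate,
#' and the top-level seed from which all per-sample random streams are derived.
#'
#' @param samples data.frame with columns `sample_id`, `condition`, `reads`
#'   (reads per library, positive integer).
#' @param adenylation_prob probability that a sequenced molecule of a given
#'   miRNA carries one non-templated 3' A. Either a single number (all
#'   miRNAs, all conditions), a named vector over conditions, or a matrix
#'   with one row per miRNA (rownames = miRNA ids) and one column per
#'   condition (colnames = condition labels). All values in [0, 1].
#' @param abundance_weights positive per-miRNA sampling weights (named
#'   numeric, or NULL for uniform). Reads are drawn multinomially by weight.
#' @param adapter 3' adapter sequence appended to every insert (DNA alphabet),
#'   or "" for no adapter (the default).
#' @param error_rate per-base substitution probability in [0, 1); applied
#'   after adapter ligation. No indels are simulated.
#' @param read_length instrument read length; reads longer than this are
#'   truncated. NULL (default) means full read-through of insert + adapter.
#' @param seed integer seed; a fixed seed yields byte-identical outputs.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(samples,
                       adenylation_prob = 0.2,
                       abundance_weights = NULL,
                       adapter = "",
                       error_rate = 0,
                       read_length = NULL,
                       seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "condition", "reads") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (any(samples$reads <= 0) || any(samples$reads != round(samples$reads)))
    stop("reads_per_sample must be positive integers")
  p <- unlist(adenylation_prob)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("adenylation probabilities must lie in [0, 1]")
  if (!is.null(abundance_weights) && any(abundance_weights <= 0))
    stop("abundance weights must be > 0")
  if (!is.character(adapter) || length(adapter) != 1L)
    stop("adapter must be a single string (possibly empty)")
  if (nzchar(adapter)) .check_dna(adapter, "adapter")
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  structure(
    list(samples = samples,
         adenylation_prob = adenylation_prob,
         abundance_weights = abundance_weights,
         adapter = adapter,
         error_rate = error_rate,
         read_length = read_length,
         seed = as.integer(seed)),
    class = "sim_config")
}

.DNA <- c("A", "C", "G", "T")

.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("%s contains non-ACGT characters (first offender: %s)",
                 what, x[bad][1L]))
  invisible(x)
}

#' Convert RNA-alphabet sequences to DNA alphabet
#'
#' Mature miRNA sequences are often distributed in RNA alphabet (U); sequencing
#' reads are DNA-space. This helper uppercases and replaces U with T.
#'
#' @param x character vector of sequences.
#' @return character vector in the {A,C,G,T} alphabet.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# Derive one reproducible child seed per stream from a top-level seed.
.derive_seeds <- function(seed, n) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic mature miRNA reference
#'
#' Draws `n_mirnas` unique random sequences with lengths uniform in
#' `length_range` and builds the paired canonical / "+A" reference set. By
#' construction the set is collision-free: no two canonical sequences are
#' equal, and no canonical sequence equals another canonical sequence plus a
#' terminal A (which would make a mono-adenylated read ambiguous). A collision
#' can be injected deliberately to exercise downstream collision reporting.
#'
#' @param n_mirnas number of miRNAs (>= 1).
#' @param length_range integer pair, inclusive range of mature lengths in nt.
#' @param seed integer seed (deterministic output).
#' @param inject_collision if TRUE, appends one extra record whose sequence is
#'   the first canonical sequence plus "A" (a canonical-equals-adenylated
#'   collision), for testing collision detection.
#' @return a [reference_set] object.
#' @export
generate_reference <- function(n_mirnas, length_range = c(20L, 24L), seed = 1L,
                               inject_collision = FALSE) {
  if (n_mirnas < 1) stop("n_mirnas must be >= 1")
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            length_range[1] >= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  seqs <- character(0)
  taboo <- character(0)   # sequences and their +/- A variants already claimed
  len_opts <- seq.int(length_range[1], length_range[2])
  max_tries <- 1000L * n_mirnas + 1000L
  tries <- 0L
  while (length(seqs) < n_mirnas) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(
        "could not draw %d collision-free unique sequences of length %d-%d",
        n_mirnas, length_range[1], length_range[2]))
    len <- len_opts[sample.int(length(len_opts), 1L)]
    s <- paste(sample(.DNA, len, replace = TRUE), collapse = "")
    # collision-free: s, s+"A" and s-minus-terminal-A must all be unclaimed
    variants <- c(s, paste0(s, "A"), if (endsWith(s, "A")) substr(s, 1L, len - 1L))
    if (any(variants %in% taboo)) next
    seqs <- c(seqs, s)
    taboo <- c(taboo, variants)
  }
  ids <- sprintf("sim-miR-%03d", seq_len(n_mirnas))
  if (inject_collision) {
    ids <- c(ids, "sim-miR-collision")
    seqs <- c(seqs, paste0(seqs[1L], "A"))
  }
  reference_set(data.frame(mirna_id = ids, sequence = seqs,
                           stringsAsFactors = FALSE))
}

.aden_prob_matrix <- function(p, mirna_ids, conditions) {
  n <- length(mirna_ids)
  k <- length(conditions)
  if (is.matrix(p)) {
    if (is.null(rownames(p)) || is.null(colnames(p)))
      stop("adenylation_prob matrix needs miRNA rownames and condition colnames")
    missing_m <- setdiff(mirna_ids, rownames(p))
    if (length(missing_m))
      stop("adenylation_prob missing miRNAs: ", paste(missing_m, collapse = ", "))
    missing_c <- setdiff(conditions, colnames(p))
    if (length(missing_c))
      stop("adenylation_prob missing conditions: ",
           paste(missing_c, collapse = ", "))
    return(p[mirna_ids, conditions, drop = FALSE])
  }
  if (!is.null(names(p)) && all(conditions %in% names(p))) {
    return(matrix(rep(p[conditions], each = n), nrow = n,
                  dimnames = list(mirna_ids, conditions)))
  }
  if (length(p) == 1L) {
    return(matrix(p, n, k, dimnames = list(mirna_ids, conditions)))
  }
  stop("adenylation_prob must be scalar, condition-named vector, or matrix")
}

#' Simulate small RNA-seq libraries with known adenylation ground truth
#'
#' Each read is one mature miRNA sequence or that sequence plus one
#' non-templated 3' A. The miRNA is drawn multinomially from the abundance
#' weights; mono-adenylation is Bernoulli with the per-miRNA, per-condition
#' probability; the 3' adapter (if any) is then appended, the read truncated
#' at the instrument read length, and per-base substitution errors applied.
#' The returned truth records the pre-error labels, so with `error_rate = 0`
#' and no adapter the realized counts are exactly recoverable by exact
#' matching.
#'
#' @param refset a [reference_set].
#' @param config a [sim_config]. Every miRNA named in a matrix
#'   `adenylation_prob` must exist in `refset`.
#' @return a list of class `smallrna_sim` with elements `reads` (named list of
#'   per-sample character vectors), `truth` (list with per-miRNA x per-sample
#'   integer matrices `canonical` and `adenylated`), `samples`, and `config`.
#' @export
simulate_reads <- function(refset, config) {
  stopifnot(inherits(refset, "reference_set"), inherits(config, "sim_config"))
  ids <- refset$canonical$mirna_id
  if (length(ids) == 0L) stop("empty reference")
  smp <- config$samples
  conditions <- unique(smp$condition)
  pmat <- .aden_prob_matrix(config$adenylation_prob, ids, conditions)
  w <- config$abundance_weights
  if (is.null(w)) {
    w <- rep(1, length(ids))
  } else {
    if (!is.null(names(w))) {
      missing_w <- setdiff(ids, names(w))
      if (length(missing_w))
        stop("abundance_weights missing miRNAs: ",
             paste(missing_w, collapse = ", "))
      w <- w[ids]
    }
    if (length(w) != length(ids)) stop("abundance_weights length mismatch")
  }
  can_seq <- refset$canonical$sequence
  ade_seq <- refset$adenylated$sequence

  seeds <- .derive_seeds(config$seed, nrow(smp))
  old <- .save_rng()
  on.exit(.restore_rng(old))

  n_m <- length(ids)
  canon_counts <- matrix(0L, n_m, nrow(smp),
                         dimnames = list(ids, smp$sample_id))
  aden_counts <- canon_counts
  reads_out <- vector("list", nrow(smp))
  names(reads_out) <- smp$sample_id

  for (i in seq_len(nrow(smp))) {
    set.seed(seeds[i])
    n_reads <- smp$reads[i]
    cond <- smp$condition[i]
    mirna_idx <- sample.int(n_m, n_reads, replace = TRUE, prob = w)
    adenylated <- stats::runif(n_reads) < unname(pmat[mirna_idx, cond])
    canon_counts[, i] <- tabulate(mirna_idx[!adenylated], nbins = n_m)
    aden_counts[, i] <- tabulate(mirna_idx[adenylated], nbins = n_m)
    reads <- ifelse(adenylated, ade_seq[mirna_idx], can_seq[mirna_idx])
    if (nzchar(config$adapter)) reads <- paste0(reads, config$adapter)
    if (!is.null(config$read_length))
      reads <- substr(reads, 1L, config$read_length)
    if (config$error_rate > 0) reads <- .apply_errors(reads, config$error_rate)
    reads_out[[i]] <- reads
  }
  structure(list(reads = reads_out,
                 truth = list(canonical = canon_counts,
                              adenylated = aden_counts),
                 samples = smp,
                 config = config),
            class = "smallrna_sim")
}

# Substitution-only error model: each base flips to one of the other three
# bases with probability `rate`, independently.
.apply_errors <- function(reads, rate) {
  lens <- nchar(reads)
  chars <- strsplit(reads, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    # draw a uniform among the 3 alternative bases
    cur <- match(flat[hit], .DNA)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    flat[hit] <- .DNA[((cur - 1L + shift) %% 4L) + 1L]
  }
  # reassemble without a per-read loop
  grp <- rep.int(seq_along(reads), lens)
  unname(vapply(split(flat, grp), paste, character(1), collapse = ""))
}

#' Write simulated libraries and truth tables to disk
#'
#' Emits the reference FASTA (canonical and "+A"), one FASTQ per sample
#' (constant quality `I`), truth count tables as TSV, and the configuration
#' echoed as JSON. Output bytes are fully determined by the simulation object.
#'
#' @param sim a `smallrna_sim` from [simulate_reads()].
#' @param refset the [reference_set] used to simulate.
#' @param outdir output directory (created if needed).
#' @param gzip compress FASTQ files with gzip.
#' @return invisibly, a named character vector of the files written.
#' @export
write_simulation <- function(sim, refset, outdir, gzip = FALSE) {
  stopifnot(inherits(sim, "smallrna_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(reference = file.path(outdir, "reference.fa"))
  write_reference_fasta(refset, files["reference"])
  for (s in names(sim$reads)) {
    f <- file.path(outdir, paste0(s, if (gzip) ".fastq.gz" else ".fastq"))
    write_fastq(sim$reads[[s]], f, id_prefix = s, gzip = gzip)
    files[s] <- f
  }
  tf <- file.path(outdir, "truth_counts.tsv")
  write_count_table(
    structure(list(canonical = sim$truth$canonical,
                   adenylated = sim$truth$adenylated,
                   totals = NULL), class = "count_table"), tf)
  files["truth"] <- tf
  cf <- file.path(outdir, "config.json")
  cfg <- sim$config
  cfg$samples <- as.data.frame(cfg$samples)
  # named vectors must round-trip as JSON objects, not bare arrays
  for (fld in c("adenylation_prob", "abundance_weights")) {
    if (!is.null(names(cfg[[fld]])) && !is.matrix(cfg[[fld]]))
      cfg[[fld]] <- as.list(cfg[[fld]])
  }
  jsonlite::write_json(cfg, cf, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  files["config"] <- cf
  invisible(files)
}

#' Design a qPCR screen ground truth
#'
#' Builds the relative-expression matrix of a miRNome panel across three
#' groups (control, disease, disease+knockdown) in which a designed subset of
#' miRNAs is downregulated in disease and restored to control level on
#' knockdown of the driver, and (optionally) a decoy subset that is down in
#' disease but NOT restored. All other miRNAs sit at control level throughout.
#'
#' @param n_mirnas panel size.
#' @param n_down number of designed down-and-restored miRNAs.
#' @param n_decoy number of down-but-not-restored decoys.
#' @param fold_down fold change (< 1) of designed miRNAs in the disease group.
#' @param replicates named integer vector: replicates per group; names are the
#'   group labels (control / disease / knockdown, in that role order).
#' @param seed seed used to choose which miRNAs carry the designed effects.
#' @return list with `expression` (targets x samples matrix), `groups` (named
#'   character, sample -> group), `down_restored` and `decoys` (character
#'   vectors of miRNA ids).
#' @export
design_screen_truth <- function(n_mirnas = 200L, n_down = 20L, n_decoy = 0L,
                                fold_down = 0.25,
                                replicates = c(control = 3L, disease = 3L,
                                               knockdown = 3L),
                                seed = 1L) {
  stopifnot(n_down + n_decoy <= n_mirnas, length(replicates) == 3L,
            !is.null(names(replicates)))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  ids <- sprintf("panel-miR-%03d", seq_len(n_mirnas))
  chosen <- sample(ids, n_down + n_decoy)
  down <- chosen[seq_len(n_down)]
  decoys <- setdiff(chosen, down)
  grp_names <- names(replicates)
  sample_ids <- unlist(lapply(grp_names, function(g)
    paste0(g, "_", seq_len(replicates[[g]]))))
  groups <- stats::setNames(rep(grp_names, replicates), sample_ids)
  expr <- matrix(1, n_mirnas, length(sample_ids),
                 dimnames = list(ids, sample_ids))
  disease_cols <- groups == grp_names[2L]
  kd_cols <- groups == grp_names[3L]
  expr[down, disease_cols] <- fold_down
  expr[decoys, disease_cols] <- fold_down
  expr[decoys, kd_cols] <- fold_down   # decoys stay down on knockdown
  list(expression = expr, groups = groups,
       down_restored = down, decoys = decoys)
}

#' Simulate a qPCR Ct panel from true relative expression
#'
#' Converts a relative-expression matrix into cycle thresholds through the
#' log-linear qPCR model `Ct = baseline - log2(expression) + noise` and adds a
#' stable internal-control row (constant Ct up to the same Gaussian noise).
#' With `noise_sd = 0` the downstream 2^-ddCt computation recovers the
#' designed folds exactly.
#'
#' @param expression targets x samples matrix of true relative expression
#'   (strictly positive).
#' @param groups named character vector mapping sample id -> group label.
#' @param internal_control name of the internal-control row to add (e.g. U6).
#' @param baseline_ct Ct of a target at relative expression 1.
#' @param control_ct Ct of the internal control.
#' @param noise_sd Gaussian Ct noise standard deviation (cycles; default 0).
#' @param seed seed for the noise stream.
#' @return a [ct_table].
#' @export
simulate_qpcr_panel <- function(expression, groups,
                                internal_control = "U6",
                                baseline_ct = 25, control_ct = 15,
                                noise_sd = 0, seed = 1L) {
  if (any(!is.finite(expression)) || any(expression <= 0))
    stop("relative expression must be strictly positive and finite")
  if (is.null(colnames(expression)) || is.null(rownames(expression)))
    stop("expression matrix needs row (target) and column (sample) names")
  stopifnot(all(colnames(expression) %in% names(groups)))
  if (internal_control %in% rownames(expression))
    stop("internal control id clashes with a panel target")
  ct <- baseline_ct - log2(expression)
  ct <- rbind(ct, matrix(control_ct, 1L, ncol(ct),
                         dimnames = list(internal_control, colnames(ct))))
  if (noise_sd > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    ct <- ct + matrix(stats::rnorm(length(ct), 0, noise_sd), nrow(ct))
  }
  ct_table(ct, groups = groups[colnames(ct)],
           internal_control = internal_control)
}

#' Simulate an assay plate with known true ratios
#'
#' Emits paired supernatant/attached absorbances for the LDH cell-death
#' fraction and firefly/Renilla luminescence pairs with configurable true
#' values, one row per well per measurement kind, in the long plate format
#' consumed by the assay formulas.
#'
#' @param n_wells wells per group (>= 1).
#' @param death_fraction true relative cell death per group (named vector or
#'   scalar): supernatant absorbance = total x fraction.
#' @param total_absorbance total LDH absorbance per well.
#' @param luciferase_ratio true firefly/Renilla ratio per group.
#' @param renilla Renilla luminescence level.
#' @param noise_sd multiplicative Gaussian noise sd on each reading (0 = none).
#' @param groups group labels.
#' @param seed seed for the noise stream.
#' @return data.frame with columns `well`, `group`, `kind`, `value`.
#' @export
simulate_assay_plate <- function(n_wells = 3L,
                                 death_fraction = 0.25,
                                 total_absorbance = 1.0,
                                 luciferase_ratio = 2.0,
                                 renilla = 100,
                                 noise_sd = 0,
                                 groups = "control",
                                 seed = 1L) {
  if (n_wells < 1) stop("n_wells must be >= 1")
  df <- rep_len(death_fraction, length(groups))
  lr <- rep_len(luciferase_ratio, length(groups))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  rows <- list()
  for (g in seq_along(groups)) {
    for (wl in seq_len(n_wells)) {
      well <- sprintf("%s_w%02d", groups[g], wl)
      vals <- c(absorbance_supernatant = total_absorbance * df[g],
                absorbance_attached = total_absorbance * (1 - df[g]),
                firefly = renilla * lr[g],
                renilla = renilla)
      if (noise_sd > 0)
        vals <- vals * exp(stats::rnorm(length(vals), 0, noise_sd))
      rows[[length(rows) + 1L]] <-
        data.frame(well = well, group = groups[g], kind = names(vals),
                   value = unname(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
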