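# Dual-reference construction, adapter trimming, read assignment, counting.

# mature miR-7 mimic sequence used as a realistic fixture
MIR7 <- "TGGAAGACTAGTGATTTTGTT"

test_that("build_references appends one A per record and converts U to T", {
  fa <- write_fasta_fixture(c("hsa-miR-7-5p" = MIR7))
  ref <- build_references(fa)
  expect_equal(ref$adenylated$sequence, "TGGAAGACTAGTGATTTTGTTA")
  expect_equal(ref$canonical$mirna_id, "hsa-miR-7-5p")

  fa_rna <- write_fasta_fixture(c("hsa-miR-7-5p" = chartr("T", "U", MIR7)))
  expect_equal(build_references(fa_rna)$canonical$sequence, MIR7)
})

test_that("build_references reports collisions and rejects bad input", {
  fa <- write_fasta_fixture(c(x = "ACGTACGTACGTACGTACGT",
                              y = "ACGTACGTACGTACGTACGT"))
  ref <- build_references(fa)
  expect_equal(ref$collisions$kind, "duplicate")
  expect_setequal(c(ref$collisions$id1, ref$collisions$id2), c("x", "y"))

  fa2 <- write_fasta_fixture(c(x = "ACGTACGTACGTACGTACGTA",
                               y = "ACGTACGTACGTACGTACGT"))
  ref2 <- build_references(fa2)
  expect_equal(ref2$collisions$kind, "canonical_equals_adenylated")
  expect_equal(ref2$collisions$id1, "x")   # x == y + "A"
  expect_equal(ref2$collisions$id2, "y")

  fa3 <- write_fasta_fixture(c(a = MIR7, a = MIR7))
  expect_error(build_references(fa3), "duplicate ids")
  fa4 <- write_fasta_fixture(c(a = "ACGTNACGTACGTACGTACGT"))
  expect_error(build_references(fa4), "non-ACGT")
  empty <- tempfile(fileext = ".fa"); file.create(empty)
  expect_error(build_references(empty), "empty")
})

test_that("trim_adapter removes the leftmost adapter hit 3'-ward", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  # full adapter, exact
  tr <- trim_adapter(paste0(MIR7, adapter), adapter, max_mismatch = 0)
  expect_equal(tr$trimmed, MIR7)
  expect_false(tr$untrimmed)
  # partial adapter read-through (prefix only, >= min_overlap)
  tr2 <- trim_adapter(paste0(MIR7, substr(adapter, 1, 5)), adapter)
  expect_equal(tr2$trimmed, MIR7)
  # no adapter: unchanged and flagged
  tr3 <- trim_adapter(MIR7, adapter)
  expect_equal(tr3$trimmed, MIR7)
  expect_true(tr3$untrimmed)
  # one substitution tolerated at max_mismatch = 1
  mut <- adapter
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  expect_true(trim_adapter(paste0(MIR7, mut), adapter, 0)$untrimmed)
  expect_equal(trim_adapter(paste0(MIR7, mut), adapter, 1)$trimmed, MIR7)
})

test_that("trim_adapter agrees with a brute-force scan over cut positions", {
  adapter <- "TGGAATTCTCGG"
  set.seed(31)
  for (rep in 1:40) {
    insert <- paste(sample(c("A", "C", "G", "T"), sample(15:24, 1),
                           replace = TRUE), collapse = "")
    keep <- sample(0:nchar(adapter), 1)
    read <- paste0(insert, substr(adapter, 1, keep))
    if (runif(1) < 0.3 && nchar(read) > 4) {   # sprinkle a substitution
      p <- sample(nchar(read), 1)
      substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    for (mm in 0:1) {
      got <- trim_adapter(read, adapter, max_mismatch = mm)
      want <- oracle_trim(read, adapter, max_mismatch = mm)
      expect_identical(got$trimmed, want$read)
      expect_identical(got$untrimmed, !want$trimmed)
    }
  }
})

test_that("assign_read implements the mono-A reference semantics", {
  fa <- write_fasta_fixture(c(X = MIR7, Y = "CCCCCGGGGGAAAAATTTTTC"))
  ref <- build_references(fa)
  expect_equal(assign_read(MIR7, ref)$status, "canonical")
  expect_equal(assign_read(MIR7, ref)$mirna_id, "X")
  a1 <- assign_read(paste0(MIR7, "A"), ref)
  expect_equal(a1$status, "adenylated")
  expect_equal(a1$mirna_id, "X")
  # +AA is outside the mono-A reference design
  expect_equal(assign_read(paste0(MIR7, "AA"), ref)$status, "unassigned")
  # reads shorter than any reference are unassigned (no prefix matching)
  expect_equal(assign_read(substr(MIR7, 1, 18), ref)$status, "unassigned")
})

test_that("duplicate references give ambiguous; priority resolves overlap", {
  fa <- write_fasta_fixture(c(x = MIR7, y = MIR7))
  ref <- build_references(fa)
  expect_equal(assign_read(MIR7, ref)$status, "ambiguous")

  # canonical(X) == canonical(Y) + "A": the +1A read of Y collides with X
  fa2 <- write_fasta_fixture(c(X = paste0(MIR7, "A"), Y = MIR7))
  ref2 <- build_references(fa2)
  r <- paste0(MIR7, "A")
  expect_equal(assign_read(r, ref2)$status, "ambiguous")
  pc <- assign_read(r, ref2, priority = "canonical")
  expect_equal(pc$status, "canonical")
  expect_equal(pc$mirna_id, "X")
})

test_that("assignment with mismatches matches the naive oracle", {
  ref <- generate_reference(12, seed = 21)
  set.seed(99)
  pool <- c(ref$canonical$sequence, ref$adenylated$sequence)
  reads <- sample(pool, 120, replace = TRUE)
  # mutate a third of them at 1-2 positions
  mut_idx <- sample(length(reads), 40)
  for (i in mut_idx) {
    for (k in seq_len(sample(1:2, 1))) {
      p <- sample(nchar(reads[i]), 1)
      substr(reads[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
  }
  for (mm in 0:2) {
    got <- assign_reads(reads, ref, max_mismatch = mm)
    for (i in seq_along(reads)) {
      want <- oracle_assign(reads[i], ref, max_mismatch = mm)
      expect_identical(got$status[i], want$status)
      if (want$status %in% c("canonical", "adenylated"))
        expect_identical(got$mirna_id[i], want$mirna_id)
    }
  }
})

test_that("count_reads reproduces simulation truth exactly (round trip)", {
  ref <- generate_reference(10, seed = 13)
  cfg <- sim_config(sample_sheet(reads = 1000L), adenylation_prob = 0.3,
                    seed = 14)
  sim <- simulate_reads(ref, cfg)
  ct <- count_reads(sim, ref)
  expect_identical(unclass(ct$canonical), sim$truth$canonical)
  expect_identical(unclass(ct$adenylated), sim$truth$adenylated)
  expect_true(all(ct$totals$assigned + ct$totals$ambiguous +
                    ct$totals$unassigned == ct$totals$total))
  # round trip survives adapter read-through when trimming is enabled
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  cfg_a <- sim_config(sample_sheet(reads = 1000L), adenylation_prob = 0.3,
                      adapter = adapter, seed = 14)
  ct_a <- count_reads(simulate_reads(ref, cfg_a), ref, adapter = adapter)
  expect_identical(unclass(ct_a$adenylated), sim$truth$adenylated)
})

test_that("count_reads handles degenerate libraries and FASTQ files", {
  ref <- generate_reference(3, seed = 1)
  ct0 <- count_reads(list(s1 = character(0)), ref)
  expect_true(all(ct0$canonical == 0L) && all(ct0$adenylated == 0L))
  expect_equal(ct0$totals$total, 0L)

  reads <- rep(ref$adenylated$sequence[2], 57)
  ct1 <- count_reads(list(s1 = reads), ref)
  expect_equal(unname(ct1$adenylated[2, 1]), 57L)
  expect_equal(sum(ct1$adenylated) + sum(ct1$canonical), 57L)

  d <- withr::local_tempdir()
  fq <- file.path(d, "s1.fastq.gz")
  write_fastq(reads, fq, gzip = TRUE)
  ct2 <- count_reads(c(s1 = fq), ref)
  expect_identical(ct2$canonical, ct1$canonical)
  expect_identical(ct2$adenylated, ct1$adenylated)
  expect_error(count_reads(c(s1 = file.path(d, "nope.fastq")), ref),
               "no such FASTQ")
})

test_that("raising max_mismatch never decreases assigned reads", {
  ref <- generate_reference(8, seed = 23)
  cfg <- sim_config(sample_sheet(reads = 800L), adenylation_prob = 0.3,
                    error_rate = 0.03, seed = 24)
  sim <- simulate_reads(ref, cfg)
  assigned <- sapply(0:3, function(mm)
    sum(count_reads(sim, ref, max_mismatch = mm)$totals$assigned))
  expect_true(all(diff(assigned) >= 0))
})

test_that("fractional assignment splits multi-hit reads evenly", {
  fa <- write_fasta_fixture(c(x = MIR7, y = MIR7, z = "CCCCCGGGGGAAAAATTTTTC"))
  ref <- build_references(fa)
  ct <- count_reads(list(s1 = rep(MIR7, 10)), ref, multi = "fractional")
  expect_equal(unname(ct$canonical[c("x", "y"), 1]), c(5, 5))
  expect_equal(ct$totals$assigned, 10)
  expect_equal(ct$totals$ambiguous, 0)
  # default policy discards them as ambiguous
  ct_d <- count_reads(list(s1 = rep(MIR7, 10)), ref)
  expect_equal(sum(ct_d$canonical), 0L)
  expect_equal(ct_d$totals$ambiguous, 10)
})
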