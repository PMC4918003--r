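# Domain types, readers/writers, coordinate handling, germline filter.

write_probe_file <- function(path, rows, meta = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (meta) {
    writeLines(c("# lesion: L1", "# patient: P1", "# histology: LCIS"), con)
  }
  writeLines("probe\tchrom\tpos\tlogratio", con)
  writeLines(rows, con)
}

test_that("probe reader validates, sorts, and drops probes outside all arms", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # out of order + one probe beyond every arm (chrom 1 ends at 1e7)
  write_probe_file(f, c("P1\t1\t5000\t0.1", "P2\t1\t2000\t-0.2",
                        "P3\t2\t100\t0.0", "P4\t1\t99999999\t0.5"))
  expect_message(pp <- read_probe_profile(f, toy_gp), "dropped 1 probe")
  expect_s3_class(pp, "probe_profile")
  expect_equal(nrow(pp$probes), 3)
  expect_equal(pp$probes$pos, c(2000, 5000, 100))  # chrom 1 sorted, then 2
  expect_equal(pp$lesion, "L1")
  expect_equal(pp$histology, "LCIS")

  # well-formed 4-probe file inside arms round-trips in sorted order
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_probe_file(f2, c("P1\t1\t5000\t0.1", "P2\t1\t2000\t-0.2",
                         "P3\t2\t100\t0.0", "P4\t2\t50\t0.3"))
  pp2 <- read_probe_profile(f2, toy_gp)
  expect_equal(nrow(pp2$probes), 4)
  expect_equal(pp2$probes$pos, c(2000, 5000, 50, 100))
})

test_that("probe reader reports format and parse errors precisely", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe\tchrom\tpos", "P1\t1\t100"), f)
  expect_error(read_probe_profile(f, toy_gp), "missing required column")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_probe_file(f2, c("P1\t1\t5000\t0.1", "P2\t1\t6000\tnot_a_number"))
  expect_error(read_probe_profile(f2, toy_gp), "non-numeric log ratio.*line 2")
})

test_that("probe and mutation profiles round-trip through their writers", {
  set.seed(1)
  pp <- flat_probe_profile(n_per_arm = 20)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probe_profile(pp, f)
  pp2 <- read_probe_profile(f, toy_gp)
  expect_equal(pp2$probes, pp$probes)
  expect_equal(pp2[c("lesion", "patient", "histology")],
               pp[c("lesion", "patient", "histology")])

  mp <- make_mut_profile("L1", pos = c(10, 20, 30), pop_af = c(NA, 0.01, 0))
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(mp, fm)
  mp2 <- read_mutation_table(fm)
  expect_equal(mp2$mutations, mp$mutations)
})

test_that("mutation tables collapse duplicate keys and reject unknown classes", {
  mp <- make_mut_profile("L1", pos = 1:5)
  expect_equal(n_mutations(mp), 5)

  expect_warning(
    dup <- mutation_profile("L1", "P1", "LCIS", data.frame(
      chrom = "1", pos = c(1, 1, 2), ref = "A", alt = "T", gene = "G1")),
    "duplicate")
  expect_equal(n_mutations(dup), 2)

  # MAF-style synonyms map into the closed vocabulary
  syn <- mutation_profile("L1", "P1", "LCIS", data.frame(
    chrom = "1", pos = 1:3, ref = "A", alt = "T", gene = "G1",
    func_class = c("Missense_Mutation", "Silent", "Frame_Shift_Del")))
  expect_equal(syn$mutations$func_class,
               c("missense", "synonymous", "frameshift"))

  expect_error(
    mutation_profile("L1", "P1", "LCIS", data.frame(
      chrom = "1", pos = 1, ref = "A", alt = "T", gene = "G1",
      func_class = "mystery")),
    "unknown functional class")
})

test_that("germline filter keeps the threshold boundary and is idempotent", {
  mp <- make_mut_profile("L1", pos = c(1, 2, 3, 4),
                         pop_af = c(0, 0.04, 0.051, NA))
  flt <- filter_germline_suspects(mp, 0.05)
  expect_equal(n_mutations(flt), 3)  # 0, 0.04, NA (treated as 0) kept
  expect_false(3 %in% flt$mutations$pos)

  # frequency exactly at the threshold is kept (">" reading)
  at <- make_mut_profile("L1", pos = 1:2, pop_af = c(0.05, 0.0500001))
  expect_equal(filter_germline_suspects(at, 0.05)$mutations$pos, 1)

  expect_equal(filter_germline_suspects(flt, 0.05), flt)

  # threshold 0 retains only frequency-0 (and unobserved) mutations
  z <- filter_germline_suspects(mp, 0)
  expect_equal(sort(z$mutations$pos), c(1, 4))

  all0 <- make_mut_profile("L1", pos = 1:3, pop_af = 0)
  expect_equal(filter_germline_suspects(all0, 0.05), all0)
})

test_that("shared mutation counts are exact-key and symmetric", {
  a <- make_mut_profile("A", pos = c(1, 2, 3, 4))
  b <- make_mut_profile("B", pos = c(3, 4, 5))
  sab <- shared_mutations(a, b)
  sba <- shared_mutations(b, a)
  expect_equal(sab$m, 2)
  expect_equal(sab$m, sba$m)
  expect_equal(sab$n_a, 4)
  expect_equal(sab$n_b, 3)

  expect_equal(shared_mutations(a, make_mut_profile("C", pos = 10:12))$m, 0)
  expect_equal(shared_mutations(a, a)$m, 4)

  # same position, different allele is not a match
  b2 <- mutation_profile("B2", "P1", "LCIS", data.frame(
    chrom = "1", pos = 1, ref = "A", alt = "G", gene = "G1"))
  expect_equal(shared_mutations(a, b2)$m, 0)

  other <- make_mut_profile("X", pos = 1:2, patient = "P9")
  expect_warning(shared_mutations(a, other), "different patients")
})

test_that("cytoband loader builds a valid arm partition", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tband",
               "1\t0\t500\tp12", "1\t500\t1000\tp11",
               "1\t1000\t2000\tq11", "2\t0\t800\tq10"), f)
  gp <- read_cytoband_arms(f)
  expect_equal(gp$arms$arm, c("1p", "1q", "2q"))
  expect_equal(gp$arms$start, c(1, 1001, 1))  # 0-based starts shifted
  expect_equal(gp$arms$end, c(1000, 2000, 800))
})

test_that("genome partitions reject overlap and >2 arms per chromosome", {
  expect_error(genome_partition(data.frame(
    arm = c("1p", "1q"), chrom = "1", start = c(1, 50), end = c(100, 200))),
    "overlap")
  expect_error(genome_partition(data.frame(
    arm = c("1p", "1q", "1x"), chrom = "1",
    start = c(1, 101, 201), end = c(100, 200, 300))),
    "at most two arms")
})
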