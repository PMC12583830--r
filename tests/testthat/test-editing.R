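test_that("unedited reads give zero conversion and zero indels", {
  spec <- make_amplicon(c(4, 6, 8))
  reads <- rep(spec$amplicon, 1000)
  res <- quantify_reads(reads, spec)
  expect_equal(res$n_reads_total, 1000L)
  expect_equal(res$n_reads_eligible, 1000L)
  expect_equal(res$n_reads_indel, 0L)
  expect_equal(res$indel_pct, 0)
  pct <- res$per_position$pct_C_to_T
  expect_equal(pct[!is.na(pct)], rep(0, 3))
})

test_that("planted conversion and indel rates are recovered within 3 binomial SDs", {
  spec <- make_amplicon(c(4, 6, 8))
  n <- 10000
  reads <- gen_reads(spec, n_reads = n,
                     conversion = data.frame(position = 6, to = "T", rate = 0.3),
                     indel_rate = 0.05, indel_size_range = c(2, 2), seed = 101)
  res <- quantify_reads(reads, spec)
  # indel fraction
  sd_i <- sqrt(0.05 * 0.95 / n) * 100
  expect_lt(abs(res$indel_pct - 5), 3 * sd_i)
  # conversion among eligible (non-indel) reads
  n_el <- res$n_reads_eligible
  sd_c <- sqrt(0.3 * 0.7 / n_el) * 100
  got <- res$per_position$pct_C_to_T[6]
  expect_lt(abs(got - 30), 3 * sd_c)
  # substitution calls never use gapped reads
  expect_equal(res$n_reads_eligible + res$n_reads_indel +
                 res$n_reads_gapped_outside, res$n_reads_aligned)
  expect_equal(res$n_reads_aligned + res$n_reads_discarded, res$n_reads_total)
})

test_that("quantification is deterministic for a fixed read set", {
  spec <- make_amplicon(c(5, 7))
  reads <- gen_reads(spec, 500,
                     conversion = data.frame(position = 5, to = "T", rate = 0.4),
                     indel_rate = 0.1, seq_error_rate = 0.002, seed = 55)
  r1 <- quantify_reads(reads, spec)
  r2 <- quantify_reads(reads, spec)
  expect_identical(r1$base_counts, r2$base_counts)
  expect_identical(r1$per_position, r2$per_position)
})

test_that("planted conversion recovery holds across rates (coverage property)", {
  spec <- make_amplicon(6)
  n <- 2000
  hits <- 0L; trials <- 0L
  for (p in c(0.05, 0.3, 0.8)) {
    for (s in 1:8) {
      reads <- gen_reads(spec, n,
                         conversion = data.frame(position = 6, to = "T", rate = p),
                         seed = 7000 + 100 * s + round(100 * p))
      res <- quantify_reads(reads, spec)
      got <- res$per_position$pct_C_to_T[6] / 100
      trials <- trials + 1L
      if (abs(got - p) <= 3 * sqrt(p * (1 - p) / n)) hits <- hits + 1L
    }
  }
  expect_gte(hits / trials, 0.95)
})

test_that("reverse-strand protospacers reproduce the forward result exactly", {
  spec <- make_amplicon(c(4, 6), len = 90, protospacer_start = 25)
  reads <- gen_reads(spec, 3000,
                     conversion = data.frame(position = c(4, 6), to = "T",
                                             rate = c(0.1, 0.4)),
                     indel_rate = 0.04, seed = 77)
  fwd <- quantify_reads(reads, spec)

  amp_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spec$amplicon)))
  start_rc <- nchar(spec$amplicon) - spec$protospacer_start -
    spec$protospacer_length + 2L
  spec_rc <- amplicon_spec(amp_rc, protospacer_start = start_rc, strand = "-")
  expect_equal(spec_rc$protospacer, spec$protospacer)
  rev <- quantify_reads(Biostrings::reverseComplement(reads), spec_rc)
  expect_equal(rev$base_counts, fwd$base_counts)
  expect_equal(rev$per_position, fwd$per_position)
  expect_equal(rev$n_reads_indel, fwd$n_reads_indel)
})

test_that("short reads are discarded and empty read sets error", {
  spec <- make_amplicon(6)
  reads <- c(rep(spec$amplicon, 10), substr(spec$amplicon, 1, 20))
  res <- quantify_reads(reads, spec)
  expect_equal(res$n_reads_discarded, 1L)
  expect_equal(res$n_reads_aligned, 10L)
  expect_error(quantify_reads(Biostrings::DNAStringSet(), spec),
               class = "fitscan_error_empty_reads")
})

test_that("product purity returns normalized fractions of planted products", {
  spec <- make_amplicon(6)
  # all converted reads are C->G at position 6
  reads <- gen_reads(spec, 2000,
                     conversion = data.frame(position = 6, to = "G", rate = 0.5),
                     seed = 5)
  res <- quantify_reads(reads, spec)
  pur <- product_purity(res, 6)
  expect_equal(unname(pur[c("T", "G", "A")]), c(0, 1, 0))

  # planted T:G:A = 1:8:1
  reads2 <- gen_reads(spec, 10000,
                      conversion = data.frame(position = 6, to = c("T", "G", "A"),
                                              rate = c(0.05, 0.40, 0.05)),
                      seed = 6)
  res2 <- quantify_reads(reads2, spec)
  pur2 <- product_purity(res2, 6)
  expect_equal(sum(pur2), 1)
  n_conv <- sum(res2$base_counts[c("T", "G", "A"), 6])
  for (frac in list(c("T", 0.1), c("G", 0.8), c("A", 0.1))) {
    p <- as.numeric(frac[2])
    expect_lt(abs(pur2[frac[1]] - p), 3 * sqrt(p * (1 - p) / n_conv))
  }
  # no converted reads -> explicit error
  clean <- quantify_reads(rep(spec$amplicon, 50), spec)
  expect_error(product_purity(clean, 6), class = "fitscan_error_no_converted_reads")
})

test_that("window profiles average across sites with tracked denominators", {
  spec1 <- make_amplicon(6, seed = 21)
  spec2 <- make_amplicon(c(6, 9), seed = 22)
  r1 <- quantify_reads(gen_reads(spec1, 1500,
    conversion = data.frame(position = 6, to = "T", rate = 0.10), seed = 1), spec1)
  r2 <- quantify_reads(gen_reads(spec2, 1500,
    conversion = data.frame(position = 6, to = "T", rate = 0.30), seed = 2), spec2)

  # one site: the profile is that site's conversion vector
  p1 <- window_profile(list(r1))
  expect_equal(p1$mean_pct, r1$per_position$pct_C_to_T)

  prof <- window_profile(list(r1, r2))
  expect_equal(prof$n_sites[6], 2L)
  expect_equal(prof$mean_pct[6],
               mean(c(r1$per_position$pct_C_to_T[6],
                      r2$per_position$pct_C_to_T[6])))
  # position 9 is editable only at site 2: denominator excludes site 1
  expect_equal(prof$n_sites[9], 1L)
  expect_equal(prof$mean_pct[9], r2$per_position$pct_C_to_T[9])
  # exact two-site mean sanity: (10 + 30) / 2 = 20 within sampling noise
  expect_lt(abs(prof$mean_pct[6] - 20), 4)
})

test_that("window activity planted at positions 4-8 stays confined there", {
  specs <- lapply(1:6, function(i) make_amplicon(c(2, 4, 5, 6, 7, 8, 11, 15),
                                                 seed = 30 + i))
  results <- lapply(seq_along(specs), function(i) {
    conv <- data.frame(position = c(4, 5, 6, 7, 8), to = "T",
                       rate = c(0.2, 0.35, 0.4, 0.35, 0.2))
    quantify_reads(gen_reads(specs[[i]], 800, conversion = conv,
                             seq_error_rate = 0.001, seed = 400 + i),
                   specs[[i]])
  })
  prof <- window_profile(results)
  inside <- prof$mean_pct[4:8]
  outside <- prof$mean_pct[setdiff(which(!is.na(prof$mean_pct)), 4:8)]
  expect_gt(min(inside), max(outside))
})

test_that("editing results round-trip to TSV with two-decimal percentages", {
  spec <- make_amplicon(6)
  res <- quantify_reads(gen_reads(spec, 300,
    conversion = data.frame(position = 6, to = "T", rate = 0.25), seed = 9), spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_editing_tsv(res, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 20L)
  expect_equal(back$pct_C_to_T[6], round(res$per_position$pct_C_to_T[6], 2))
})

test_that("FASTQ reads round-trip through write and read", {
  spec <- make_amplicon(5)
  reads <- gen_reads(spec, 25, seed = 3)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_reads(reads, path)
  back <- read_fastq_reads(path)
  expect_equal(as.character(back), as.character(reads), ignore_attr = TRUE)
})
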