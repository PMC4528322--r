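test_that("well-formed records load, inconsistent lineage rows are rejected with row numbers", {
  rec <- count_fixture(n_snps = 1, reps_per_family = 1)
  expect_equal(nrow(validate_counts(rec)), 4L)

  bad <- rec
  bad$lineage[1] <- "European"  # AE maternal must be Africanized
  out <- suppressMessages(validate_counts(bad))
  expect_equal(nrow(out), 3L)
  expect_equal(dropped_sites(out)$row, 1L)
  expect_equal(dropped_sites(out)$reason, "lineage_inconsistent_with_family_parent")

  expect_error(validate_counts(dplyr::mutate(rec, family = "XX")), "unknown family")
  expect_error(validate_counts(dplyr::mutate(rec, sample_group = "pupae")),
               "unknown sample_group")
  expect_error(validate_counts(dplyr::mutate(rec, count = -1)), "non-negative")
  dup <- dplyr::bind_rows(rec, rec[1, ])
  expect_error(validate_counts(dup), "duplicated")
})

test_that("records at SNPs absent from the informative table are rejected", {
  rec <- count_fixture(n_snps = 2, reps_per_family = 1)
  snps <- tibble::tibble(
    family = rep(c("AE", "EA"), each = 1), chrom = "chr1", pos = 100,
    transcript_id = "tx1",
    maternal_allele = c("A", "G"), paternal_allele = c("G", "A"),
    maternal_lineage = c("Africanized", "European"),
    paternal_lineage = c("European", "Africanized"))
  out <- suppressMessages(validate_counts(rec, snps = snps))
  expect_true(all(out$pos == 100))
  expect_true(all(dropped_sites(out)$reason == "snp_not_informative"))
})

test_that("counts round-trip through TSV write and load unchanged", {
  sim <- simulate_dataset(sim_config(n_transcripts = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(sim$counts, path)
  back <- read_allele_counts(path)
  expect_equal(strip_meta(back),
               as.data.frame(dplyr::mutate(sim$counts, pos = as.integer(pos),
                                           count = as.numeric(count))))
})

test_that("coverage filtering drops cells below the threshold and matches a record-wise oracle", {
  # a 4+5 cell is dropped at min_total = 10
  rec <- count_fixture(n_snps = 1, reps_per_family = 2,
                       counts = c(4L, 5L, rep(20L, 6)))
  out <- filter_counts(rec, min_total_per_snp_library = 10,
                       min_libraries_per_family = 1)
  expect_equal(nrow(out), 6L)
  expect_equal(filter_report(out)$n_dropped_low_coverage, 2L)

  # min_total = 0 is the identity
  out0 <- filter_counts(rec, min_total_per_snp_library = 0,
                        min_libraries_per_family = 1)
  expect_equal(nrow(out0), nrow(rec))
  expect_equal(filter_report(out0)$n_dropped_low_coverage, 0L)

  expect_error(filter_counts(rec, min_total_per_snp_library = -1), "non-negative")

  # randomized fixture vs brute-force filter applied record-wise
  set.seed(42)
  sim <- simulate_dataset(sim_config(n_transcripts = 15, mean_depth = 12, seed = 8))
  rec2 <- sim$counts
  thr <- list(total = 15, snps = 2, libs = 2)
  out2 <- filter_counts(rec2, thr$total, thr$snps, thr$libs)

  cell_key <- function(x) paste(x$transcript_id, x$chrom, x$pos, x$replicate_id)
  totals <- tapply(rec2$count, cell_key(rec2), sum)
  keep1 <- rec2[totals[cell_key(rec2)] >= thr$total, ]
  keep_tx <- logical(nrow(keep1))
  for (i in seq_len(nrow(keep1))) {
    sub <- keep1[keep1$transcript_id == keep1$transcript_id[i] &
                   keep1$sample_group == keep1$sample_group[i], ]
    keep_tx[i] <- length(unique(paste(sub$chrom, sub$pos))) >= thr$snps &&
      length(unique(sub$replicate_id[sub$family == "AE"])) >= thr$libs &&
      length(unique(sub$replicate_id[sub$family == "EA"])) >= thr$libs
  }
  oracle <- keep1[keep_tx, ]
  expect_equal(nrow(out2), nrow(oracle))
  expect_setequal(
    paste(cell_key(out2), out2$parent),
    paste(cell_key(oracle), oracle$parent))
  rep2 <- filter_report(out2)
  expect_equal(rep2$n_input_records,
               rep2$n_retained_records + rep2$n_dropped_low_coverage +
                 rep2$n_dropped_few_snps)
})

test_that("filtering is monotone: raising any threshold never grows the retained set", {
  sim <- simulate_dataset(sim_config(n_transcripts = 10, mean_depth = 15, seed = 21))
  key <- function(x) paste(x$transcript_id, x$chrom, x$pos, x$replicate_id, x$parent)
  for (thr in list(c(5, 1, 1), c(10, 1, 1), c(10, 2, 1), c(10, 2, 2), c(20, 2, 2))) {
    loose <- filter_counts(sim$counts, thr[1], thr[2], thr[3])
    tight <- filter_counts(sim$counts, thr[1] + 5, thr[2] + 1, thr[3] + 1)
    expect_true(all(key(tight) %in% key(loose)))
  }
})

test_that("pooled family ratios equal the brute-force summation oracle and hand values", {
  # symmetric totals: maternal {30, 20}, paternal {25, 25} -> R_AE = 0.5
  rec <- count_fixture(n_snps = 1, reps_per_family = 2,
                       counts = c(30L, 25L, 20L, 25L, 30L, 25L, 20L, 25L))
  r <- family_ratios(rec)
  expect_equal(r$R_AE, 0.5)

  # single SNP, maternal 80 / paternal 20 -> R = 0.8
  rec2 <- count_fixture(n_snps = 1, reps_per_family = 1,
                        counts = c(80L, 20L, 80L, 20L))
  r2 <- family_ratios(rec2)
  expect_equal(r2$R_AE, 0.8)
  expect_equal(r2$R_EA, 0.8)

  # 3 SNPs x 2 replicates: pooled ratio equals a sum over raw rows
  set.seed(5)
  rec3 <- count_fixture(n_snps = 3, reps_per_family = 2,
                        counts = sample(5:60, 24, TRUE))
  r3 <- family_ratios(rec3)
  for (fam in c("AE", "EA")) {
    sub <- rec3[rec3$family == fam, ]
    expect_equal(r3[[paste0("R_", fam)]],
                 sum(sub$count[sub$parent == "maternal"]) / sum(sub$count))
    expect_equal(r3[[paste0("Q_", fam)]],
                 sum(sub$count[sub$lineage == "Africanized"]) / sum(sub$count))
  }
})

test_that("ratio complementarity and the family-lineage identity hold on simulated data", {
  sim <- simulate_dataset(sim_config(
    n_transcripts = 20,
    class_proportions = c(null = .4, maternal = .2, lineage_A = .2, asym_maternal_EA = .2),
    seed = 17))
  rec <- sim$counts
  r <- family_ratios(rec)
  for (fam in c("AE", "EA")) {
    sub <- split(rec, paste(rec$transcript_id, rec$sample_group))
    for (s in sub) {
      ss <- s[s$family == fam, ]
      if (sum(ss$count) == 0) next
      rm <- sum(ss$count[ss$parent == "maternal"]) / sum(ss$count)
      rp <- sum(ss$count[ss$parent == "paternal"]) / sum(ss$count)
      expect_equal(rm + rp, 1)
    }
  }
  # in AE the maternal ratio is the Africanized ratio; in EA its complement
  expect_equal(r$R_AE, r$Q_AE)
  expect_equal(r$R_EA, 1 - r$Q_EA)
  expect_true(all(r$R_AE >= 0 & r$R_AE <= 1, na.rm = TRUE))
})

test_that("a zero-total family yields NA ratios rather than an error", {
  rec <- count_fixture(n_snps = 1, reps_per_family = 1,
                       counts = c(50L, 30L, 0L, 0L))
  r <- family_ratios(rec)
  expect_equal(r$R_AE, 0.625)
  expect_true(is.na(r$R_EA))
})
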