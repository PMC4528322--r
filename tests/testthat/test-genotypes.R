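test_that("all six biallelic queen x drone configurations yield exactly the two informative ones", {
  # enumeration oracle: queen in {aa, ab, bb}, drone in {a, b}
  a <- "A"; b <- "G"
  configs <- list(
    list(queen = c(a, a), drone = a, informative = FALSE),
    list(queen = c(a, a), drone = b, informative = TRUE, mat = a, pat = b),
    list(queen = c(a, b), drone = a, informative = FALSE),
    list(queen = c(a, b), drone = b, informative = FALSE),
    list(queen = c(b, b), drone = a, informative = TRUE, mat = b, pat = a),
    list(queen = c(b, b), drone = b, informative = FALSE)
  )
  sites <- purrr::imap_dfr(configs, function(cf, i) {
    site(pos = 100 * i, queen = cf$queen, drone = cf$drone)
  })
  out <- suppressMessages(select_informative_snps(sites))
  expect_equal(nrow(out), 2L)
  expect_setequal(out$pos, c(200, 500))
  kept <- configs[c(2, 5)]
  for (k in seq_along(kept)) {
    row <- out[out$pos == c(200, 500)[k], ]
    expect_equal(row$maternal_allele, kept[[k]]$mat)
    expect_equal(row$paternal_allele, kept[[k]]$pat)
  }
  # AE family: maternal lineage is Africanized
  expect_true(all(out$maternal_lineage == "Africanized"))
  expect_true(all(out$paternal_lineage == "European"))
})

test_that("selection is idempotent, order-independent, and parental alleles always differ", {
  set.seed(71)
  bases <- c("A", "C", "G", "T")
  n <- 60
  sites <- tibble::tibble(
    family = sample(c("AE", "EA"), n, TRUE),
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    pos = sample(1:5000, n),
    queen_a1 = sample(bases, n, TRUE),
    queen_a2 = sample(bases, n, TRUE),
    drone_allele = sample(bases, n, TRUE),
    transcript_id = sample(paste0("tx", 1:8), n, TRUE)
  )
  out1 <- suppressMessages(select_informative_snps(sites))
  out2 <- suppressMessages(select_informative_snps(sites[sample(n), ]))
  expect_equal(strip_meta(out1), strip_meta(out2))
  expect_true(all(out1$maternal_allele != out1$paternal_allele))
  # EA rows have European mothers
  expect_true(all(out1$maternal_lineage[out1$family == "EA"] == "European"))
  # retained set matches the configuration rule applied row-wise
  manual <- sites$queen_a1 == sites$queen_a2 & sites$drone_allele != sites$queen_a1
  expect_equal(nrow(out1), sum(manual))
})

test_that("missing genotypes are skipped with a reason; heterozygous drones abort", {
  sites <- dplyr::bind_rows(
    site(pos = 100),
    site(pos = 200, queen = c(NA, "A")),
    site(pos = 300, drone = NA)
  )
  out <- suppressMessages(select_informative_snps(sites))
  expect_equal(out$pos, 100)
  expect_equal(sort(dropped_sites(out)$pos), c(200, 300))
  expect_true(all(dropped_sites(out)$reason == "missing_genotype"))

  het <- site(pos = 400, drone = "A/G")
  expect_error(select_informative_snps(het), "haploid")
  # diploid-style homozygous drone calls are accepted as the single allele
  hom <- site(pos = 500, queen = c("A", "A"), drone = "G/G")
  out2 <- select_informative_snps(hom)
  expect_equal(out2$paternal_allele, "G")
})

test_that("multi-allelic sites are dropped entirely", {
  sites <- dplyr::bind_rows(
    site(pos = 100, queen = c("A", "C"), drone = "G"),  # 3 alleles + het queen
    site(pos = 200, queen = c("A", "A"), drone = "G")
  )
  out <- suppressMessages(select_informative_snps(sites))
  expect_equal(out$pos, 200)
  expect_true("multiallelic" %in% dropped_sites(out)$reason)
})

test_that("family pairing equals a brute-force join on (chrom, pos, allele set)", {
  set.seed(13)
  mk <- function(fam, n, pos_pool) {
    pos <- sample(pos_pool, n)
    mat <- sample(c("A", "C", "G", "T"), n, TRUE)
    pat <- vapply(mat, function(m) sample(setdiff(c("A", "C", "G", "T"), m), 1), "")
    tibble::tibble(family = fam, chrom = "chr1", pos = pos,
                   transcript_id = NA_character_,
                   maternal_allele = mat, paternal_allele = unname(pat),
                   maternal_lineage = if (fam == "AE") "Africanized" else "European",
                   paternal_lineage = if (fam == "AE") "European" else "Africanized")
  }
  ae <- mk("AE", 100, 1:150)
  ea <- mk("EA", 100, 1:150)
  out <- suppressMessages(intersect_families(ae, ea))

  # independent join oracle
  key <- function(x) paste(x$chrom, x$pos,
                           pmin(x$maternal_allele, x$paternal_allele),
                           pmax(x$maternal_allele, x$paternal_allele))
  paired_oracle <- intersect(key(ae), key(ea))
  ae_pos_only <- setdiff(ae$pos, ea$pos)
  ea_pos_only <- setdiff(ea$pos, ae$pos)
  expect_equal(sum(out$status == "paired"), length(paired_oracle))
  expect_setequal(out$pos[out$status == "AE_only"], ae_pos_only)
  expect_setequal(out$pos[out$status == "EA_only"], ea_pos_only)
  # shared positions with discordant allele pairs are excluded, not paired
  shared <- intersect(ae$pos, ea$pos)
  set_of <- function(x, p) {
    r <- x[x$pos == p, ]
    sort(c(r$maternal_allele, r$paternal_allele))
  }
  mismatch <- shared[vapply(shared, function(p) {
    !identical(set_of(ae, p), set_of(ea, p))
  }, logical(1))]
  expect_setequal(dropped_sites(out)$pos, mismatch)
  expect_equal(sum(out$status == "paired"), length(shared) - length(mismatch))
  expect_equal(nrow(out) + nrow(dropped_sites(out)),
               length(union(ae$pos, ea$pos)))
})

test_that("simulated parental VCFs round-trip through reading and selection", {
  cfg <- sim_config(n_transcripts = 6, snp_lambda = 1, seed = 99)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  for (fam in c("AE", "EA")) {
    sites <- read_parental_vcf(file.path(dir, sprintf("parents_%s.vcf", fam)),
                               queen_sample = paste0("queen_", fam),
                               drone_sample = paste0("drone_", fam),
                               family = fam)
    out <- select_informative_snps(sites)
    truth <- dplyr::arrange(sim$snps[sim$snps$family == fam, ], chrom, pos)
    expect_equal(nrow(out), nrow(truth))  # every simulated site is informative
    expect_equal(out$pos, truth$pos)
    expect_equal(out$maternal_allele, truth$maternal_allele)
    expect_equal(out$paternal_allele, truth$paternal_allele)
  }
})
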