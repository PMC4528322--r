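#' Configuration for the reciprocal-cross simulator
#'
#' Defaults reproduce the study design the package targets: two reciprocal
#' families (AE: Africanized mother, EA: European mother), pooled larvae
#' (2 libraries per family), pooled adults (2 per family) and individual
#' brains (3 per family), biallelic SNPs with a 1:1 maternal:paternal read
#' expectation under the null.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param class_proportions Named proportions over the truth classes
#'   `null`, `maternal`, `paternal`, `lineage_A`, `lineage_E`,
#'   `asym_maternal_AE`, `asym_maternal_EA`; must sum to 1.
#' @param theta_m Expected maternal read fraction for parent-biased classes
#'   (default 0.8; paternal classes use `1 - theta_m`).
#' @param theta_l Expected Africanized read fraction for lineage-biased
#'   classes (default 0.8).
#' @param snp_lambda SNPs per transcript are `1 + Poisson(snp_lambda)`
#'   (default 2).
#' @param replicates Named list: libraries per family for each sample
#'   group. Default `list(larvae = c(AE = 2, EA = 2), adults = c(AE = 2,
#'   EA = 2), brains = c(AE = 3, EA = 3))`.
#' @param mean_depth Mean total reads per SNP per library (default 50).
#' @param depth_size Negative-binomial size (dispersion) of the total depth
#'   (default 8; variance `mu + mu^2/size`).
#' @param rho Beta-binomial overdispersion of the allelic fraction within a
#'   (SNP, library) cell (default 0.02; 0 gives pure binomial sampling).
#' @param mapping_bias Probability that a read carrying the Africanized
#'   allele is lost, emulating alignment to a European-derived reference
#'   (default 0; in `[0, 1)`).
#' @param seed Default RNG seed used by [simulate_dataset()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 500,
                       class_proportions = c(null = 1, maternal = 0, paternal = 0,
                                             lineage_A = 0, lineage_E = 0,
                                             asym_maternal_AE = 0, asym_maternal_EA = 0),
                       theta_m = 0.8,
                       theta_l = 0.8,
                       snp_lambda = 2,
                       replicates = list(larvae = c(AE = 2, EA = 2),
                                         adults = c(AE = 2, EA = 2),
                                         brains = c(AE = 3, EA = 3)),
                       mean_depth = 50,
                       depth_size = 8,
                       rho = 0.02,
                       mapping_bias = 0,
                       seed = 1L) {
  classes <- c("null", "maternal", "paternal", "lineage_A", "lineage_E",
               "asym_maternal_AE", "asym_maternal_EA")
  props <- setNames(rep(0, length(classes)), classes)
  assert_tokens(names(class_proportions), classes, "truth class")
  props[names(class_proportions)] <- class_proportions
  if (abs(sum(props) - 1) > 1e-8) abort("class proportions must sum to 1")
  if (any(props < 0)) abort("class proportions must be non-negative")
  if (theta_m <= 0 || theta_m >= 1 || theta_l <= 0 || theta_l >= 1) {
    abort("theta_m and theta_l must lie in (0, 1)")
  }
  if (mean_depth <= 0) abort("mean_depth must be positive")
  if (mapping_bias < 0 || mapping_bias >= 1) abort("mapping_bias must lie in [0, 1)")
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  assert_tokens(names(replicates), .sample_groups, "sample_group")
  structure(list(
    n_transcripts = n_transcripts, class_proportions = props,
    theta_m = theta_m, theta_l = theta_l, snp_lambda = snp_lambda,
    replicates = replicates, mean_depth = mean_depth, depth_size = depth_size,
    rho = rho, mapping_bias = mapping_bias, seed = seed
  ), class = "sim_config")
}

# Expected maternal read fraction per family for each truth class.
# Lineage classes translate through the family-lineage mapping: the
# maternal allele is Africanized only in family AE.
class_maternal_fractions <- function(class, theta_m, theta_l) {
  f_AE <- dplyr::case_when(
    class == "null" ~ 0.5,
    class == "maternal" ~ theta_m,
    class == "paternal" ~ 1 - theta_m,
    class == "lineage_A" ~ theta_l,
    class == "lineage_E" ~ 1 - theta_l,
    class == "asym_maternal_AE" ~ theta_m,
    class == "asym_maternal_EA" ~ 0.5
  )
  f_EA <- dplyr::case_when(
    class == "null" ~ 0.5,
    class == "maternal" ~ theta_m,
    class == "paternal" ~ 1 - theta_m,
    class == "lineage_A" ~ 1 - theta_l,
    class == "lineage_E" ~ theta_l,
    class == "asym_maternal_AE" ~ 0.5,
    class == "asym_maternal_EA" ~ theta_m
  )
  tibble::tibble(exp_R_AE = f_AE, exp_R_EA = f_EA)
}

#' Simulate a reciprocal-cross allele-count dataset with known truth
#'
#' Draws, for each transcript, a truth class, a number of SNPs and then,
#' for every (SNP, library) cell, a negative-binomial total depth and a
#' beta-binomial maternal count at the class- and family-specific expected
#' maternal fraction. Reads on the Africanized allele are then thinned with
#' probability `mapping_bias`, emulating reference-mapping loss. The output
#' is deterministic given the seed.
#'
#' @param config A [sim_config()] object.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A `psge_sim` list with tibbles `snps` (informative SNPs for both
#'   families), `counts` (long allele-count records), `truth` (class and
#'   expected per-family maternal fractions per transcript) and the
#'   `config` echo.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_tx <- config$n_transcripts
  classes <- names(config$class_proportions)

  tx <- tibble::tibble(
    transcript_id = sprintf("TX%05d", seq_len(n_tx)),
    class = sample(classes, n_tx, replace = TRUE, prob = config$class_proportions),
    n_snps = 1L + rpois(n_tx, config$snp_lambda)
  )
  truth <- dplyr::bind_cols(
    tx,
    class_maternal_fractions(tx$class, config$theta_m, config$theta_l)
  )

  # SNP scaffold: two synthetic chromosomes, transcripts in contiguous
  # blocks, uniformly spaced positions; REF is the European allele
  snp_tx <- rep(tx$transcript_id, tx$n_snps)
  n_snp <- length(snp_tx)
  half <- ceiling(n_tx / 2)
  chrom_of_tx <- setNames(ifelse(seq_len(n_tx) <= half, "chr1", "chr2"),
                          tx$transcript_id)
  chrom <- unname(chrom_of_tx[snp_tx])
  pos <- integer(n_snp)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 100L * seq_along(idx)
  }
  pair <- t(vapply(seq_len(n_snp), function(i) sample(c("A", "C", "G", "T"), 2),
                   character(2)))
  snp_base <- tibble::tibble(
    chrom = chrom, pos = pos, transcript_id = snp_tx,
    african_allele = pair[, 1], european_allele = pair[, 2]
  )
  snps <- purrr::map_dfr(.families, function(fam) {
    mat_afr <- fam == "AE"
    tibble::tibble(
      family = fam,
      chrom = snp_base$chrom, pos = snp_base$pos,
      transcript_id = snp_base$transcript_id,
      maternal_allele = if (mat_afr) snp_base$african_allele else snp_base$european_allele,
      paternal_allele = if (mat_afr) snp_base$european_allele else snp_base$african_allele,
      maternal_lineage = maternal_lineage_of(fam),
      paternal_lineage = ifelse(maternal_lineage_of(fam) == "Africanized",
                                "European", "Africanized")
    )
  })

  libs <- purrr::imap_dfr(config$replicates, function(reps, grp) {
    purrr::map_dfr(.families, function(fam) {
      n <- reps[[fam]]
      tibble::tibble(sample_group = grp, family = fam,
                     replicate_id = sprintf("%s_%s_%d", grp, fam, seq_len(n)))
    })
  })

  cells <- tidyr::crossing(
    dplyr::select(snp_base, "chrom", "pos", "transcript_id"), libs) |>
    dplyr::left_join(dplyr::select(truth, "transcript_id", "exp_R_AE", "exp_R_EA"),
                     by = "transcript_id") |>
    dplyr::mutate(mu = ifelse(.data$family == "AE", .data$exp_R_AE, .data$exp_R_EA))

  n_cell <- nrow(cells)
  total <- rnbinom(n_cell, mu = config$mean_depth, size = config$depth_size)
  p_cell <- if (config$rho > 0) {
    nu <- 1 / config$rho - 1
    rbeta(n_cell, cells$mu * nu, (1 - cells$mu) * nu)
  } else {
    cells$mu
  }
  maternal <- rbinom(n_cell, total, p_cell)
  paternal <- total - maternal

  # one-sided mapping bias: thin reads carrying the Africanized allele
  if (config$mapping_bias > 0) {
    afr_is_maternal <- cells$family == "AE"
    afr <- ifelse(afr_is_maternal, maternal, paternal)
    afr <- rbinom(n_cell, afr, 1 - config$mapping_bias)
    maternal <- ifelse(afr_is_maternal, afr, maternal)
    paternal <- ifelse(afr_is_maternal, paternal, afr)
  }

  counts <- dplyr::bind_rows(
    dplyr::mutate(cells, parent = "maternal", count = maternal),
    dplyr::mutate(cells, parent = "paternal", count = paternal)
  ) |>
    dplyr::mutate(lineage = lineage_of(.data$family, .data$parent)) |>
    dplyr::select("transcript_id", "chrom", "pos", "family", "replicate_id",
                  "sample_group", "parent", "lineage", "count") |>
    dplyr::arrange(.data$transcript_id, .data$chrom, .data$pos, .data$family,
                   .data$sample_group, .data$replicate_id, .data$parent)

  structure(list(snps = snps, counts = counts, truth = truth, config = config,
                 seed = seed),
            class = "psge_sim")
}

#' @export
print.psge_sim <- function(x, ...) {
  cat(sprintf("<psge_sim> %d transcripts, %d SNPs, %d count records (seed %s)\n",
              nrow(x$truth), nrow(x$snps) / 2, nrow(x$counts),
              format(x$seed)))
  print(dplyr::count(x$truth, .data$class))
  invisible(x)
}

# Plain VCF 4.2 emission for one family: a diploid queen and a haploid
# drone. REF is the European allele (the simulated reference lineage).
write_family_vcf <- function(snp_base, family, path) {
  queen_is_afr <- family == "AE"
  gt_queen <- if (queen_is_afr) "1/1" else "0/0"
  gt_drone <- if (queen_is_afr) "0" else "1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=psger-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tqueen_%s\tdrone_%s",
            family, family)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s\t%s",
                  snp_base$chrom, snp_base$pos,
                  snp_base$european_allele, snp_base$african_allele,
                  gt_queen, gt_drone)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits one VCF per family (queen diploid GT, drone haploid GT), the
#' informative-SNP table, the long counts table, the truth table and a JSON
#' echo of the configuration.
#'
#' @param sim A `psge_sim` object from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "psge_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snp_base <- sim$snps |>
    dplyr::filter(.data$family == "AE") |>
    dplyr::transmute(.data$chrom, .data$pos, .data$transcript_id,
                     african_allele = .data$maternal_allele,
                     european_allele = .data$paternal_allele)
  for (fam in .families) {
    write_family_vcf(snp_base, fam, file.path(dir, sprintf("parents_%s.vcf", fam)))
  }
  write_informative_snps(sim$snps, file.path(dir, "informative_snps.tsv"))
  write_allele_counts(sim$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  cfg <- sim$config
  cfg$replicates <- lapply(cfg$replicates, as.list)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Mapping-bias null experiment
#'
#' Simulates an all-null dataset in which reads carrying the Africanized
#' allele are lost with probability `mapping_bias`, runs the full pipeline,
#' and reports the resulting call rates. Mapping bias masquerades as a
#' lineage effect but is symmetric with respect to parent across the
#' reciprocal families, so lineage-biased calls inflate with the bias while
#' parent-of-origin calls stay near the nominal null rate — the signature
#' distinguishing reference-mapping artifacts from true parent effects.
#'
#' @param config A [sim_config()] whose class proportions put all mass on
#'   `null` (enforced).
#' @param seed RNG seed; defaults to `config$seed`.
#' @param ... Passed to [run_psge()] (thresholds etc.).
#' @return A list with `rates` (one row per sample group: tested count,
#'   parent/lineage call rates and the raw `p_P < 0.05` rate) and the full
#'   `result`.
#' @export
simulate_ascertainment_null <- function(config, seed = config$seed, ...) {
  if (config$class_proportions["null"] != 1) {
    abort("class proportions must put all mass on 'null' for the mapping-bias null experiment")
  }
  sim <- simulate_dataset(config, seed = seed)
  res <- run_psge(sim$counts, snps = sim$snps, ...)
  rates <- res$calls |>
    dplyr::left_join(dplyr::select(res$fits, "transcript_id", "sample_group", "p_P"),
                     by = c("transcript_id", "sample_group")) |>
    dplyr::group_by(.data$sample_group) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      parent_call_rate = mean(.data$maternal_psge | .data$paternal_psge),
      lineage_call_rate = mean(.data$lineage_A | .data$lineage_E),
      raw_p_P_rate = mean(.data$p_P < 0.05, na.rm = TRUE),
      .groups = "drop"
    )
  list(rates = rates, result = res)
}
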