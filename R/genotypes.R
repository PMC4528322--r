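#' Select SNPs at which the parental origin of every F1 allele is unambiguous
#'
#' In a cross between a diploid queen and a haploid drone, a site is
#' informative when the queen is homozygous for one allele and the drone
#' carries a different allele. Every F1 worker is then heterozygous with a
#' known maternal and paternal allele, and maternal:paternal reads are
#' expected at 1:1 under the null. All other configurations (heterozygous
#' queen, drone matching the queen, multi-allelic sites) are dropped.
#'
#' @param sites A data frame of parental genotypes with columns
#'   `family` ("AE" or "EA"), `chrom`, `pos`, `queen_a1`, `queen_a2`
#'   (the two queen alleles), `drone_allele` (single base; drones are
#'   haploid), and optionally `transcript_id`. Missing genotypes are `NA`.
#' @return A tibble of informative SNPs with columns `family`, `chrom`,
#'   `pos`, `transcript_id`, `maternal_allele`, `paternal_allele`,
#'   `maternal_lineage`, `paternal_lineage`. Sites that were skipped are
#'   recorded, with a reason, in the `"dropped"` attribute (see
#'   [dropped_sites()]).
#' @details A drone genotype reported as heterozygous violates haploidy and
#'   is treated as a genotyping error: the call aborts rather than salvaging
#'   the site. Reference/alternate status plays no role: `aa x b` and
#'   `bb x a` are handled identically.
#' @examples
#' sites <- tibble::tibble(
#'   family = "AE", chrom = "chr1", pos = c(100, 200),
#'   queen_a1 = c("A", "A"), queen_a2 = c("A", "C"),
#'   drone_allele = "G", transcript_id = "tx1"
#' )
#' select_informative_snps(sites) # pos 200 dropped: heterozygous queen
#' @export
select_informative_snps <- function(sites) {
  assert_cols(sites, c("family", "chrom", "pos", "queen_a1", "queen_a2", "drone_allele"),
              "`sites`")
  sites <- tibble::as_tibble(sites)
  if (!"transcript_id" %in% names(sites)) sites$transcript_id <- NA_character_
  assert_tokens(sites$family, .families, "family")

  het_drone <- !is.na(sites$drone_allele) & grepl("[/|]", sites$drone_allele) &
    vapply(strsplit(sites$drone_allele, "[/|]"),
           function(a) length(unique(a)) > 1, logical(1))
  if (any(het_drone)) {
    abort(sprintf(
      "heterozygous drone genotype at %d site(s) (e.g. %s:%s): drones are haploid; refusing to continue",
      sum(het_drone), sites$chrom[het_drone][1], sites$pos[het_drone][1]))
  }
  # a diploid-style homozygous drone call ("G/G") collapses to its allele
  sites$drone_allele <- sub("^([ACGT])[/|]\\1$", "\\1", sites$drone_allele)

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(sites))
  missing_gt <- is.na(sites$queen_a1) | is.na(sites$queen_a2) | is.na(sites$drone_allele)
  reason[missing_gt] <- "missing_genotype"

  bad_allele <- !missing_gt &
    (!sites$queen_a1 %in% bases | !sites$queen_a2 %in% bases | !sites$drone_allele %in% bases)
  reason[bad_allele] <- "invalid_allele"

  n_alleles <- mapply(function(a, b, d) length(unique(c(a, b, d))),
                      sites$queen_a1, sites$queen_a2, sites$drone_allele)
  multi <- is.na(reason) & n_alleles > 2
  reason[multi] <- "multiallelic"

  het_queen <- is.na(reason) & sites$queen_a1 != sites$queen_a2
  reason[het_queen] <- "heterozygous_queen"

  concordant <- is.na(reason) & sites$queen_a1 == sites$drone_allele
  reason[concordant] <- "drone_matches_queen"

  kept <- sites[is.na(reason), , drop = FALSE]
  dropped <- sites[!is.na(reason), c("family", "chrom", "pos"), drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  if (nrow(dropped) > 0) {
    inform(sprintf("select_informative_snps: dropped %d of %d site(s) (%s)",
                   nrow(dropped), nrow(sites),
                   paste(sprintf("%s: %d", names(table(dropped$reason)),
                                 as.integer(table(dropped$reason))), collapse = ", ")))
  }

  out <- tibble::tibble(
    family = kept$family,
    chrom = kept$chrom,
    pos = kept$pos,
    transcript_id = kept$transcript_id,
    maternal_allele = kept$queen_a1,
    paternal_allele = kept$drone_allele,
    maternal_lineage = maternal_lineage_of(kept$family),
    paternal_lineage = ifelse(maternal_lineage_of(kept$family) == "Africanized",
                              "European", "Africanized")
  )
  out <- dplyr::arrange(out, .data$family, .data$chrom, .data$pos)
  stopifnot(all(out$maternal_allele != out$paternal_allele))
  attr(out, "dropped") <- tibble::as_tibble(dropped)
  out
}

#' Sites skipped by an upstream selection or validation step
#'
#' @param x A tibble returned by [select_informative_snps()],
#'   [intersect_families()] or [validate_counts()].
#' @return A tibble of skipped rows with a `reason` column.
#' @export
dropped_sites <- function(x) {
  attr(x, "dropped") %||% tibble::tibble()
}

#' Pair informative SNPs across the two reciprocal families
#'
#' Lineage and interaction contrasts need sites assayable in both crosses.
#' Sites informative in both families with the same two alleles are paired;
#' sites informative in only one family are kept but flagged, since they
#' support within-family ratios only. A position carrying different allele
#' pairs in the two families is excluded.
#'
#' @param snps_AE,snps_EA Informative-SNP tibbles (from
#'   [select_informative_snps()]) for families AE and EA.
#' @return One row per (chrom, pos) with a `status` column
#'   (`"paired"`, `"AE_only"`, `"EA_only"`) and per-family maternal and
#'   paternal alleles. Excluded allele-mismatch positions are in the
#'   `"dropped"` attribute.
#' @export
intersect_families <- function(snps_AE, snps_EA) {
  for (x in list(snps_AE, snps_EA)) {
    assert_cols(x, c("family", "chrom", "pos", "maternal_allele", "paternal_allele"),
                "informative-SNP table")
  }
  if (nrow(snps_AE) > 0 && !all(snps_AE$family == "AE")) abort("`snps_AE` must have family == 'AE'")
  if (nrow(snps_EA) > 0 && !all(snps_EA$family == "EA")) abort("`snps_EA` must have family == 'EA'")

  key <- function(x, suffix) {
    tibble::tibble(
      chrom = x$chrom, pos = x$pos,
      transcript_id = if ("transcript_id" %in% names(x)) x$transcript_id else NA_character_,
      "maternal_{suffix}" := x$maternal_allele,
      "paternal_{suffix}" := x$paternal_allele,
      "alleles_{suffix}" := paste(pmin(x$maternal_allele, x$paternal_allele),
                                  pmax(x$maternal_allele, x$paternal_allele), sep = "/")
    )
  }
  joined <- dplyr::full_join(key(snps_AE, "AE"), key(snps_EA, "EA"),
                             by = c("chrom", "pos"), suffix = c("_AE", "_EA"))
  joined <- dplyr::mutate(joined,
    transcript_id = dplyr::coalesce(.data$transcript_id_AE, .data$transcript_id_EA),
    status = dplyr::case_when(
      is.na(.data$alleles_AE) ~ "EA_only",
      is.na(.data$alleles_EA) ~ "AE_only",
      .data$alleles_AE == .data$alleles_EA ~ "paired",
      TRUE ~ "allele_mismatch"
    )
  )
  dropped <- dplyr::filter(joined, .data$status == "allele_mismatch")
  if (nrow(dropped) > 0) {
    inform(sprintf("intersect_families: excluded %d position(s) with discordant allele pairs",
                   nrow(dropped)))
  }
  out <- joined |>
    dplyr::filter(.data$status != "allele_mismatch") |>
    dplyr::select("chrom", "pos", "transcript_id", "status",
                  "maternal_AE", "paternal_AE", "maternal_EA", "paternal_EA") |>
    dplyr::arrange(.data$chrom, .data$pos)
  attr(out, "dropped") <- dplyr::select(dropped, "chrom", "pos", "alleles_AE", "alleles_EA")
  out
}

#' Read parental genotypes for one cross family from a VCF
#'
#' Extracts the queen (diploid) and drone (haploid) GT calls for one family
#' from a VCF 4.x file and returns one `ParentalSite` row per record, ready
#' for [select_informative_snps()]. Half-calls and `./.` are treated as
#' missing; a heterozygous drone GT is reported as-is so that
#' [select_informative_snps()] raises the haploidy error.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param queen_sample,drone_sample Sample names in the VCF.
#' @param family `"AE"` or `"EA"`.
#' @return A tibble with columns `family`, `chrom`, `pos`, `queen_a1`,
#'   `queen_a2`, `drone_allele`.
#' @export
read_parental_vcf <- function(path, queen_sample, drone_sample, family) {
  assert_tokens(family, .families, "family")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  for (s in c(queen_sample, drone_sample)) {
    if (!s %in% colnames(gt)) {
      abort(sprintf("sample '%s' not found in %s (samples: %s)",
                    s, path, paste(colnames(gt), collapse = ", ")))
    }
  }
  alleles_at <- function(i) c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1]])
  decode <- function(gt_str, i) {
    if (is.na(gt_str)) return(NA_character_)
    idx <- strsplit(gt_str, "[/|]")[[1]]
    if (any(idx == ".")) return(rep(NA_character_, length(idx)))
    alleles_at(i)[as.integer(idx) + 1L]
  }
  n <- nrow(fix)
  queen_a1 <- queen_a2 <- drone <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    qa <- decode(gt[i, queen_sample], i)
    if (length(qa) == 1) qa <- c(qa, qa)  # haploid-style queen call, duplicate
    queen_a1[i] <- qa[1]; queen_a2[i] <- qa[2]
    da <- decode(gt[i, drone_sample], i)
    drone[i] <- if (all(is.na(da))) NA_character_ else paste(da, collapse = "/")
  }
  tibble::tibble(
    family = family,
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    queen_a1 = queen_a1, queen_a2 = queen_a2,
    drone_allele = drone
  )
}

#' Write an informative-SNP table to TSV
#'
#' @param snps Tibble from [select_informative_snps()].
#' @param path Output path.
#' @return `snps`, invisibly.
#' @export
write_informative_snps <- function(snps, path) {
  readr::write_tsv(
    dplyr::select(snps, "family", "chrom", "pos", "transcript_id",
                  "maternal_allele", "paternal_allele", "maternal_lineage"),
    path)
  invisible(snps)
}
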