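# small in-code fixtures and independent oracles shared across tests

# drop bookkeeping attributes so content can be compared directly
strip_meta <- function(x) {
  attr(x, "dropped") <- NULL
  attr(x, "filter_report") <- NULL
  as.data.frame(x)
}

# one ParentalSite row
site <- function(family = "AE", chrom = "chr1", pos = 100,
                 queen = c("A", "A"), drone = "G", transcript_id = "tx1") {
  tibble::tibble(family = family, chrom = chrom, pos = pos,
                 queen_a1 = queen[1], queen_a2 = queen[2],
                 drone_allele = drone, transcript_id = transcript_id)
}

# a balanced two-family count fixture: one row per
# (snp, library, parent), counts supplied cell-wise
count_fixture <- function(n_snps = 2, reps_per_family = 2,
                          sample_group = "brains",
                          counts = NULL, transcript_id = "tx1") {
  grid <- expand.grid(
    snp = seq_len(n_snps), family = c("AE", "EA"),
    rep = seq_len(reps_per_family), parent = c("maternal", "paternal"),
    stringsAsFactors = FALSE)
  grid <- grid[order(grid$snp, grid$family, grid$rep, grid$parent), ]
  n <- nrow(grid)
  if (is.null(counts)) counts <- rep(20L, n)
  tibble::tibble(
    transcript_id = transcript_id,
    chrom = "chr1", pos = 100L * grid$snp,
    family = grid$family,
    replicate_id = sprintf("%s_%s_%d", sample_group, grid$family, grid$rep),
    sample_group = sample_group,
    parent = grid$parent,
    lineage = ifelse(grid$parent == "maternal",
                     ifelse(grid$family == "AE", "Africanized", "European"),
                     ifelse(grid$family == "AE", "European", "Africanized")),
    count = counts
  )
}

# naive Storer-Kim p-value: scalar double loop over the full outcome grid
naive_storer_kim <- function(x1, n1, x2, n2, alternative = "two_sided") {
  z_of <- function(y1, y2) {
    p <- (y1 + y2) / (n1 + n2)
    if (p <= 0 || p >= 1) return(0)
    (y1 / n1 - y2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  }
  z_obs <- z_of(x1, x2)
  phat <- (x1 + x2) / (n1 + n2)
  total <- 0
  for (y1 in 0:n1) {
    for (y2 in 0:n2) {
      z <- z_of(y1, y2)
      extreme <- if (alternative == "two_sided") {
        abs(z) >= abs(z_obs) - 1e-12
      } else {
        z >= z_obs - 1e-12
      }
      if (extreme) total <- total + dbinom(y1, n1, phat) * dbinom(y2, n2, phat)
    }
  }
  min(total, 1)
}

# direct combinatorial sum for the hypergeometric upper tail P[X >= o]
hyper_direct_sum <- function(N, k1, k2, o) {
  hi <- min(k1, k2)
  if (o > hi) stop("o out of range")
  if (o <= max(0, k1 + k2 - N)) return(1)
  sum(vapply(o:hi, function(j) {
    exp(lchoose(k1, j) + lchoose(N - k1, k2 - j) - lchoose(N, k2))
  }, numeric(1)))
}

# independent Benjamini-Hochberg step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# brute-force classification rule evaluators (scalar)
oracle_parent <- function(q, rae, rea, thr = 0.6, qs = 0.05) {
  if (is.na(q) || is.na(rae) || is.na(rea) || q >= qs) return(NA_character_)
  if (rae > thr && rea > thr) return("maternal")
  if (rae < 1 - thr && rea < 1 - thr) return("paternal")
  NA_character_
}
oracle_lineage <- function(q, qae, qea, thr = 0.6, qs = 0.05) {
  if (is.na(q) || is.na(qae) || is.na(qea) || q >= qs) return(NA_character_)
  if (qae > thr && qea > thr) return("Africanized")
  if (qae < 1 - thr && qea < 1 - thr) return("European")
  NA_character_
}
oracle_asym <- function(q, rae, rea, thr = 0.6, qs = 0.05) {
  if (is.na(q) || q >= qs) return(NA_character_)
  in_ae <- !is.na(rae) && rae > thr
  in_ea <- !is.na(rea) && rea > thr
  if (in_ae && !in_ea) return("AE")
  if (in_ea && !in_ae) return("EA")
  NA_character_
}
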