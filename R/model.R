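#' Build the per-transcript model design
#'
#' One row per (SNP, library, parental allele) count cell. The response is
#' `log2(count + 1)`; parent and lineage are effect-coded at +/- 1/2
#' (maternal, Africanized positive), so the parent coefficient is the
#' maternal - paternal mean difference on the log2 scale. The interaction
#' column is the exact product `PL = P * L`.
#'
#' With exactly two reciprocal families the product column is aliased with
#' the family indicator: within AE every row has `L = P` (so `PL = +1/4`)
#' and within EA `L = -P` (`PL = -1/4`). The interaction coefficient is
#' therefore estimated against between-family variation; this identity is
#' asserted at build time.
#'
#' @param records Filtered allele-count records for one transcript and one
#'   sample group.
#' @param response `"log2"` (default) for `log2(count + 1)`, or `"raw"`.
#' @return A tibble with columns `y`, `P`, `L`, `PL`, `snp_id`,
#'   `replicate_id`, `cell_id` (the SNP-by-library cell whose total depth
#'   both parental counts share), `family`. If only one family is present the result
#'   carries `attr(, "single_family") = TRUE`: lineage and interaction are
#'   then confounded with parent and the model falls back to a parent-only
#'   fit.
#' @export
build_design <- function(records, response = c("log2", "raw")) {
  response <- match.arg(response)
  assert_cols(records, c("transcript_id", "chrom", "pos", "family",
                         "replicate_id", "parent", "lineage", "count"),
              "`records`")
  if (dplyr::n_distinct(records$transcript_id) > 1) {
    abort("`build_design()` expects records for a single transcript")
  }
  if ("sample_group" %in% names(records) &&
      dplyr::n_distinct(records$sample_group) > 1) {
    abort("`build_design()` expects records for a single sample group")
  }
  design <- tibble::tibble(
    y = if (response == "log2") log2(records$count + 1) else as.numeric(records$count),
    P = ifelse(records$parent == "maternal", 0.5, -0.5),
    L = ifelse(records$lineage == "Africanized", 0.5, -0.5),
    snp_id = paste(records$chrom, records$pos, sep = ":"),
    replicate_id = records$replicate_id,
    family = records$family
  )
  design$PL <- design$P * design$L
  # the two parental counts at one SNP in one library share that cell's
  # sequencing depth; the cell identifier carries that pairing
  design$cell_id <- paste(design$snp_id, design$replicate_id, sep = "@")
  design <- design[, c("y", "P", "L", "PL", "snp_id", "replicate_id",
                       "cell_id", "family")]
  # reciprocal-design aliasing identity: PL is a scaled family indicator
  stopifnot(all(design$PL[design$family == "AE"] == 0.25),
            all(design$PL[design$family == "EA"] == -0.25))
  single <- dplyr::n_distinct(design$family) < 2
  if (single) {
    warn(sprintf("single-family transcript (family %s only): lineage and interaction are not estimable; fitting parent-only model",
                 design$family[1]))
  }
  attr(design, "single_family") <- single
  design
}

# Wald chi-square(1) p-value with the degenerate-fit conventions:
# SE = 0 with a zero coefficient -> p = 1; SE = 0 with a nonzero
# coefficient (noiseless fit, infinite statistic) -> p = 0.
wald_p <- function(estimate, se, tol = 1e-8) {
  if (is.na(estimate) || is.na(se)) return(NA_real_)
  if (se <= tol) {
    return(if (abs(estimate) <= tol) 1 else 0)
  }
  pchisq((estimate / se)^2, df = 1, lower.tail = FALSE)
}

# two-sided t (equivalently F with 1 numerator df) at the term's
# denominator df, with the same zero-SE conventions
t_p <- function(estimate, se, df, tol = 1e-8) {
  if (is.na(estimate) || is.na(se)) return(NA_real_)
  if (se <= tol) {
    return(if (abs(estimate) <= tol) 1 else 0)
  }
  2 * stats::pt(abs(estimate / se), df = max(df, 1), lower.tail = FALSE)
}

# between-within denominator degrees of freedom. Parent and lineage are
# within-cell contrasts (each SNP-by-library cell contributes one maternal
# and one paternal count), so they are tested against within-cell
# replication; the interaction is aliased with the family indicator and is
# a between-library contrast, tested against library-level replication.
bw_df <- function(term, n_obs, n_cells, n_reps) {
  switch(term,
         "P" = ,
         "L" = max(n_obs - n_cells - 2, 1),
         "PL" = max(n_reps - 2, 1),
         max(n_reps - 1, 1))  # intercept
}

#' Wald term test for a fitted transcript model
#'
#' @param fit A `psge_fit` object from [fit_transcript()].
#' @param term One of `"P"` (parent-of-origin), `"L"` (lineage-of-origin),
#'   `"PL"` (their interaction).
#' @return The upper chi-square(1) tail probability at `(estimate / SE)^2`
#'   (the large-sample Wald test, regardless of the `df_method` the fit was
#'   produced with). Deterministic given the fit; degenerate zero-SE fits
#'   return 0 (nonzero coefficient) or 1 (zero coefficient) by convention.
#' @export
wald_term_test <- function(fit, term = c("P", "L", "PL")) {
  term <- match.arg(term)
  co <- fit$coefficients
  row <- co[co$term == term, , drop = FALSE]
  if (nrow(row) == 0) return(NA_real_)
  wald_p(row$estimate, row$std_error)
}

# Fit the fixed-effect part by OLS; used for noiseless/degenerate designs
# and as the fallback when all variance components hit the boundary.
fit_fixed_ols <- function(design, terms) {
  X <- as.matrix(cbind(`(Intercept)` = 1, design[, terms, drop = FALSE]))
  fit <- lm.fit(X, design$y)
  rank <- fit$rank
  n <- nrow(X)
  rss <- sum(fit$residuals^2)
  s2 <- if (n > rank) rss / (n - rank) else 0
  XtXinv <- chol2inv(chol(crossprod(X[, seq_len(rank), drop = FALSE])))
  se <- rep(NA_real_, ncol(X))
  se[seq_len(rank)] <- sqrt(pmax(diag(XtXinv) * s2, 0))
  est <- fit$coefficients
  tibble::tibble(
    term = colnames(X),
    estimate = as.numeric(est),
    std_error = se
  ) |> list(sigma2_resid = s2)
}

#' Fit the reciprocal-cross mixed model for one transcript
#'
#' Fits `y ~ P + L + PL` with random intercepts for SNP, library
#' (replicate) and the SNP-by-library cell by REML, on the design from
#' [build_design()]. Parent, lineage and their interaction are fixed
#' effects; SNP and replicate variation is absorbed by the random factors,
#' and the cell intercept accounts for the sequencing depth that the two
#' parental counts of one cell share (without it the within-cell parent
#' contrast would be tested against depth variability and the test would be
#' badly conservative).
#'
#' Per-term p-values are Wald tests of `(estimate / SE)^2`. By default the
#' statistic is referred to an F(1, df) distribution with between-within
#' denominator degrees of freedom: parent and lineage contrasts vary within
#' the SNP-by-library cells and use the within-cell df, while the
#' interaction is aliased with the family indicator in a two-family
#' reciprocal design and uses library-level df. `df_method = "asymptotic"`
#' gives the large-sample chi-square(1) reference instead (anticonservative
#' in the far tail at these replicate counts; see [wald_term_test()]).
#'
#' Variance components are constrained non-negative; a component estimated
#' at the zero boundary is set to 0 and the model refit without that term.
#' When both random terms are dropped (or a grouping factor has a single
#' level) the fit reduces to ordinary least squares. A design that is
#' exactly interpolated by the fixed effects (noiseless synthetic data, or
#' a constant response) is detected up front: coefficients come from OLS,
#' all variance components are 0, and zero-SE p-value conventions apply,
#' with the fit flagged `degenerate`.
#'
#' @param design Tibble from [build_design()].
#' @param min_rows Minimum number of rows required (default 4).
#' @param df_method `"between_within"` (default) for F(1, df) tests with
#'   between-within denominator df, or `"asymptotic"` for chi-square(1).
#' @return A `psge_fit` object: a list with `coefficients` (term, estimate,
#'   std_error, p_value), `varcomp` (`sigma2_snp`, `sigma2_rep`,
#'   `sigma2_cell`, `sigma2_resid`), `n_obs`, `n_snps`, `n_replicates`, `converged`,
#'   `single_family`, `degenerate`. Supports [tidy()] and [glance()].
#' @export
fit_transcript <- function(design, min_rows = 4,
                           df_method = c("between_within", "asymptotic")) {
  df_method <- match.arg(df_method)
  if (nrow(design) < min_rows) {
    abort(sprintf("design has %d row(s); at least %d required", nrow(design), min_rows))
  }
  if (dplyr::n_distinct(design$P) < 2) {
    abort("design must contain both maternal and paternal rows")
  }
  if (all(design$y == 0)) {
    abort("all counts are zero: transcript untestable")
  }
  single <- isTRUE(attr(design, "single_family"))
  terms <- if (single) "P" else c("P", "L", "PL")

  n_snps <- dplyr::n_distinct(design$snp_id)
  n_reps <- dplyr::n_distinct(design$replicate_id)

  n_cell_groups <- dplyr::n_distinct(design$cell_id)
  make_fit <- function(co_tbl, vc, converged, degenerate) {
    co_tbl$df <- vapply(co_tbl$term, bw_df, numeric(1),
                        n_obs = nrow(design), n_cells = n_cell_groups,
                        n_reps = n_reps)
    co_tbl$p_value <- vapply(seq_len(nrow(co_tbl)), function(i) {
      if (df_method == "asymptotic") {
        wald_p(co_tbl$estimate[i], co_tbl$std_error[i])
      } else {
        t_p(co_tbl$estimate[i], co_tbl$std_error[i], co_tbl$df[i])
      }
    }, numeric(1))
    full <- tibble::tibble(term = c("(Intercept)", "P", "L", "PL")) |>
      dplyr::left_join(co_tbl, by = "term")
    structure(list(
      coefficients = full,
      varcomp = vc,
      n_obs = nrow(design), n_snps = n_snps, n_replicates = n_reps,
      df_method = df_method,
      converged = converged, single_family = single, degenerate = degenerate
    ), class = "psge_fit")
  }

  # exact-interpolation / constant-response shortcut: REML is undefined at
  # zero residual variance, and OLS already gives the exact coefficients
  ols <- fit_fixed_ols(design, terms)
  if (ols$sigma2_resid < 1e-16) {
    return(make_fit(ols[[1]],
                    c(sigma2_snp = 0, sigma2_rep = 0, sigma2_cell = 0,
                      sigma2_resid = ols$sigma2_resid),
                    converged = TRUE, degenerate = TRUE))
  }

  active <- c(snp_id = n_snps >= 2,
              replicate_id = n_reps >= 2,
              cell_id = n_cell_groups >= 2 && n_cell_groups < nrow(design))
  fixed <- paste("y ~", paste(terms, collapse = " + "))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")

  fit_lmm <- function(active) {
    groups <- names(active)[active]
    if (length(groups) == 0) return(NULL)
    f <- as.formula(paste(fixed, "+",
                          paste(sprintf("(1 | %s)", groups), collapse = " + ")))
    ok <- TRUE
    m <- withCallingHandlers(
      tryCatch(lme4::lmer(f, data = design, REML = TRUE, control = ctrl),
               error = function(e) NULL),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (is.null(m)) return(NULL)
    list(model = m, converged = ok)
  }
  vc_of <- function(m) {
    vc <- as.data.frame(lme4::VarCorr(m))
    setNames(vc$vcov, vc$grp)
  }

  # variance components are constrained non-negative; components estimated
  # at the zero boundary are set to 0 and the model refit without them
  boundary_tol <- 1e-5
  res <- fit_lmm(active)
  for (pass in 1:3) {
    if (is.null(res)) break
    vc <- vc_of(res$model)
    tot <- sum(vc)
    act <- names(active)[active]
    present <- act[act %in% names(vc)]
    at_zero <- present[vc[present] < boundary_tol * tot]
    if (length(at_zero) == 0) break
    active[at_zero] <- FALSE
    res <- fit_lmm(active)
  }

  if (is.null(res)) {
    # no random structure left (or lmer failed): ordinary least squares
    ols <- fit_fixed_ols(design, terms)
    return(make_fit(ols[[1]],
                    c(sigma2_snp = 0, sigma2_rep = 0, sigma2_cell = 0,
                      sigma2_resid = ols$sigma2_resid),
                    converged = TRUE, degenerate = FALSE))
  }

  m <- res$model
  vc <- vc_of(m)
  pick <- function(g) if (g %in% names(vc)) unname(vc[g]) else 0
  sm <- summary(m)$coefficients
  co_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"]
  )
  make_fit(co_tbl,
           c(sigma2_snp = pick("snp_id"), sigma2_rep = pick("replicate_id"),
             sigma2_cell = pick("cell_id"), sigma2_resid = pick("Residual")),
           converged = res$converged, degenerate = FALSE)
}

#' @export
print.psge_fit <- function(x, ...) {
  cat(sprintf("<psge_fit> %d obs, %d SNP(s), %d librarie(s)%s%s\n",
              x$n_obs, x$n_snps, x$n_replicates,
              if (x$single_family) ", single-family" else "",
              if (!x$converged) ", NOT converged" else ""))
  print(x$coefficients)
  cat(sprintf("variance components: snp %.4g, replicate %.4g, cell %.4g, residual %.4g\n",
              x$varcomp["sigma2_snp"], x$varcomp["sigma2_rep"],
              x$varcomp["sigma2_cell"], x$varcomp["sigma2_resid"]))
  invisible(x)
}

#' Tidy a per-transcript mixed-model fit
#'
#' @param x A `psge_fit` object.
#' @param ... Unused.
#' @return One row per fixed-effect term with `term`, `estimate`,
#'   `std_error`, `p_value`.
#' @export
tidy.psge_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a per-transcript mixed-model fit
#'
#' @param x A `psge_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with sizes, variance components and flags.
#' @export
glance.psge_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_snps = x$n_snps, n_replicates = x$n_replicates,
    sigma2_snp = unname(x$varcomp["sigma2_snp"]),
    sigma2_rep = unname(x$varcomp["sigma2_rep"]),
    sigma2_cell = unname(x$varcomp["sigma2_cell"]),
    sigma2_resid = unname(x$varcomp["sigma2_resid"]),
    converged = x$converged, single_family = x$single_family,
    degenerate = x$degenerate
  )
}

#' Fit the mixed model for every transcript and sample group
#'
#' Maps [build_design()] + [fit_transcript()] over each
#' (transcript, sample group) in a filtered count table and returns one
#' wide row per fit. Transcripts whose counts are all zero, or with too few
#' rows, are excluded with a reason (attribute `"untestable"`).
#'
#' @param records Filtered allele-count tibble ([filter_counts()]).
#' @param response Response scale passed to [build_design()].
#' @param df_method Denominator-df method passed to [fit_transcript()].
#' @return A tibble with per-term estimates, standard errors and Wald
#'   p-values (`estimate_P`, `se_P`, `p_P`, ... for `L` and `PL`), variance
#'   components, sizes and flags. Pipe into [adjust_fdr()] for q-values.
#' @export
fit_psge <- function(records, response = c("log2", "raw"),
                     df_method = c("between_within", "asymptotic")) {
  response <- match.arg(response)
  df_method <- match.arg(df_method)
  groups <- records |>
    dplyr::group_by(.data$transcript_id, .data$sample_group) |>
    dplyr::group_split()
  untestable <- list()
  rows <- purrr::map(groups, function(g) {
    tid <- g$transcript_id[1]
    grp <- g$sample_group[1]
    fit <- tryCatch(
      suppressWarnings(fit_transcript(build_design(g, response = response),
                                      df_method = df_method)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      untestable[[length(untestable) + 1]] <<- tibble::tibble(
        transcript_id = tid, sample_group = grp, reason = conditionMessage(fit))
      return(NULL)
    }
    co <- fit$coefficients
    grab <- function(term, col) co[[col]][co$term == term]
    tibble::tibble(
      transcript_id = tid, sample_group = grp,
      n_obs = fit$n_obs, n_snps = fit$n_snps, n_replicates = fit$n_replicates,
      estimate_P = grab("P", "estimate"), se_P = grab("P", "std_error"),
      p_P = grab("P", "p_value"),
      estimate_L = grab("L", "estimate"), se_L = grab("L", "std_error"),
      p_L = grab("L", "p_value"),
      estimate_PL = grab("PL", "estimate"), se_PL = grab("PL", "std_error"),
      p_PL = grab("PL", "p_value"),
      sigma2_snp = unname(fit$varcomp["sigma2_snp"]),
      sigma2_rep = unname(fit$varcomp["sigma2_rep"]),
      sigma2_cell = unname(fit$varcomp["sigma2_cell"]),
      sigma2_resid = unname(fit$varcomp["sigma2_resid"]),
      converged = fit$converged, single_family = fit$single_family,
      degenerate = fit$degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      transcript_id = character(), sample_group = character(),
      n_obs = integer(), n_snps = integer(), n_replicates = integer(),
      estimate_P = double(), se_P = double(), p_P = double(),
      estimate_L = double(), se_L = double(), p_L = double(),
      estimate_PL = double(), se_PL = double(), p_PL = double(),
      sigma2_snp = double(), sigma2_rep = double(), sigma2_cell = double(),
      sigma2_resid = double(),
      converged = logical(), single_family = logical(), degenerate = logical()
    )
  }
  attr(out, "untestable") <- dplyr::bind_rows(untestable)
  out
}

#' Benjamini-Hochberg q-values per sample group and model term
#'
#' Applies the step-up false-discovery-rate adjustment separately within
#' each sample group for each of the three model terms, adding `q_P`,
#' `q_L`, `q_PL` columns. Significance downstream means q below the
#' false-discovery threshold (default 0.05).
#'
#' @param fits Tibble from [fit_psge()].
#' @return `fits` with q-value columns appended.
#' @export
adjust_fdr <- function(fits) {
  fits |>
    dplyr::group_by(.data$sample_group) |>
    dplyr::mutate(
      q_P = p.adjust(.data$p_P, method = "BH"),
      q_L = p.adjust(.data$p_L, method = "BH"),
      q_PL = p.adjust(.data$p_PL, method = "BH")
    ) |>
    dplyr::ungroup()
}

#' Write per-group model results to TSV files
#'
#' @param fits Tibble from [fit_psge()] (after [adjust_fdr()]).
#' @param dir Output directory; one `fits_<group>.tsv` per sample group.
#' @return `fits`, invisibly.
#' @export
write_fits <- function(fits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (grp in unique(fits$sample_group)) {
    readr::write_tsv(dplyr::filter(fits, .data$sample_group == grp),
                     file.path(dir, paste0("fits_", grp, ".tsv")))
  }
  invisible(fits)
}
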