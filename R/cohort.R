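#' Behavioral camouflaging score
#'
#' Operationalizes camouflaging as the discrepancy between extrinsic
#' behavioral presentation (ADOS social-communication total) and intrinsic
#' status (self-rated AQ and RMET mentalizing performance). Within the
#' autistic sample, each instrument is standardized by mean-centering to the
#' whole autism sample and dividing by its maximum possible score; then
#' CF1 = S_AQ - S_ADOS and CF2 = -S_RMET - S_ADOS, and the camouflaging
#' score CF is the first principal component of (CF1, CF2), sign-oriented so
#' that higher CF indicates more camouflaging (positive correlation with
#' CF1 + CF2).
#'
#' @param table A `cohort_table` (or data frame with columns `diagnosis`,
#'   `AQ`, `ADOS_SC`, `RMET`).
#' @param max_scores Named maxima used for scaling, `c(AQ=, ADOS_SC=, RMET=)`.
#' @return An object of class `camouflage_scores`: data frame `scores` (per
#'   autistic subject: id, S_AQ, S_ADOS, S_RMET, CF1, CF2, CF) plus
#'   `var_explained` (fraction of variance on PC1) and the PC1 `loadings`.
#' @export
camouflage_score <- function(table,
                             max_scores = c(AQ = 50, ADOS_SC = 22, RMET = 36)) {
  stopifnot(all(c("diagnosis", "AQ", "ADOS_SC", "RMET") %in% names(table)))
  if (any(max_scores <= 0)) stop("max_scores must be positive")
  aut <- table[table$diagnosis == "autism", , drop = FALSE]
  if (nrow(aut) < 3) stop("need at least 3 autistic subjects")
  if (anyNA(aut[, c("AQ", "ADOS_SC", "RMET")])) {
    stop("missing AQ/ADOS_SC/RMET values in the autistic sample")
  }
  s_aq <- (aut$AQ - mean(aut$AQ)) / max_scores[["AQ"]]
  s_ados <- (aut$ADOS_SC - mean(aut$ADOS_SC)) / max_scores[["ADOS_SC"]]
  s_rmet <- (aut$RMET - mean(aut$RMET)) / max_scores[["RMET"]]
  cf1 <- s_aq - s_ados
  cf2 <- -s_rmet - s_ados
  if (sd(cf1) == 0 && sd(cf2) == 0) {
    stop("zero variance in CF1 and CF2; camouflaging undefined")
  }
  pc <- prcomp(cbind(CF1 = cf1, CF2 = cf2), center = TRUE, scale. = FALSE)
  cf <- pc$x[, 1]
  if (cor(cf, cf1 + cf2) < 0) {
    cf <- -cf
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  structure(list(
    scores = data.frame(id = if ("id" %in% names(aut)) aut$id else
      seq_len(nrow(aut)),
      sex = if ("sex" %in% names(aut)) aut$sex else NA,
      S_AQ = s_aq, S_ADOS = s_ados, S_RMET = s_rmet,
      CF1 = cf1, CF2 = cf2, CF = unname(cf)),
    var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
    loadings = pc$rotation[, 1]
  ), class = "camouflage_scores")
}

#' Gene-set enrichment by hypergeometric overlap
#'
#' Builds the 2x2 table of membership in two gene sets over a background of
#' `background_n` genes, and reports the enrichment odds ratio together with
#' the one-tailed (over-representation) hypergeometric p-value
#' P(X >= overlap).
#'
#' @param set_a,set_b Character vectors of gene symbols (deduplicated and
#'   case-normalized internally).
#' @param background_n Total number of genes in the background.
#' @return An object of class `enrichment_result`: `overlap`, `odds_ratio`
#'   (0 or `Inf` with `or_degenerate = TRUE` when a margin is empty),
#'   `p_value`, and the 2x2 `table`.
#' @export
enrichment_test <- function(set_a, set_b, background_n) {
  a <- unique(toupper(trimws(as.character(set_a))))
  b <- unique(toupper(trimws(as.character(set_b))))
  a <- a[nzchar(a)]
  b <- b[nzchar(b)]
  if (length(a) > background_n || length(b) > background_n) {
    stop("set larger than the background")
  }
  n11 <- length(intersect(a, b))
  n12 <- length(a) - n11
  n21 <- length(b) - n11
  n22 <- background_n - length(a) - length(b) + n11
  if (n22 < 0) stop("background smaller than the union of the sets")
  tab <- matrix(c(n11, n12, n21, n22), nrow = 2, byrow = TRUE,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  degenerate <- (n12 == 0 || n21 == 0 || n11 == 0 || n22 == 0)
  or <- if (n12 == 0 || n21 == 0) {
    if (n11 > 0) Inf else 0
  } else {
    (n11 * n22) / (n12 * n21)
  }
  p <- phyper(n11 - 1, length(a), background_n - length(a), length(b),
              lower.tail = FALSE)
  structure(list(overlap = n11, odds_ratio = or, p_value = p, table = tab,
                 or_degenerate = degenerate,
                 n_a = length(a), n_b = length(b),
                 background_n = background_n),
            class = "enrichment_result")
}

#' Compare two correlations with Fisher's r-to-z transform
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with a
#' two-tailed p-value from the standard normal distribution.
#'
#' @param r1,r2 Sample correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each > 3.
#' @return A list with `z` and `p` (two-tailed).
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must lie inside (-1, 1)")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Contrast-driven partial least squares on parcel data
#'
#' Non-rotated task PLS relating a group contrast to subject-by-parcel data:
#' the cross-block matrix between the contrast design and the group-mean
#' parcel profiles is singular-value-decomposed; latent-variable
#' significance is assessed by permuting subjects' group labels, and
#' parcel-level reliability by bootstrap ratios (BSR = salience divided by
#' its bootstrap standard error under within-group resampling with sign
#' alignment to the original saliences). Parcels in the top 20th percentile
#' of |BSR| form the reliability mask.
#'
#' @param H_matrix Numeric matrix, subjects x parcels (column names are
#'   parcel labels).
#' @param groups Factor (or vector) of group labels, one per subject; its
#'   levels map onto the contrast entries in order.
#' @param contrast Numeric contrast over the group levels; must sum to 0.
#'   The default `c(1, -1, -1, 1)` codes a sex-by-diagnosis interaction for
#'   groups ordered (TD male, autistic male, TD female, autistic female).
#' @param n_perm,n_boot Number of permutations / bootstrap resamples.
#' @param seed Integer seed.
#' @return An object of class `pls_result`: `singular_value`, `effect_size`
#'   (observed singular value standardized against the permutation null),
#'   `p_perm`, `saliences` (unit norm), `bsr`, `top_mask` (logical,
#'   `ceil(0.2 * n_parcels)` parcels), `excluded_parcels`.
#' @export
pls_group_contrast <- function(H_matrix, groups, contrast = c(1, -1, -1, 1),
                               n_perm = 10000, n_boot = 10000, seed = 1L) {
  X <- as.matrix(H_matrix)
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(contrast) != length(lev)) {
    stop("contrast length must match the number of group levels")
  }
  if (abs(sum(contrast)) > 1e-12) stop("contrast must sum to zero")
  if (any(table(groups) < 2)) stop("need at least 2 subjects per group")
  if (n_perm < 100) warning("fewer than 100 permutations")
  const <- apply(X, 2, sd) == 0
  if (any(const)) {
    warning(sprintf("%d constant parcel(s) excluded", sum(const)))
    X <- X[, !const, drop = FALSE]
  }
  p <- ncol(X)
  set.seed(seed)

  sv_of <- function(grp) {
    M <- rowsum(X, grp) / as.vector(table(grp))
    cross <- drop(contrast %*% M[lev, , drop = FALSE])
    sqrt(sum(cross^2))
  }
  M <- rowsum(X, groups) / as.vector(table(groups))
  cross <- drop(contrast %*% M[lev, , drop = FALSE])
  s_obs <- sqrt(sum(cross^2))
  if (s_obs == 0) stop("contrast profile is identically zero")
  v <- cross / s_obs

  s_perm <- vapply(seq_len(n_perm), function(b) {
    sv_of(sample(groups))
  }, 0)
  p_perm <- (1 + sum(s_perm >= s_obs)) / (1 + n_perm)
  effect <- if (sd(s_perm) > 0) (s_obs - mean(s_perm)) / sd(s_perm) else Inf

  idx_by_group <- split(seq_along(groups), groups)
  v_boot <- matrix(0, nrow = n_boot, ncol = p)
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_group, function(ix) {
      sample(ix, length(ix), replace = TRUE)
    }), use.names = FALSE)
    Mb <- rowsum(X[take, , drop = FALSE], groups[take]) /
      as.vector(table(groups[take]))
    crb <- drop(contrast %*% Mb[lev, , drop = FALSE])
    sb <- sqrt(sum(crb^2))
    vb <- if (sb > 0) crb / sb else crb
    if (sum(vb * v) < 0) vb <- -vb
    v_boot[b, ] <- vb
  }
  se <- apply(v_boot, 2, sd)
  bsr <- ifelse(se > 0, v / se, Inf * sign(v))
  n_top <- ceiling(0.2 * p)
  mask <- rank(-abs(bsr), ties.method = "first") <= n_top
  names(v) <- names(bsr) <- names(mask) <- colnames(X)
  structure(list(singular_value = s_obs, effect_size = effect,
                 p_perm = p_perm, saliences = v, bsr = bsr, top_mask = mask,
                 excluded_parcels = names(const)[const],
                 n_perm = n_perm, n_boot = n_boot, contrast = contrast,
                 levels = lev),
            class = "pls_result")
}

#' Generate a synthetic four-group cohort
#'
#' Emulates a 2x2 (sex by diagnosis) resting-state cohort with parcel-wise
#' Hurst exponents and behavioral instruments. A sex-by-diagnosis
#' interaction is planted in a subset of parcels: autistic males are shifted
#' down by `d_male` standard deviations (a TD > autism effect) and autistic
#' females by `d_female` (negative values produce an autism > TD effect).
#' In autistic females the first affected parcel is additionally coupled to
#' a latent camouflaging trait with correlation `r_camouflage_f`; AQ, ADOS
#' social-communication and RMET scores are generated from that latent
#' trait so that the derived camouflaging score recovers it.
#'
#' @param n_per_group Named counts `c(TD_M=, AUT_M=, TD_F=, AUT_F=)`.
#' @param n_parcels Number of parcels.
#' @param affected_parcels Integer indices of parcels carrying the planted
#'   interaction.
#' @param d_male,d_female Planted Cohen's d of the TD-minus-autism shift in
#'   males / females within affected parcels.
#' @param h_mean,h_sd Baseline mean and SD of parcel H.
#' @param r_camouflage_f Latent H-camouflage correlation in autistic
#'   females, |r| < 1.
#' @param seed Integer seed.
#' @return A `cohort_table` data frame with columns `id`, `sex`
#'   (`"M"`/`"F"`), `diagnosis` (`"autism"`/`"TD"`), `group`, parcel columns
#'   `h_parcel_001` ... , `AQ`, `ADOS_SC`, `RMET`, `meanFD`, `FIQ` (ADOS is
#'   `NA` for TD subjects, as it is only administered to the autistic
#'   sample); parcel column names are stored in `attr(, "parcels")`.
#' @export
generate_synthetic_cohort <- function(n_per_group = c(TD_M = 29, AUT_M = 23,
                                                      TD_F = 33, AUT_F = 25),
                                      n_parcels = 180,
                                      affected_parcels = 1:18,
                                      d_male = 1.3, d_female = -0.27,
                                      h_mean = 1.0, h_sd = 0.15,
                                      r_camouflage_f = 0.6, seed = 1L) {
  if (any(n_per_group < 4)) stop("need at least 4 subjects per group")
  if (length(affected_parcels) > 0 &&
      (max(affected_parcels) > n_parcels || min(affected_parcels) < 1)) {
    stop("affected parcels out of range")
  }
  if (abs(r_camouflage_f) >= 1) {
    stop("r_camouflage_f must lie strictly inside (-1, 1): ",
         "correlation structure not positive definite")
  }
  set.seed(seed)
  grp_names <- c("TD_M", "AUT_M", "TD_F", "AUT_F")
  n_per_group <- n_per_group[grp_names]
  n <- sum(n_per_group)
  group <- factor(rep(grp_names, times = n_per_group), levels = grp_names)
  sex <- ifelse(group %in% c("TD_M", "AUT_M"), "M", "F")
  diagnosis <- ifelse(group %in% c("AUT_M", "AUT_F"), "autism", "TD")

  H <- matrix(rnorm(n * n_parcels, h_mean, h_sd), nrow = n)
  colnames(H) <- sprintf("h_parcel_%03d", seq_len(n_parcels))
  if (length(affected_parcels) > 0) {
    H[group == "AUT_M", affected_parcels] <-
      H[group == "AUT_M", affected_parcels] - d_male * h_sd
    H[group == "AUT_F", affected_parcels] <-
      H[group == "AUT_F", affected_parcels] - d_female * h_sd
  }

  # latent camouflaging trait for autistic subjects
  cam <- rep(NA_real_, n)
  aut <- diagnosis == "autism"
  cam[aut] <- rnorm(sum(aut))
  autf <- group == "AUT_F"
  if (length(affected_parcels) > 0 && abs(r_camouflage_f) > 0) {
    j <- affected_parcels[1]
    z <- rnorm(sum(autf))
    H[autf, j] <- (h_mean - d_female * h_sd) +
      h_sd * (r_camouflage_f * cam[autf] +
                sqrt(1 - r_camouflage_f^2) * z)
  }

  # behavioral instruments: autistic scores built from the latent trait so
  # that CF1 and CF2 both track it; TD scores from normative distributions
  AQ <- ADOS <- RMET <- rep(NA_real_, n)
  s_ados <- rnorm(sum(aut), 0, 0.08)
  cf1 <- cam[aut] * 0.12 + rnorm(sum(aut), 0, 0.05)
  cf2 <- cam[aut] * 0.12 + rnorm(sum(aut), 0, 0.05)
  AQ[aut] <- pmin(pmax(round((cf1 + s_ados) * 50 + 35), 0), 50)
  ADOS[aut] <- pmin(pmax(round(s_ados * 22 + 7), 0), 22)
  RMET[aut] <- pmin(pmax(round(-(cf2 + s_ados) * 36 + 22), 0), 36)
  AQ[!aut] <- pmin(pmax(round(rnorm(sum(!aut), 14, 5)), 0), 50)
  RMET[!aut] <- pmin(pmax(round(rnorm(sum(!aut), 28, 3)), 0), 36)

  out <- data.frame(
    id = sprintf("sub%03d", seq_len(n)),
    sex = sex, diagnosis = diagnosis, group = group,
    H, AQ = AQ, ADOS_SC = ADOS, RMET = RMET,
    meanFD = abs(rnorm(n, 0.17, 0.05)),
    FIQ = round(rnorm(n, 116, 12)),
    stringsAsFactors = FALSE
  )
  attr(out, "parcels") <- colnames(H)
  class(out) <- c("cohort_table", class(out))
  out
}

#' Read / write a cohort table as delimited text
#'
#' @param table A `cohort_table`.
#' @param path File path (tab-separated with header).
#' @return `read_cohort_table` returns a `cohort_table`.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  attr(out, "parcels") <- grep("^h_", names(out), value = TRUE)
  class(out) <- c("cohort_table", class(out))
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> overlap %d (|A| = %d, |B| = %d, background %d): OR = %.3g, p = %.3g\n",
    x$overlap, x$n_a, x$n_b, x$background_n, x$odds_ratio, x$p_value))
  invisible(x)
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf(
    "<pls_result> singular value %.3g, effect size %.2f, p_perm = %.4g (%d perms, %d boots)\n",
    x$singular_value, x$effect_size, x$p_perm, x$n_perm, x$n_boot))
  invisible(x)
}
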