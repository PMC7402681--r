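test_that("camouflage score follows its defining algebra", {
  # two subjects with (CF1, CF2) = (1, 1) and (-1, -1): PC1 separates them
  tab <- data.frame(
    diagnosis = c("autism", "autism", "autism"),
    AQ = c(40, 20, 30), ADOS_SC = c(5, 9, 7), RMET = c(15, 29, 22))
  cs <- camouflage_score(tab)
  expect_equal(cs$scores$CF1, cs$scores$S_AQ - cs$scores$S_ADOS)
  expect_equal(cs$scores$CF2, -cs$scores$S_RMET - cs$scores$S_ADOS)
  # standardized scores are mean-centered over the autism sample
  expect_equal(mean(cs$scores$S_AQ), 0, tolerance = 1e-12)
  expect_equal(mean(cs$scores$S_ADOS), 0, tolerance = 1e-12)
  # subject with high AQ, low ADOS, low RMET camouflages most
  expect_equal(which.max(cs$scores$CF), 1)
  # degenerate inputs
  same <- data.frame(diagnosis = rep("autism", 4), AQ = 30, ADOS_SC = 7,
                     RMET = 20)
  expect_error(camouflage_score(same), "variance")
  expect_error(camouflage_score(tab[1:2, ]), "at least 3")
})

test_that("camouflage PC1 captures nearly collinear CF1/CF2", {
  set.seed(31)
  n <- 40
  latent <- rnorm(n)
  s_ados <- rnorm(n, 0, 0.05)
  tab <- data.frame(
    diagnosis = "autism",
    AQ = (latent * 0.1 + s_ados) * 50 + 30,
    ADOS_SC = s_ados * 22 + 8,
    RMET = -(latent * 0.1 + s_ados) * 36 + 20)
  cs <- camouflage_score(tab)
  expect_gt(cs$var_explained, 0.9)
  m <- scale(cs$scores$CF1) + scale(cs$scores$CF2)
  expect_gt(abs(cor(cs$scores$CF, m)), 0.99)
  # CF oriented positively with CF1 + CF2
  expect_gt(cor(cs$scores$CF, cs$scores$CF1 + cs$scores$CF2), 0)
  # invariance to adding a constant to a raw instrument
  tab2 <- tab
  tab2$AQ <- tab2$AQ + 5
  expect_equal(camouflage_score(tab2)$scores$CF, cs$scores$CF,
               tolerance = 1e-9)
})

test_that("enrichment matches exhaustive hypergeometric enumeration", {
  # exhaustive check over all feasible overlap configurations, background <= 30
  for (bg in c(12, 20, 30)) {
    for (na in c(3, 5)) {
      for (nb in c(4, 7)) {
        for (ov in 0:min(na, nb)) {
          a <- paste0("G", seq_len(na))
          b <- c(if (ov > 0) paste0("G", 1:ov),
                 if (nb > ov) paste0("H", 1:(nb - ov)))
          res <- enrichment_test(a, b, bg)
          expect_equal(res$overlap, ov)
          expect_equal(res$p_value, oracle_hyper_tail(ov, na, nb, bg),
                       tolerance = 1e-12)
          n11 <- ov; n12 <- na - ov; n21 <- nb - ov; n22 <- bg - na - nb + ov
          if (n12 > 0 && n21 > 0) {
            expect_equal(res$odds_ratio, n11 * n22 / (n12 * n21))
          }
        }
      }
    }
  }
  # empty overlap: OR = 0, p = 1
  r0 <- enrichment_test(c("A1", "A2"), c("B1", "B2", "B3"), 50)
  expect_equal(r0$odds_ratio, 0)
  expect_equal(r0$p_value, 1)
  # identical sets: infinite OR with degeneracy flag, minimal attainable p
  ri <- enrichment_test(paste0("G", 1:10), paste0("g", 1:10), 100)
  expect_true(is.infinite(ri$odds_ratio))
  expect_true(ri$or_degenerate)
  expect_equal(ri$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  expect_error(enrichment_test(paste0("G", 1:10), "G1", 5), "background")
})

test_that("Fisher r-to-z comparison reproduces the worked example", {
  res <- fisher_rz_compare(0.60, 25, -0.10, 23)
  expect_lt(abs(res$z - 2.58), 0.05)
  expect_lt(res$p, 0.05)
  # equal correlations give z = 0, p = 1
  r_eq <- fisher_rz_compare(0.4, 30, 0.4, 50)
  expect_equal(r_eq$z, 0)
  expect_equal(r_eq$p, 1)
  # antisymmetry under swapping the groups
  a <- fisher_rz_compare(0.5, 20, 0.1, 25)
  b <- fisher_rz_compare(0.1, 25, 0.5, 20)
  expect_equal(a$z, -b$z)
  # |z| grows with n at a fixed correlation gap
  expect_gt(abs(fisher_rz_compare(0.5, 100, 0.1, 100)$z), abs(a$z))
  expect_error(fisher_rz_compare(0.5, 3, 0.1, 25), "exceed 3")
  expect_error(fisher_rz_compare(1, 30, 0.1, 25), "inside")
})

test_that("contrast PLS pins a parcel that codes the contrast exactly", {
  set.seed(7)
  n_per <- 6
  groups <- factor(rep(c("TD_M", "AUT_M", "TD_F", "AUT_F"), each = n_per),
                   levels = c("TD_M", "AUT_M", "TD_F", "AUT_F"))
  X <- matrix(rnorm(4 * n_per * 10, sd = 0.1), ncol = 10)
  contrast <- c(1, -1, -1, 1)
  X[, 4] <- contrast[as.integer(groups)]
  res <- pls_group_contrast(X, groups, contrast, n_perm = 500, n_boot = 200,
                            seed = 2)
  expect_equal(which.max(abs(res$saliences)), 4)
  expect_equal(res$p_perm, 1 / 501, tolerance = 1e-12)
  expect_true(res$top_mask[4])
  expect_equal(sum(res$top_mask), ceiling(0.2 * 10))
  expect_equal(sum(res$saliences^2), 1, tolerance = 1e-8)
  expect_error(pls_group_contrast(X, groups, c(1, -1, -1, 2)), "sum to zero")
  expect_warning(pls_group_contrast(cbind(X, 0), groups, contrast,
                                    n_perm = 100, n_boot = 50, seed = 1),
                 "constant")
})

test_that("synthetic cohorts carry the planted effect structure", {
  # null generator: no group differences beyond sampling error
  fps <- sapply(1:30, function(s) {
    tab <- generate_synthetic_cohort(n_per_group = c(TD_M = 10, AUT_M = 10,
                                                     TD_F = 10, AUT_F = 10),
                                     n_parcels = 12, affected_parcels = 1:4,
                                     d_male = 0, d_female = 0,
                                     r_camouflage_f = 0, seed = s)
    h <- rowMeans(as.matrix(tab[, attr(tab, "parcels")]))
    t.test(h[tab$diagnosis == "autism"], h[tab$diagnosis == "TD"])$p.value
  })
  expect_gt(mean(fps > 0.05), 0.8)

  # planted male effect of d = 1.3 is recovered within sampling bounds
  ds <- sapply(1:30, function(s) {
    tab <- generate_synthetic_cohort(n_per_group = c(TD_M = 30, AUT_M = 30,
                                                     TD_F = 30, AUT_F = 30),
                                     n_parcels = 5, affected_parcels = 1,
                                     seed = 100 + s)
    x <- tab$h_parcel_001[tab$group == "TD_M"]
    y <- tab$h_parcel_001[tab$group == "AUT_M"]
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / sp
  })
  expect_gt(mean(ds > 0.8 & ds < 1.8), 0.9)

  # female H-camouflage coupling near the requested correlation
  rs <- sapply(1:30, function(s) {
    tab <- generate_synthetic_cohort(r_camouflage_f = 0.6, seed = 200 + s)
    cs <- camouflage_score(tab)
    autf <- tab$group == "AUT_F"
    cor(tab$h_parcel_001[autf], cs$scores$CF[cs$scores$sex == "F"])
  })
  expect_gt(mean(rs > 0.3 & rs < 0.8), 0.9)

  expect_error(generate_synthetic_cohort(r_camouflage_f = 1.2),
               "positive definite")
  expect_error(generate_synthetic_cohort(affected_parcels = 500), "range")
})

test_that("cohort tables round-trip through delimited text", {
  tab <- generate_synthetic_cohort(seed = 5, n_parcels = 8,
                                   affected_parcels = 1:3)
  path <- tempfile(fileext = ".tsv")
  write_cohort_table(tab, path)
  back <- read_cohort_table(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$h_parcel_001, tab$h_parcel_001, tolerance = 1e-9)
  expect_equal(attr(back, "parcels"), attr(tab, "parcels"))
})
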