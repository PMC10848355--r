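make_lfq <- function(x, groups) {
  lfq_matrix(x, groups)
}

test_that("detection filter keeps proteins with >= 2 detections in a group", {
  x <- matrix(rnorm(24, 20), 4, 6,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:6)))
  grp <- setNames(rep(c("A", "B"), each = 3), colnames(x))
  # p1 fully observed; p2 once per group; p3 twice in A; p4 once in A only
  x[2, c(1, 2, 4, 5)] <- NA
  x[3, 4:6] <- NA; x[3, 3] <- NA
  x[4, 2:6] <- NA
  lf <- make_lfq(x, grp)
  kept <- rownames(detection_filter(lf, 2)$intensity)
  expect_setequal(kept, c("p1", "p3"))
  # randomized masks vs per-group loop oracle
  set.seed(5)
  for (rep in 1:5) {
    y <- matrix(rnorm(60, 20), 10, 6, dimnames = list(paste0("q", 1:10), names(grp)))
    y[matrix(runif(60) < 0.4, 10, 6)] <- NA
    keep <- logical(10)
    for (i in 1:10) {
      for (g in c("A", "B")) {
        if (sum(!is.na(y[i, grp == g])) >= 2) keep[i] <- TRUE
      }
    }
    got <- rownames(detection_filter(make_lfq(y, grp), 2)$intensity)
    expect_setequal(got, rownames(y)[keep])
  }
})

test_that("imputation honors the two tiers and never touches observed values", {
  x <- matrix(rnorm(40, 20, 1), 5, 8,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:8)))
  grp <- setNames(rep(c("A", "B"), each = 4), colnames(x))
  # p1: tier-2 case in group A (2 observed of 4); p2: tier-1 case (0 observed in B)
  x[1, c(1, 2)] <- c(18, 20); x[1, c(3, 4)] <- NA
  x[2, 5:8] <- NA
  lf <- make_lfq(x, grp)
  imp <- impute_lfq(lf, seed = 1)
  # observed entries unchanged
  expect_equal(imp$completed[!lf$mask], x[!lf$mask])
  expect_identical(imp$imputed, lf$mask)
  # tier 2: normal MLE mean of observed replicates {18, 20} -> 19
  expect_equal(unname(imp$completed[1, 3]), 19)
  expect_equal(unname(imp$completed[1, 4]), 19)
  # tier 1: draws land near column mean - 2.5 sd
  for (j in 5:8) {
    mu <- mean(x[-2, j]); s <- sd(x[-2, j])
    expect_lt(abs(imp$completed[2, j] - (mu - 2.5 * s)), 5 * s)
  }
  # deterministic under a fixed seed
  expect_identical(impute_lfq(lf, seed = 1), imp)
  expect_false(identical(impute_lfq(lf, seed = 2)$completed, imp$completed))
  # no-missing identity
  full <- make_lfq(matrix(rnorm(24, 20), 4, 6,
                          dimnames = list(paste0("q", 1:4), names(grp)[1:6])),
                   grp[1:6])
  out <- impute_lfq(full, seed = 3)
  expect_identical(out$completed, full$intensity)
  expect_true(!any(out$imputed))
  # column with < 3 observed values errors by name
  bad <- x; bad[1:3, 1] <- NA; bad[4, 1] <- NA
  expect_error(impute_lfq(make_lfq(bad, grp), 1), "s1")
})

test_that("tier-1 draws have mean mu - 2.5 sd and width 0.3 sd", {
  set.seed(2)
  d <- downshift_draws(1e5, mu = 20, sigma = 1)
  expect_lt(abs(mean(d) - 17.5), 4 * 0.3 / sqrt(1e5))
  expect_lt(abs(sd(d) - 0.3), 0.01)
})

test_that("moderated t matches the hand formula with an injected prior", {
  x <- matrix(c(10, 11, 12, 14, 15, 16,
                20, 20, 20, 21, 21, 21,
                5, 7, 9, 5, 6, 10), 3, 6, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:6)))
  grp <- setNames(rep(c("A", "B"), each = 3), colnames(x))
  mt <- moderated_t(x, grp, c("B", "A"), d0 = 4, s0_sq = 1)
  for (i in 1:3) {
    mA <- mean(x[i, 4:6]); mB <- mean(x[i, 1:3])
    s2 <- (sum((x[i, 1:3] - mB)^2) + sum((x[i, 4:6] - mA)^2)) / 4
    s2_post <- (4 * 1 + 4 * s2) / (4 + 4)
    tt <- (mA - mB) / sqrt(s2_post * (2 / 3))
    expect_equal(mt$t[i], tt, tolerance = 1e-10)
    expect_equal(mt$p[i], 2 * pt(-abs(tt), df = 8), tolerance = 1e-10)
  }
  # d0 = 0 reduces to the ordinary equal-variance t-test (rows with variance)
  mt0 <- moderated_t(x, grp, c("B", "A"), d0 = 0, s0_sq = 1)
  for (i in c(1, 3)) {
    ref <- t.test(x[i, 4:6], x[i, 1:3], var.equal = TRUE)
    expect_equal(mt0$p[i], ref$p.value, tolerance = 1e-10)
  }
  # equal residual variances -> infinite prior df, pooled variance everywhere
  y <- rbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7), c(0, 1, 2, 3, 4, 5))
  dimnames(y) <- list(paste0("q", 1:3), names(grp))
  mty <- moderated_t(y, grp, c("B", "A"))
  expect_true(is.infinite(attr(mty, "d0")))
})

test_that("moderated-t prior agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(12)
  n <- 400
  s2_true <- 1 / rchisq(n, df = 8) * 8
  x <- matrix(rnorm(n * 8, 0, sqrt(s2_true)), n, 8,
              dimnames = list(sprintf("p%03d", 1:n), paste0("s", 1:8)))
  grp <- setNames(rep(c("A", "B"), each = 4), colnames(x))
  mt <- moderated_t(x, grp, c("B", "A"))
  sq <- limma::squeezeVar(apply(x, 1, function(r) {
    (sum((r[1:4] - mean(r[1:4]))^2) + sum((r[5:8] - mean(r[5:8]))^2)) / 6
  }), df = 6)
  expect_lt(abs(log(attr(mt, "d0") / sq$df.prior)), 0.5)
  expect_lt(abs(log(attr(mt, "s0_sq") / sq$var.prior)), 0.2)
})

test_that("moderated-t p-values are super-uniform on null data", {
  set.seed(13)
  n <- 5000
  s2 <- 1 / rchisq(n, df = 5) * 5
  x <- matrix(rnorm(n * 8, 0, sqrt(s2)), n, 8,
              dimnames = list(sprintf("p%04d", 1:n), paste0("s", 1:8)))
  grp <- setNames(rep(c("A", "B"), each = 4), colnames(x))
  mt <- moderated_t(x, grp, c("B", "A"))
  expect_gt(suppressWarnings(ks.test(mt$p, "punif")$p.value), 0.01)
})

test_that("significance curve enforces both asymptotes", {
  expect_false(significance_curve(1, 1e-30))
  expect_false(significance_curve(-1, 1e-30))
  expect_true(significance_curve(1e6, 0.049))
  expect_false(significance_curve(1e6, 0.051))
  expect_true(significance_curve(1.5, 1e-4))
  # curvature 0 is the rectangular rule
  expect_true(significance_curve(1.01, 0.05, curvature = 0))
  expect_false(significance_curve(0.99, 1e-10, curvature = 0))
  # significant set shrinks as curvature grows
  set.seed(3)
  lfc <- rnorm(200, 0, 2); padj <- runif(200)^2
  n_sig <- sapply(c(0, 0.25, 0.5, 1, 2),
                  function(cv) sum(significance_curve(lfc, padj, curvature = cv)))
  expect_true(all(diff(n_sig) <= 0))
  expect_error(significance_curve(2, 0.01, curvature = -1), "curvature")
})

test_that("repeated imputation flags consistent calls", {
  # no missing values: every cycle identical, consistent == significant
  set.seed(14)
  x <- matrix(rnorm(240, 20), 40, 6,
              dimnames = list(sprintf("p%02d", 1:40), paste0("s", 1:6)))
  x[1:5, 4:6] <- x[1:5, 4:6] + 3
  grp <- setNames(rep(c("ctl", "case"), each = 3), colnames(x))
  lf <- make_lfq(x, grp)
  dep <- repeated_imputation_de(lf, c("case", "ctl"), n_cycles = 5, base_seed = 1)
  expect_equal(dep$consistent, dep$significant)
  # single cycle: consistent == significant by construction
  sim <- gen_lfq(120, c(control = 4, case = 4), frac_de = 0.1, delta = 3,
                 seed = 4)
  one <- repeated_imputation_de(sim$lfq, c("case", "control"), n_cycles = 1,
                                base_seed = 2)
  expect_equal(one$consistent, one$significant)
  # consistent implies significant in the reported table
  many <- repeated_imputation_de(sim$lfq, c("case", "control"), n_cycles = 8,
                                 base_seed = 2)
  expect_true(all(!many$consistent | many$significant))
  expect_true(all(c("n_detected_A", "n_detected_B") %in% names(many)))
})
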