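make_features <- function(n, p, seed = 1, prefix = "G") {
  set.seed(seed)
  imputed_features(
    matrix(rnorm(n * p), n, p),
    tibble::tibble(gene_id = sprintf("%s%03d", prefix, seq_len(p)),
                   tissue = "liver"),
    sprintf("i%03d", seq_len(n)))
}

test_that("regress_r2: exact fit, single-feature identity, oracle agreement", {
  fx <- make_features(50, 3, seed = 61)
  beta <- c(2, -1, 0.5)
  y <- as.vector(fx$values %*% beta) + 4
  expect_equal(regress_r2(fx, y), 1, tolerance = 1e-12)

  y2 <- rnorm(50)
  one <- fx$values[, 1, drop = FALSE]
  expect_equal(regress_r2(one, y2), cor(one[, 1], y2)^2, tolerance = 1e-12)

  fx2 <- make_features(200, 10, seed = 62)
  y3 <- rnorm(200)
  expect_equal(regress_r2(fx2, y3), r2_oracle(fx2$values, y3),
               tolerance = 1e-10)
  expect_lt(regress_r2(fx2, y3), 0.15)
})

test_that("collinear signature columns are dropped, not fatal", {
  fx <- make_features(40, 2, seed = 63)
  X <- cbind(fx$values, fx$values[, 1] * 2)
  y <- rnorm(40)
  expect_warning(r2 <- regress_r2(X, y), "collinear")
  expect_equal(r2, r2_oracle(fx$values, y), tolerance = 1e-10)
})

test_that("regress_r2 guards its preconditions", {
  fx <- make_features(5, 4, seed = 64)
  expect_error(regress_r2(fx, rnorm(5)), "n >")
  expect_error(regress_r2(make_features(10, 2), rnorm(9)), "misaligned")
})

test_that("shuffled null: identity permutation equals observed R2; mean ~ p/(n-1)", {
  fx <- make_features(100, 5, seed = 65)
  y <- rnorm(100)
  # Q-basis scoring of the unpermuted response reproduces regress_r2
  Q <- dosesig:::r2_basis(fx$values)
  expect_equal(unname(dosesig:::r2_from_basis(Q, y)), regress_r2(fx, y),
               tolerance = 1e-12)

  nulls <- null_shuffled(fx, y, n_perm = 4000, seed = 2)
  expect_length(nulls, 4000)
  expect_equal(mean(nulls), 5 / 99, tolerance = 0.15)
  expect_identical(nulls, null_shuffled(fx, y, n_perm = 4000, seed = 2))
})

test_that("random-signature null excludes the signature and forces ties", {
  fx <- make_features(60, 10, seed = 66)
  sig <- tibble::tibble(gene_id = c("G001", "G002"), tissue = "liver")
  y <- rnorm(60)
  set.seed(10)
  # complement exactly the signature size -> constant null
  small <- imputed_features(fx$values[, 1:4],
                            fx$features[1:4, ], fx$individuals)
  nulls <- null_random_signatures(small, sig, y, n_draws = 50, seed = 3)
  expect_equal(length(unique(nulls)), 1)

  # exclusion contract: signature columns never drawn
  fx2 <- make_features(60, 6, seed = 67)
  sig_cols <- fx2$values[, c("G001|liver", "G002|liver")]
  y_sig <- as.vector(sig_cols %*% c(5, 5))
  nulls2 <- null_random_signatures(fx2, sig, y_sig, n_draws = 300, seed = 4)
  # y is exactly linear in the signature; if a draw contained both signature
  # columns its R2 would be 1
  expect_lt(max(nulls2), 1 - 1e-6)
  expect_error(null_random_signatures(small, tibble::tibble(
    gene_id = sprintf("G%03d", 1:3), tissue = "liver"), y, 10, 1),
    "complement")
})

test_that("shuffled and random-signature nulls agree under exchangeability", {
  # both null models estimate the same R^2 distribution when every feature
  # is i.i.d. noise; compare them marginally by pooling over replicate
  # datasets (a single dataset's random-signature null carries irreducible
  # finite-pool fluctuation)
  ns_all <- nr_all <- c()
  sig <- tibble::tibble(gene_id = sprintf("G%03d", 1:4), tissue = "liver")
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(150 * 200), 150, 200)
    y <- rnorm(150)
    fx <- imputed_features(X, tibble::tibble(gene_id = sprintf("G%03d", 1:200),
                                             tissue = "liver"),
                           sprintf("i%03d", 1:150))
    ns_all <- c(ns_all, null_shuffled(signature_features(fx, sig), y,
                                      n_perm = 500, seed = 100 + s))
    nr_all <- c(nr_all, null_random_signatures(fx, sig, y, n_draws = 500,
                                               seed = 200 + s))
  }
  ks <- suppressWarnings(stats::ks.test(ns_all, nr_all)$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("empirical p-values follow the add-one rule", {
  nulls <- seq(0, 1, length.out = 10000)
  expect_equal(empirical_p(2, nulls), 1 / 10001)
  expect_equal(empirical_p(-1, nulls), 1)
  med_nulls <- rnorm(9999)
  expect_equal(empirical_p(stats::median(med_nulls), med_nulls), 0.5,
               tolerance = 0.01)
  # antitone in the observed statistic
  obs <- sort(runif(20))
  ps <- vapply(obs, empirical_p, numeric(1), null_vector = nulls)
  expect_true(all(diff(ps) <= 0))
})

test_that("BH matches a brute-force step-up oracle on dense small grids", {
  expect_equal(fdr_bh(0.04)$q_values, 0.04)
  expect_true(fdr_bh(0.04)$rejected)
  expect_false(any(fdr_bh(rep(1, 5))$rejected))
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04))$rejected))

  set.seed(71)
  grid <- seq(0.01, 1, by = 0.01)
  for (len in 1:8) {
    for (rep in 1:30) {
      p <- sample(grid, len, replace = TRUE)
      got <- fdr_bh(p)$rejected
      expect_identical(got, bh_reject_oracle(p), label = paste(p, collapse = ","))
    }
  }
  # q >= p always
  p <- runif(50)
  expect_true(all(fdr_bh(p)$q_values >= p))
})

test_that("between-study similarity follows per-pair means", {
  A <- make_features(30, 5, seed = 72)
  expect_equal(between_study_similarity(A, A)$rho, 1, tolerance = 1e-12)
  B <- imputed_features(-A$values, A$features, A$individuals)
  expect_equal(between_study_similarity(A, B)$rho, -1, tolerance = 1e-12)
  # 3 shared pairs with perfectly linear means
  mk <- function(mean_vals) imputed_features(
    rbind(mean_vals + 1, mean_vals - 1),
    tibble::tibble(gene_id = c("G001", "G002", "G003"), tissue = "liver"),
    c("a", "b"))
  expect_equal(between_study_similarity(mk(c(1, 2, 3)), mk(c(2, 4, 6)))$rho,
               1, tolerance = 1e-12)
  expect_error(between_study_similarity(
    mk(c(1, 2, 3)),
    imputed_features(matrix(1, 2, 1),
                     tibble::tibble(gene_id = "Z", tissue = "x"),
                     c("a", "b"))), "3 shared")
})

test_that("between-strategy similarity averages per-pair correlations", {
  G <- make_features(20, 4, seed = 73)
  expect_equal(between_strategy_similarity(G, G)$mean_rho, 1,
               tolerance = 1e-12)
  # two pairs: one perfectly correlated, one orthogonal by construction
  v1 <- c(seq_len(10))
  v2 <- rep(c(1, -1), 5)  # cor(v1, shifted alternation) == 0
  Ga <- imputed_features(cbind(v1, v1),
                         tibble::tibble(gene_id = c("G001", "G002"),
                                        tissue = "liver"),
                         sprintf("i%02d", 1:10))
  Gb <- imputed_features(cbind(v1, v2),
                         tibble::tibble(gene_id = c("G001", "G002"),
                                        tissue = "liver"),
                         sprintf("i%02d", 1:10))
  res <- between_strategy_similarity(Ga, Gb)
  expect_equal(res$mean_rho, (1 + cor(v1, v2)) / 2, tolerance = 1e-12)
  # constant pair excluded with a message
  Gc <- imputed_features(cbind(v1, rep(1, 10)), Ga$features, Ga$individuals)
  expect_message(res2 <- between_strategy_similarity(Ga, Gc), "excluded")
  expect_equal(res2$n_pairs, 1)
  expect_equal(res2$mean_rho, 1, tolerance = 1e-12)
})

test_that("single-feature reports handle signal, null and degenerate input", {
  set.seed(74)
  dose <- rnorm(100, 35, 5)
  resid <- dose - 35
  rep1 <- single_feature_report(dose, dose, resid, n_perm = 200, seed = 1)
  expect_equal(rep1$rho, 1, tolerance = 1e-12)
  expect_equal(rep1$r2, 1, tolerance = 1e-12)
  expect_lte(rep1$p_shuffled, 1 / 201 + 1e-12)

  repc <- single_feature_report(rep(2, 100), dose, resid)
  expect_true(is.na(repc$rho))
  expect_match(repc$note, "constant")
})

test_that("signature evaluation assembles r2, nulls, p and FDR report", {
  fx <- make_features(80, 12, seed = 75)
  sig <- signature_from_frequencies(
    tibble::tibble(gene_id = c("G001", "G002"), tissue = "liver",
                   selection_freq = 1),
    training_cohort = "tr", strategy = "generic")
  y <- as.vector(fx$values[, 1:2] %*% c(3, 2)) + rnorm(80)
  ev <- evaluate_signature(sig, fx, y, n_perm = 400, seed = 3)
  expect_gt(ev$r2, 0.8)
  expect_lt(ev$p_shuffled, 0.01)
  expect_lt(ev$p_random, 0.01)
  expect_length(ev$null_shuffled, 400)
  expect_length(ev$null_random, 400)

  rpt <- eval_report(list(ev, ev))
  expect_equal(nrow(rpt), 2)
  expect_true(all(c("q_random", "q_shuffled", "sig_random", "sig_shuffled")
                  %in% names(rpt)))
  expect_true(all(rpt$q_random >= rpt$p_random))
})
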