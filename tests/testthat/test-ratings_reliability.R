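# Judge-score averaging, Cronbach's alpha, trait network, clusters,
# gender contrasts.

toy_table <- function() {
  data.frame(judge_id = c("j1", "j2", "j1", "j2"),
             ratee_id = c("r1", "r1", "r2", "r2"),
             trait = "Friendly",
             score = c(4L, 6L, 9L, 9L))
}

test_that("mean ratings are plain judge averages with counts", {
  mr <- mean_ratings(toy_table())
  expect_equal(mr$means["r1", "Friendly"], 5.0)
  expect_equal(mr$means["r2", "Friendly"], 9.0)
  expect_equal(unname(mr$n_judges["r1", "Friendly"]), 2L)
})

test_that("averaging is invariant to judge order", {
  tab <- toy_table()
  mr1 <- mean_ratings(tab)
  mr2 <- mean_ratings(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(mr1$means, mr2$means)
})

test_that("rating-table validation rejects malformed data", {
  tab <- toy_table()
  bad <- tab; bad$score[2] <- 10L
  expect_error(mean_ratings(bad), "1-9")
  bad <- tab; bad$trait <- "Grumpy"
  expect_error(mean_ratings(bad), "unknown trait")
  bad <- rbind(tab, tab[1, ])
  expect_error(mean_ratings(bad), "duplicate")
  bad <- tab; bad$judge_id[1] <- "r1"
  expect_error(mean_ratings(bad), "themself")
})

test_that("cell means respect the CLT bound under judge noise", {
  coh <- small_cohort()
  mr <- mean_ratings(coh$ratings)
  # every cell mean is an average of 20 scores with judge noise ~1.5 plus
  # bias 0.5; at least 99% of cells must sit within 3 standard errors
  sig <- coh$latents %*% t(coh$spec$rating_loadings)
  colnames(sig) <- rownames(coh$spec$rating_loadings)
  offs <- coh$spec$gender_rating_offsets
  gsign <- ifelse(coh$genders$gender == "F", 0.5, -0.5)
  se <- sqrt(coh$spec$judge_noise^2 + coh$spec$judge_bias_sd^2) / sqrt(20)
  ok <- 0; total <- 0
  for (trait in colnames(mr$means)) {
    mu <- 5 + sig[, trait] + gsign * ifelse(trait %in% names(offs), offs[trait], 0)
    mu <- pmin(pmax(mu, 1), 9)     # clipping pulls extreme cells inward
    inb <- abs(mr$means[, trait] - mu) <= 3 * se + 0.3  # + rounding slack
    ok <- ok + sum(inb); total <- total + length(inb)
  }
  expect_gte(ok / total, 0.99)
})

test_that("Cronbach's alpha matches a spreadsheet-style hand computation", {
  M <- rbind(c(2, 4, 6, 8), c(3, 5, 7, 9), c(1, 4, 6, 9))
  # hand oracle, every intermediate written out
  item_vars <- c(var(c(2, 4, 6, 8)), var(c(3, 5, 7, 9)), var(c(1, 4, 6, 9)))
  totals <- c(2 + 3 + 1, 4 + 5 + 4, 6 + 7 + 6, 8 + 9 + 9)
  oracle <- 3 / 2 * (1 - sum(item_vars) / var(totals))
  expect_equal(cronbach_alpha(M), oracle, tolerance = 1e-12)
})

test_that("alpha is 1 for duplicated judges and near 0 for pure noise", {
  row <- c(2, 5, 7, 3, 8, 1, 6)
  expect_equal(cronbach_alpha(rbind(row, row)), 1.0, tolerance = 1e-12)
  set.seed(1)
  noise <- matrix(rnorm(5 * 500), 5)
  expect_lt(abs(cronbach_alpha(noise)), 0.1)
  expect_error(cronbach_alpha(rbind(row, row)[, c(1, 1, 1)]), "zero total variance")
  expect_error(cronbach_alpha(matrix(row, 1)), "at least 2 judges")
})

test_that("alpha grows with the judge panel as Spearman-Brown predicts", {
  set.seed(8)
  truth <- rnorm(300)
  judge_scores <- function(k) t(sapply(seq_len(k), function(j) truth + rnorm(300, 0, 1.5)))
  alphas <- sapply(c(2, 5, 10, 20), function(k) cronbach_alpha(judge_scores(k)))
  expect_true(all(diff(alphas) > 0))
})

test_that("cohort reliability lands in a plausible band and is seeded", {
  coh <- small_cohort()
  rel <- reliability(coh$ratings, coh$genders, seed = 5)
  expect_equal(nrow(rel), 24L)  # 12 traits x 2 genders
  expect_true(all(rel$alpha > 0.4 & rel$alpha < 0.99))
  rel2 <- reliability(coh$ratings, coh$genders, seed = 5)
  expect_identical(rel, rel2)
  rel_icc <- reliability(coh$ratings, coh$genders, scheme = "icc", seed = 5)
  expect_true(all(abs(rel_icc$alpha - rel$alpha) < 0.2))
})

test_that("identical traits give a unit-correlation edge", {
  coh <- small_cohort()
  mr <- mean_ratings(coh$ratings)
  M <- mr$means
  M[, "Trustworthy"] <- M[, "Friendly"]   # force an identical pair
  mr2 <- structure(list(means = M, n_judges = mr$n_judges),
                   class = "mean_ratings")
  net <- rating_network(mr2, coh$genders)
  e <- net[net$trait_a %in% c("Friendly", "Trustworthy") &
           net$trait_b %in% c("Friendly", "Trustworthy"), ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$r_f, 1.0, tolerance = 1e-12)
  expect_equal(e$scope, "both")
})

test_that("the network is symmetric in its inputs and excludes self-edges", {
  coh <- small_cohort()
  mr <- mean_ratings(coh$ratings)
  net <- rating_network(mr, coh$genders)
  expect_false(any(net$trait_a == net$trait_b))
  # flipping the trait order of the mean matrix leaves the same edge set
  mr_flip <- structure(list(means = mr$means[, rev(colnames(mr$means))],
                            n_judges = mr$n_judges), class = "mean_ratings")
  net2 <- rating_network(mr_flip, coh$genders)
  key <- function(n) sort(paste(pmin(n$trait_a, n$trait_b),
                                pmax(n$trait_a, n$trait_b)))
  expect_identical(key(net), key(net2))
})

test_that("null traits produce edges at about the nominal false-edge rate", {
  # 12 independent traits, 120 ratees, threshold p < .01: the expected
  # number of false edges is 66 * 0.01; across simulations the mean count
  # should sit near that (binomial slack over 300 runs)
  set.seed(60)
  count <- 0
  n_sim <- 300
  for (s in seq_len(n_sim)) {
    M <- matrix(rnorm(120 * 12), 120)
    r <- cor(M)
    n <- 120
    t_ <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_), n - 2)
    count <- count + (sum(p < 0.01) - 12) / 2
  }
  expect_gt(count / n_sim, 66 * 0.01 * 0.5)
  expect_lt(count / n_sim, 66 * 0.01 * 2.0)
})

test_that("block-structured traits cluster into their blocks", {
  # three blocks with within-block r = 0.8, between-block r = 0
  set.seed(13)
  blocks <- list(RATING_TRAITS[1:4], RATING_TRAITS[5:8], RATING_TRAITS[9:12])
  n <- 400
  M <- matrix(0, n, 12, dimnames = list(NULL, RATING_TRAITS))
  for (b in blocks) {
    common <- rnorm(n)
    for (tr in b) M[, tr] <- sqrt(0.8) * common + sqrt(0.2) * rnorm(n)
  }
  cl <- cluster_ratings(cor(M), k = 3)
  for (b in blocks) expect_equal(length(unique(cl[b])), 1L)
  expect_equal(length(unique(cl)), 3L)
  # degenerate cuts
  expect_equal(length(unique(cluster_ratings(cor(M), k = 12))), 12L)
  expect_equal(length(unique(cluster_ratings(cor(M), k = 1))), 1L)
  expect_error(cluster_ratings(cor(M), k = 13), "exceeds")
})

test_that("the default cohort recovers its three generative trait clusters", {
  coh <- small_cohort()
  mr <- mean_ratings(coh$ratings)
  cl <- cluster_ratings(mr, k = 3)
  same <- function(a, b) cl[a] == cl[b]
  expect_true(same("Dominating", "Masculine"))
  expect_true(same("Friendly", "Trustworthy"))
  expect_true(same("Attractive", "Physically Healthy"))
  expect_false(same("Dominating", "Friendly"))
})

test_that("Welch's t matches the closed-form computation", {
  # textbook two-sample case with known summary statistics
  set.seed(3)
  x <- as.vector(scale(rnorm(10))) * 1 + 5   # mean 5, sd 1 exactly
  y <- as.vector(scale(rnorm(10))) * 1 + 6
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 10 + var(y) / 10)
  ids <- sprintf("r%02d", 1:20)
  M <- matrix(c(x, y), ncol = 1, dimnames = list(ids, "Friendly"))
  mr <- structure(list(means = M, n_judges = M * 0 + 20), class = "mean_ratings")
  g <- data.frame(ratee_id = ids, gender = rep(c("F", "M"), each = 10))
  res <- gender_difference_test(mr, g)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  df_hand <- (var(x) / 10 + var(y) / 10)^2 /
    ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
})

test_that("identical gender distributions give t = 0, p = 1", {
  ids <- sprintf("r%02d", 1:20)
  vals <- rep(c(4, 5, 6, 7, 5), 4)
  M <- matrix(vals, ncol = 1, dimnames = list(ids, "Friendly"))
  mr <- structure(list(means = M, n_judges = M * 0 + 20), class = "mean_ratings")
  g <- data.frame(ratee_id = ids, gender = rep(c("F", "M"), times = 10))
  res <- gender_difference_test(mr, g)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
})

test_that("a 0.8-point shift at n = 100 per gender is detected reliably", {
  # analytic power: t ~ N(0.8 / sqrt(2/100), 1) = N(5.66, 1); at the
  # p < 1e-4 threshold (|t| > 3.9) the detection rate is ~96%
  set.seed(17)
  hits <- 0
  for (s in 1:200) {
    x <- rnorm(100, 5.8, 1); y <- rnorm(100, 5.0, 1)
    p <- t.test(x, y, var.equal = FALSE)$p.value
    hits <- hits + (p < 1e-4)
  }
  expect_gte(hits / 200, 0.90)
})

test_that("the default cohort shows its injected gender contrasts", {
  coh <- small_cohort()
  mr <- mean_ratings(coh$ratings)
  res <- gender_difference_test(mr, coh$genders)
  expect_equal(res$direction[res$trait == "Responsible"], "women_higher")
  expect_equal(res$direction[res$trait == "Emotionally Stable"], "men_higher")
})
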