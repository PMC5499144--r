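sft_simple <- function(orfs, values, screen_id, background = "query",
                       treatment = "chronic") {
  tab <- data.frame(orf = orfs, gene = orfs, n = 2,
                    mdr_mean = NA_real_, mdp_mean = NA_real_,
                    fitness_mean = values, fitness_median = values)
  structure(list(screen_id = screen_id, background = background,
                 treatment = treatment, table = tab,
                 replicates = stats::setNames(lapply(values, rep, 2), orfs),
                 cultures = NULL),
            class = "screen_fitness_table")
}

test_that("profile matrix unions genes and marks absences missing", {
  tabs <- list(sft_simple(c("A", "B", "C"), c(1, 2, 3), "S1"),
               sft_simple(c("A", "B", "C"), c(2, 3, 4), "S2"),
               sft_simple(c("A", "B", "C", "D"), c(3, 4, 5, 9), "S3"))
  pm <- build_profile_matrix(tabs, "fitness")
  expect_equal(dim(pm$values), c(4, 3))
  expect_equal(sum(is.na(pm$values["D", ])), 2)
  expect_equal(sum(is.na(pm$values[c("A", "B", "C"), ])), 0)
  expect_identical(pm$genes, c("A", "B", "C", "D"))  # lexicographic
})

test_that("duplicate screen labels and mixed kinds are rejected", {
  tabs <- list(sft_simple(c("A", "B", "C"), 1:3, "S1"),
               sft_simple(c("A", "B", "C"), 2:4, "S1"))
  expect_error(build_profile_matrix(tabs, "fitness"), "duplicate screen")
  expect_error(build_profile_matrix(tabs, "gis"), "interaction_table")
  expect_error(build_profile_matrix(tabs[1], "fitness"), "at least 2")
})

test_that("normalization z-scores each column and is idempotent", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(10, 30, 20))
  rownames(v) <- c("A", "B", "C")
  pm <- normalize_profiles(qfascreen:::new_profile_matrix(v, "fitness"))
  expect_equal(pm$values[, "s1"], c(A = -1, B = 0, C = 1))
  pm2 <- normalize_profiles(pm)
  expect_equal(pm2$values, pm$values, tolerance = 1e-12)
  # contract: means ~ 0, sds ~ 1
  expect_lt(max(abs(colMeans(pm$values))), 1e-12)
  expect_equal(unname(apply(pm$values, 2, sd)), c(1, 1), tolerance = 1e-12)
})

test_that("normalization preserves the missing mask and flags degeneracy", {
  v <- cbind(s1 = c(1, 2, 3, NA), s2 = c(5, 5, 5, 5))
  rownames(v) <- LETTERS[1:4]
  pm <- qfascreen:::new_profile_matrix(v, "fitness")
  expect_error(normalize_profiles(pm), "degenerate column.*s2")
  v2 <- cbind(s1 = c(1, 2, 3, NA), s2 = c(5, 6, 7, 8))
  rownames(v2) <- LETTERS[1:4]
  pm2 <- normalize_profiles(qfascreen:::new_profile_matrix(v2, "fitness"))
  expect_true(is.na(pm2$values["D", "s1"]))
})

test_that("similarity ranking finds identical and inverted profiles", {
  set.seed(31)
  v <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("Y%02d", 1:20), sprintf("s%d", 1:6)))
  v["Y02", ] <- v["Y01", ]            # clone of the query
  v["Y03", ] <- -v["Y01", ]           # inverted profile
  pm <- qfascreen:::new_profile_matrix(v, "fitness")
  rk <- rank_similar_profiles(pm, "Y01", metric = "pearson")
  expect_identical(rk$orf[1], "Y02")
  expect_equal(rk$similarity[1], 1)
  expect_identical(rk$orf[nrow(rk)], "Y03")
  expect_equal(rk$similarity[nrow(rk)], -1)
  expect_false("Y01" %in% rk$orf)    # query excluded
  expect_equal(rk$position, seq_len(nrow(rk)))
  expect_true(all(diff(rk$similarity) <= 0))
  # euclidean: the clone is at distance 0
  rk2 <- rank_similar_profiles(pm, "Y01", metric = "euclidean")
  expect_identical(rk2$orf[1], "Y02")
  expect_equal(rk2$similarity[1], 0)
})

test_that("overlap below min_overlap excludes a gene from the ranking", {
  v <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(sprintf("Y%02d", 1:5), sprintf("s%d", 1:6)))
  v["Y02", 3:6] <- NA
  pm <- qfascreen:::new_profile_matrix(v, "fitness")
  rk <- rank_similar_profiles(pm, "Y01", min_overlap = 4)
  expect_false("Y02" %in% rk$orf)
  expect_true(all(rk$n_overlap >= 4))
  rk2 <- rank_similar_profiles(pm, "Y01", min_overlap = 2)
  expect_true("Y02" %in% rk2$orf)
  v["Y03", ] <- NA
  pm2 <- qfascreen:::new_profile_matrix(v, "fitness")
  expect_error(rank_similar_profiles(pm2, "Y03"), "no profile")
})

test_that("normalized ranking is invariant to per-screen affine rescaling", {
  set.seed(8)
  v <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("Y%02d", 1:30), sprintf("s%d", 1:8)))
  pm <- qfascreen:::new_profile_matrix(v, "fitness")
  # each screen remeasured on its own scale and offset
  v2 <- sweep(sweep(v, 2, runif(8, 0.5, 4), `*`), 2, rnorm(8), `+`)
  pm2 <- qfascreen:::new_profile_matrix(v2, "fitness")
  # normalization removes per-screen scale exactly ...
  expect_equal(normalize_profiles(pm2)$values, normalize_profiles(pm)$values,
               tolerance = 1e-12)
  # ... so the normalize-then-rank workflow gives identical rankings
  rk1 <- rank_similar_profiles(normalize_profiles(pm), "Y05")
  rk2 <- rank_similar_profiles(normalize_profiles(pm2), "Y05")
  expect_identical(rk1$orf, rk2$orf)
  expect_equal(rk1$similarity, rk2$similarity, tolerance = 1e-10)
  # pearson similarity itself ignores per-gene affine changes of one profile
  v3 <- v
  v3["Y07", ] <- 2.5 * v["Y07", ] + 1
  rk_raw <- rank_similar_profiles(pm, "Y05")
  rk3 <- rank_similar_profiles(qfascreen:::new_profile_matrix(v3, "fitness"),
                               "Y05")
  expect_equal(rk3$similarity[rk3$orf == "Y07"],
               rk_raw$similarity[rk_raw$orf == "Y07"], tolerance = 1e-10)
})

test_that("similarity is symmetric and rankings are deterministic", {
  set.seed(12)
  v <- matrix(rnorm(15 * 7), 15, 7,
              dimnames = list(sprintf("Y%02d", 1:15), sprintf("s%d", 1:7)))
  pm <- qfascreen:::new_profile_matrix(v, "fitness")
  for (metric in c("pearson", "euclidean")) {
    rka <- rank_similar_profiles(pm, "Y01", metric = metric)
    rkb <- rank_similar_profiles(pm, "Y02", metric = metric)
    expect_equal(rka$similarity[rka$orf == "Y02"],
                 rkb$similarity[rkb$orf == "Y01"])
    expect_identical(rank_similar_profiles(pm, "Y01", metric = metric), rka)
  }
})

test_that("a planted co-functional module is recovered by ranking", {
  sim <- simulate_profile_matrix(n_genes = 200, n_screens = 12,
                                 module_size = 10, noise_sd = 0.3, seed = 3)
  pm <- normalize_profiles(sim$matrix)
  rk <- rank_similar_profiles(pm, sim$module[1], metric = "pearson")
  top20 <- rk$orf[1:20]
  expect_gte(sum(sim$module[-1] %in% top20), 8)
})
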