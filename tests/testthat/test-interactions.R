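# build a screen_fitness_table directly from per-gene replicate vectors
sft_from_reps <- function(reps, screen_id = "S", background = "control") {
  orf <- names(reps)
  tab <- data.frame(orf = orf, gene = orf, n = lengths(reps),
                    mdr_mean = NA_real_, mdp_mean = NA_real_,
                    fitness_mean = vapply(reps, mean, 0),
                    fitness_median = vapply(reps, median, 0))
  structure(list(screen_id = screen_id, background = background,
                 treatment = "chronic", table = tab, replicates = reps,
                 cultures = NULL),
            class = "screen_fitness_table")
}

reps_of <- function(means, noise = 0, n = 3, seed = 1) {
  set.seed(seed)
  out <- lapply(means, function(m) m + rnorm(n, 0, noise))
  names(out) <- sprintf("Y%03dW", seq_along(means))
  out
}

test_that("exact proportionality gives the exact slope under both methods", {
  ctl <- sft_from_reps(reps_of(1:20 / 2))
  qry <- sft_from_reps(lapply(ctl$replicates, `*`, 0.5), background = "query")
  expect_equal(estimate_independence_slope(ctl, qry, "lsq_origin"), 0.5)
  expect_equal(estimate_independence_slope(ctl, qry, "robust"), 0.5)
})

test_that("least-squares slope matches the closed form Sxy/Sxx", {
  ctl <- sft_from_reps(reps_of(c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2)))
  y <- c(0.5, 1, 1.5, 4, 0.5, 1, 1.5, 4, 0.5, 1)
  qry <- sft_from_reps(stats::setNames(
    lapply(y, rep, 3), names(ctl$replicates)), background = "query")
  x <- c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2)
  expect_equal(estimate_independence_slope(ctl, qry, "lsq_origin"),
               sum(x * y) / sum(x^2))
  # the outliers at x=4 pull lsq_origin up; the robust slope resists them
  m_lsq <- estimate_independence_slope(ctl, qry, "lsq_origin")
  m_rob <- estimate_independence_slope(ctl, qry, "robust")
  expect_lt(abs(m_rob - 0.5), abs(m_lsq - 0.5))
})

test_that("robust slope agrees with an independent M-estimator", {
  skip_if_not_installed("MASS")
  set.seed(14)
  x <- runif(200, 1, 40)
  y <- 0.6 * x + rnorm(200, 0, 0.5)
  out <- sample(200, 20)
  y[out] <- y[out] * 2    # planted suppressors
  ctl <- sft_from_reps(stats::setNames(lapply(x, rep, 2),
                                       sprintf("Y%03dW", 1:200)))
  qry <- sft_from_reps(stats::setNames(lapply(y, rep, 2),
                                       names(ctl$replicates)),
                       background = "query")
  m_rob <- estimate_independence_slope(ctl, qry, "robust")
  m_ref <- unname(coef(MASS::rlm(y ~ x - 1, psi = MASS::psi.bisquare,
                                 maxit = 100)))
  expect_equal(m_rob, m_ref, tolerance = 0.02)
})

test_that("slope estimation guards its preconditions", {
  ctl <- sft_from_reps(reps_of(1:5))
  qry <- sft_from_reps(lapply(ctl$replicates, `*`, 0.5), background = "query")
  expect_error(estimate_independence_slope(ctl, qry), "insufficient overlap")
  z <- sft_from_reps(stats::setNames(lapply(rep(0, 12), rep, 3),
                                     sprintf("Y%03dW", 1:12)))
  expect_error(estimate_independence_slope(z, z), "degenerate screen")
})

test_that("GIS is the deviation from the independence prediction", {
  ctl <- sft_from_reps(reps_of(c(4, rep(2, 11)), noise = 0.05, seed = 2))
  qry <- sft_from_reps(reps_of(c(3, rep(1, 11)), noise = 0.05, seed = 3),
                       background = "query")
  it <- compute_interactions(ctl, qry, m = 0.5)
  g1 <- it[it$orf == "Y001W", ]
  expect_equal(g1$gis, g1$F_query - 0.5 * g1$F_control)
  expect_gt(g1$gis, 0.9)  # suppressor direction
  expect_equal(it$F_pred, 0.5 * it$F_control)
})

test_that("identical screens give m = 1 and all-zero GIS", {
  cfg <- tiny_config()
  sft <- summarize_screen(simulate_screen_pair(cfg)$control)
  expect_equal(estimate_independence_slope(sft, sft), 1)
  it <- compute_interactions(sft, sft)
  expect_equal(max(abs(it$gis)), 0)
  expect_true(all(it$call == "none"))
})

test_that("GIS is equivariant under common fitness rescaling", {
  cfg <- tiny_config(planted_fraction_sup = 0.1, seed = 19L)
  sim <- simulate_screen_pair(cfg)
  ctl <- summarize_screen(sim$control)
  qry <- summarize_screen(sim$query)
  it1 <- compute_interactions(ctl, qry)
  scale_sft <- function(s, c) {
    s$replicates <- lapply(s$replicates, `*`, c)
    s$table$fitness_mean <- s$table$fitness_mean * c
    s$table$fitness_median <- s$table$fitness_median * c
    s
  }
  it2 <- compute_interactions(scale_sft(ctl, 3), scale_sft(qry, 3))
  expect_equal(attr(it2, "m"), attr(it1, "m"), tolerance = 1e-10)
  expect_equal(it2$gis, 3 * it1$gis, tolerance = 1e-8)
  expect_equal(it2$p, it1$p, tolerance = 1e-8)
  expect_identical(it2$call, it1$call)
})

test_that("genes with too few replicates are flagged, not called", {
  ctl <- sft_from_reps(reps_of(1:12, noise = 0.05))
  qry <- sft_from_reps(reps_of(1:12 / 2, noise = 0.05, seed = 2),
                       background = "query")
  qry$replicates[["Y001W"]] <- qry$replicates[["Y001W"]][1]
  it <- compute_interactions(ctl, qry, m = 0.5)
  r1 <- it[it$orf == "Y001W", ]
  expect_true(is.na(r1$p) && is.na(r1$q))
  expect_identical(r1$call, "none")
  expect_true(r1$flagged)
})

test_that("bh_fdr matches its frozen examples and passes NA through", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.005, NA, 0.1)), c(0.01, NA, 0.1))
  expect_error(bh_fdr(c(0.5, 1.2)), "invalid input")
  expect_error(bh_fdr(c(-0.1, 0.5)), "invalid input")
})

test_that("bh_fdr agrees with brute-force enumeration on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    p <- round(runif(sample(1:12, 1)), 3)
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
})
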