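# Benchmark statistics: flat-file parsing, deviations, metrics, bootstrap,
# deviation counts, group and size summaries

write_fixture <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

demo_records <- function(n = 50, seed = 1, sd = 1.2) {
  set.seed(seed)
  expt <- runif(n, -25, 2)
  data.frame(compound_id = sprintf("toy_%04d", seq_len(n)),
             smiles = rep("CCO", n), name = sprintf("cmp%d", seq_len(n)),
             expt = expt, expt_unc = runif(n, 0, 0.6),
             calc = expt + rnorm(n, 0, sd), calc_unc = runif(n, 0, 0.3),
             stringsAsFactors = FALSE)
}

test_that("FreeSolv-style parsing round-trips records and reports bad lines", {
  f <- write_fixture(c(
    "# synthetic two-record fixture in the upstream column layout",
    "# id; SMILES; iupac name; expt (kcal/mol); d(expt); calc; d(calc)",
    "toy_000001; OC1=CC=CC=C1; phenol-like; -6.62; 0.20; -5.90; 0.06",
    "toy_000002; O=C1NC(=O)NC(=O)N1; triazine-trione-like; -18.06; 0.50; -29.65; 0.20"))
  rec <- parse_freesolv(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$compound_id, c("toy_000001", "toy_000002"))
  # the printed experimental value parses exactly
  expect_equal(rec$expt[2], -18.06)
  expect_equal(rec$calc[2], -29.65)
  # comment-only file: empty record set
  empty <- parse_freesolv(write_fixture(c("# nothing", "# here")))
  expect_equal(nrow(empty), 0L)
  # wrong column count is a parse error naming the line
  bad <- write_fixture(c("# hdr", "id; smiles; name; -1.0; 0.1"))
  expect_error(parse_freesolv(bad), "line.*2")
})

test_that("deviations reproduce the printed arithmetic", {
  # largest negative outlier: calc -29.65 vs expt -18.06 misses by 11.59
  d <- deviation(-29.65, -18.06)
  expect_equal(d$absolute, 11.59)
  expect_equal(d$signed, -11.59)
  # most positive outlier: calc -15.51 vs expt -25.47 -> signed +9.96
  expect_equal(deviation(-15.51, -25.47)$signed, 9.96)
  expect_equal(deviation(3.3, 3.3)$absolute, 0)
})

test_that("error metrics match independent textbook formulas", {
  # perfect agreement
  rec <- data.frame(calc = c(1, 2, 3), expt = c(1, 2, 3))
  m <- error_metrics(rec)
  expect_equal(m$rmse, 0); expect_equal(m$mae, 0)
  expect_equal(m$pearson_r, 1); expect_equal(m$spearman_rho, 1)
  # closed form: pairs (0,1), (0,-1); the constant calc vector makes the
  # correlations undefined but leaves RMSE/MAE well defined
  rec2 <- data.frame(calc = c(0, 0), expt = c(1, -1))
  expect_warning(m2 <- error_metrics(rec2), "constant")
  expect_equal(m2$rmse, 1); expect_equal(m2$mae, 1)
  expect_true(is.na(m2$pearson_r) && is.na(m2$spearman_rho))
  # 50 random points vs hand-rolled formulas
  rec3 <- demo_records(50, seed = 7)
  m3 <- error_metrics(rec3)
  d <- rec3$calc - rec3$expt
  expect_equal(m3$rmse, sqrt(sum(d^2) / 50), tolerance = 1e-10)
  expect_equal(m3$mae, sum(abs(d)) / 50, tolerance = 1e-10)
  x <- rec3$calc; y <- rec3$expt
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m3$pearson_r, r_hand, tolerance = 1e-10)
  rho_hand <- {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(m3$spearman_rho, rho_hand, tolerance = 1e-10)
  expect_gte(m3$rmse, m3$mae)
  expect_warning(error_metrics(data.frame(calc = c(1, 1), expt = c(1, 2))),
                 "constant")
})

test_that("RMSE >= MAE for arbitrary data (Jensen)", {
  for (seed in 1:10) {
    rec <- demo_records(sample(5:60, 1), seed = seed, sd = runif(1, 0.1, 4))
    m <- error_metrics(rec)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("bootstrap confidence intervals behave", {
  # constant deviations: zero-width interval at the point value
  rec <- data.frame(calc = c(2, 3, 4, 5) + 1, expt = c(2, 3, 4, 5))
  ci <- bootstrap_ci(rec, "mae", B = 200, seed = 3)
  expect_equal(ci, c(1, 1))
  # interval contains the point estimate and is reproducible
  rec2 <- demo_records(40, seed = 5)
  m <- error_metrics(rec2)
  for (metric in c("rmse", "mae", "pearson_r")) {
    ci <- bootstrap_ci(rec2, metric, B = 400, seed = 9)
    pt <- switch(metric, rmse = m$rmse, mae = m$mae, pearson_r = m$pearson_r)
    expect_lte(ci[1], pt); expect_gte(ci[2], pt)
    expect_identical(ci, bootstrap_ci(rec2, metric, B = 400, seed = 9))
  }
  # degenerate B = 1 yields a valid (zero-width) interval without crashing
  ci1 <- bootstrap_ci(rec2, "rmse", B = 1, seed = 2)
  expect_equal(ci1[1], ci1[2])
  # width shrinks roughly as n^(-1/2)
  w <- sapply(c(100, 400), function(n) {
    r <- demo_records(n, seed = 11)
    ci <- bootstrap_ci(r, "rmse", B = 300, seed = 13)
    ci[2] - ci[1]
  })
  expect_lt(w[2], w[1])
})

test_that("deviation counts by threshold", {
  rec0 <- data.frame(calc = c(1, 2, 3), expt = c(1, 2, 3))
  expect_equal(deviation_counts(rec0)$count, c(0L, 0L, 0L, 0L))
  # deviations {1, 2.5, 5, 7}: >2 -> 3, >3 -> 2, >4 -> 2, >6 -> 1
  rec <- data.frame(calc = c(1, 2.5, 5, 7), expt = c(0, 0, 0, 0))
  tab <- deviation_counts(rec)
  expect_equal(tab$count, c(3L, 2L, 2L, 1L))
  expect_equal(tab$percent, 100 * c(3, 2, 2, 1) / 4)
  # monotone non-increasing in the threshold for arbitrary data
  for (seed in 1:5) {
    r <- demo_records(30, seed = seed, sd = 3)
    expect_true(all(diff(deviation_counts(r)$count) <= 0))
  }
  # threshold 0+ counts everything but exact matches
  r2 <- data.frame(calc = c(1, 2, 3.5), expt = c(1, 2, 3))
  expect_equal(deviation_counts(r2, thresholds = 1e-12)$count, 1L)
})

test_that("group summaries use the first category and a 10-member floor", {
  # one group of ten identical deviations
  rec <- data.frame(calc = rep(1.7, 10), expt = rep(0, 10),
                    group = rep("alcohol", 10))
  gs <- group_summary(rec)
  expect_equal(gs$summary$mae, 1.7)
  expect_equal(gs$summary$median_ae, 1.7)
  expect_equal(gs$summary$q3 - gs$summary$q1, 0)
  # a 9-member group is excluded and listed below threshold
  rec9 <- data.frame(calc = rnorm(9), expt = rep(0, 9),
                     group = rep("amine", 9))
  gs9 <- group_summary(rec9)
  expect_equal(nrow(gs9$summary), 0L)
  expect_equal(gs9$below_threshold$group, "amine")
  # MAE >= median flag matches direct computation on random data
  set.seed(8)
  recr <- data.frame(calc = rnorm(40, 0, 2), expt = 0,
                     group = rep(c("ether", "ester"), each = 20))
  gsr <- group_summary(recr)
  for (g in gsr$summary$group) {
    v <- abs(recr$calc[recr$group == g])
    expect_equal(gsr$summary$mae[gsr$summary$group == g], mean(v))
    expect_equal(gsr$summary$median_ae[gsr$summary$group == g], median(v))
  }
  # first-category assignment from a groups file
  recs <- demo_records(3)
  gf <- write_fixture(c("# id; categories...",
                        "toy_0001; alcohol; aromatic",
                        "toy_0002; amine",
                        "toy_0003; ether; alcohol"))
  withg <- assign_groups(recs, gf)
  expect_equal(withg$group, c("alcohol", "amine", "ether"))
})

test_that("heavy atoms are counted from SMILES including halogens", {
  expect_equal(count_heavy_atoms(c("CCO", "c1ccccc1", "Cc1ccccc1")),
               c(3L, 6L, 7L))
  expect_equal(count_heavy_atoms("ClC(Cl)(Cl)Cl"), 5L)
  expect_equal(count_heavy_atoms("BrCCBr"), 4L)
  expect_equal(count_heavy_atoms("[2H]O[2H]"), 1L)   # heavy water: one O
  expect_equal(count_heavy_atoms("O=C(O)c1ccccc1"), 9L)
  expect_equal(count_heavy_atoms("[Na+].[Cl-]"), 2L)
  expect_equal(count_heavy_atoms("C[nH0]1ccnc1"), 6L)
})

test_that("error by size bins MAE by heavy-atom count", {
  rec <- data.frame(calc = c(1, 2, 2, 4, 4, 4), expt = rep(0, 6),
                    heavy_atoms = c(2, 2, 2, 5, 5, 9))
  tab <- error_by_size(rec, B = 200, seed = 4)
  expect_equal(tab$mae, c(mean(c(1, 2, 2)), 4, 4))
  # single-molecule bin carries no band
  expect_true(is.na(tab$ci_low[tab$heavy_atoms == 9]))
  expect_false(is.na(tab$ci_low[tab$heavy_atoms == 2]))
  # pooled MAE equals the weighted mean of the bin MAEs
  expect_equal(sum(tab$mae * tab$n) / sum(tab$n),
               mean(abs(rec$calc - rec$expt)))
  # all same size: one bin equal to the global MAE
  rec1 <- data.frame(calc = c(1, 3), expt = c(0, 0), heavy_atoms = c(4, 4))
  tab1 <- error_by_size(rec1, B = 50, seed = 1)
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$mae, 2)
  # from SMILES when counts are absent
  rec2 <- demo_records(4)
  tab2 <- error_by_size(rec2, B = 50, seed = 2)
  expect_equal(tab2$heavy_atoms, 3L)
})

test_that("the packaged synthetic benchmark fixture parses and summarises", {
  f <- system.file("extdata", "synthetic_freesolv.txt", package = "saisolv")
  g <- system.file("extdata", "synthetic_groups.txt", package = "saisolv")
  rec <- parse_freesolv(f)
  expect_gt(nrow(rec), 20)
  rec <- assign_groups(rec, g)
  m <- error_metrics(rec, ci = TRUE, B = 300, seed = 1)
  expect_true(is.finite(m$rmse) && m$rmse >= m$mae)
  expect_length(m$ci$rmse, 2L)
  tab <- deviation_counts(rec)
  expect_true(all(diff(tab$count) <= 0))
  gs <- group_summary(rec, min_members = 5)
  expect_true(nrow(gs$summary) >= 1)
  expect_true(all(gs$below_threshold$n < 5))
})
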