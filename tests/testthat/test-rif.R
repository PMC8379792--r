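# 4 genes x 12 samples, 6 per condition, with g1 a "TF" and g2-g4 DE genes.
rif_fixture <- function(seed = 5) {
  set.seed(seed)
  m <- toy_em(matrix(rexp(4 * 12), 4, 12))
  list(m = m, d = toy_design(m),
       de = make_declass(c("g2", "g3", "g4"), c(2.5, -2.1, 3.0),
                         c("up", "down", "up")))
}

test_that("build_rif_input computes per-condition TF-to-DE correlations", {
  fx <- rif_fixture()
  # make the TF identical to g2 within condition A (columns 1:6)
  v <- fx$m$values
  v["g1", 1:6] <- v["g2", 1:6]
  m <- toy_em(v, samples = colnames(v))
  input <- build_rif_input(m, fx$de, "g1", fx$d)
  expect_equal(input$r_ref["g1", "g2"], 1)
  expect_identical(input$de_ids, c("g2", "g3", "g4"))
  expect_identical(input$tf_ids, "g1")
  expect_equal(input$a, rowMeans(v[c("g2", "g3", "g4"), ]),
               ignore_attr = TRUE)
})

test_that("flat profiles correlate as 0 with a warning; absent TFs reported", {
  fx <- rif_fixture()
  v <- fx$m$values
  v["g1", 1:6] <- 7            # TF constant within condition A
  m <- toy_em(v, samples = colnames(v))
  expect_warning(input <- build_rif_input(m, fx$de, c("g1", "NOTHERE"), fx$d),
                 "zero-variance")
  expect_equal(unname(input$r_ref["g1", ]), c(0, 0, 0))
  expect_identical(input$missing_tfs, "NOTHERE")
})

test_that("build_rif_input enforces its preconditions", {
  fx <- rif_fixture()
  expect_error(build_rif_input(fx$m, fx$de, "NOPE", fx$d), "no catalog TF")
  none <- make_declass("g2", 0.1, "ns")
  expect_error(build_rif_input(fx$m, none, "g1", fx$d),
               "no differentially expressed")
  small <- toy_em(fx$m$values[, 1:4], samples = colnames(fx$m$values)[1:4])
  expect_error(build_rif_input(small, fx$de, "g1", toy_design(small)),
               ">= 3 samples")
})

test_that("identical data in both conditions zeroes both raw RIF scores", {
  set.seed(7)
  half <- matrix(rexp(6 * 5), 6, 5)
  m <- toy_em(cbind(half, half))          # condition B duplicates condition A
  d <- toy_design(m)
  de <- make_declass(c("g3", "g4", "g5", "g6"), c(2, -2, 2.2, -2.2),
                     c("up", "down", "up", "down"))
  expect_warning(
    rt <- rif_scores(build_rif_input(m, de, c("g1", "g2"), d)),
    "zero variance of raw RIF")
  expect_equal(rt$rif1_raw, c(0, 0))
  expect_equal(rt$rif2_raw, c(0, 0))
})

test_that("rif_scores standardizes across TFs and needs >= 2 of them", {
  set.seed(13)
  m <- toy_em(matrix(rexp(10 * 12), 10, 12))
  d <- toy_design(m)
  de <- make_declass(c("g6", "g7", "g8"), c(2.2, -2.5, 3.1),
                     c("up", "down", "up"))
  input <- build_rif_input(m, de, c("g1", "g2", "g3", "g4", "g5"), d)
  rt <- rif_scores(input)
  expect_lt(abs(mean(rt$RIF1)), 1e-10)
  expect_equal(sd(rt$RIF1), 1, tolerance = 1e-12)
  expect_equal(sd(rt$RIF2), 1, tolerance = 1e-12)
  expect_identical(rt$sig1, abs(rt$RIF1) > 1.96)

  solo <- build_rif_input(m, de, "g1", d)
  expect_error(rif_scores(solo), ">= 2 TFs")
})

test_that("swapping conditions negates both raw RIF scores", {
  set.seed(17)
  m <- toy_em(matrix(rexp(10 * 12), 10, 12))
  de <- make_declass(c("g6", "g7", "g8"), c(2.2, -2.5, 3.1),
                     c("up", "down", "up"))
  tfs <- c("g1", "g2", "g3")
  fwd <- rif_scores(build_rif_input(m, de, tfs, toy_design(m, "A")))
  # under a label swap the Eq-3 diff (hence PIF) negates and the condition
  # roles of r/e exchange: both raw scores negate exactly
  de_sw <- de; de_sw$diff <- -de$diff
  bwd <- rif_scores(build_rif_input(m, de_sw, tfs, toy_design(m, "B")))
  expect_equal(bwd$rif1_raw, -fwd$rif1_raw)
  expect_equal(bwd$rif2_raw, -fwd$rif2_raw)
})

test_that("rif_scores is invariant to DE-gene and TF ordering", {
  set.seed(19)
  m <- toy_em(matrix(rexp(12 * 12), 12, 12))
  d <- toy_design(m)
  de <- make_declass(c("g7", "g8", "g9", "g10"), c(2, -2.2, 2.4, -2.6),
                     c("up", "down", "up", "down"))
  tfs <- c("g1", "g2", "g3", "g4")
  a <- rif_scores(build_rif_input(m, de, tfs, d))
  de_perm <- de[c(3, 1, 4, 2), ]
  b <- rif_scores(build_rif_input(m, de_perm, rev(tfs), d))
  b <- b[match(a$TF, b$TF), ]
  expect_equal(b$rif1_raw, a$rif1_raw)
  expect_equal(b$rif2_raw, a$rif2_raw)
})

test_that("a planted differentially wired TF attains the top |RIF1|", {
  sim <- sim_counts(sim_spec(n_genes = 60, n_tfs = 21, planted_module_size = 15,
                             n_samples_per_condition = 40, seed = 71))
  res <- analyze(sim$matrix, sim$design, sim$tfs)
  rt <- res$rif_table
  expect_identical(rt$TF[which.max(abs(rt$RIF1))], sim$truth$planted_tf)
})

test_that("significant_tfs applies a strict 1.96 cutoff, ordered by impact", {
  rt <- make_rif_table(c("b", "a", "c", "d"),
                       RIF1 = c(1.409, -2.016, 0.5, 2.10),
                       RIF2 = c(2.189, -0.005, -1.96, -2.10))
  out <- significant_tfs(rt)
  # b (2.189) and a (2.016) significant; c exactly at 1.96 is not;
  # d ties at 2.10 on both scores and sorts between by magnitude then id
  expect_identical(out, c("b", "d", "a"))
})

test_that("under pure noise the significant-TF rate stays near nominal", {
  set.seed(29)
  m <- toy_em(matrix(rexp(150 * 20), 150, 20))
  d <- toy_design(m)
  dt <- reverter_diff(m, d)
  tfs <- sprintf("g%d", 1:100)
  de <- classify_de(dt, 1.96, tfs)
  rt <- rif_scores(build_rif_input(m, de, tfs, d))
  expect_lt(mean(rt$sig1 | rt$sig2), 0.15)
})

test_that("read_tf_catalog skips comments/blanks and rejects empty files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# catalog", "TP53", "", "GATA1", "TP53"), path)
  expect_identical(read_tf_catalog(path), c("TP53", "GATA1"))
  writeLines("# nothing", path)
  expect_error(read_tf_catalog(path), "empty")
})
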