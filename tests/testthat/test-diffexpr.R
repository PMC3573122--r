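test_that("quantile_normalize forces identical column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  expect_identical(dimnames(out), dimnames(m))

  # identical columns are left unchanged
  m2 <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2)

  expect_error(quantile_normalize(m[, 1, drop = FALSE]), "2 columns")
})

test_that("quantile_normalize: sorted columns agree and it is idempotent", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      m <- matrix(rnorm(40 * 4, 8, 2), 40,
                  dimnames = list(paste0("g", 1:40), paste0("s", 1:4)))
      out <- quantile_normalize(m)
      ref <- unname(sort(out[, 1]))
      for (j in 2:4) expect_equal(unname(sort(out[, j])), ref)
      expect_equal(quantile_normalize(out), out)
    }
  })
})

test_that("differential handles degenerate and simple inputs", {
  m <- rbind(flat = c(5, 5, 5, 5, 5, 5),
             avg  = c(7, 7, 7, 9, 9, 9))
  colnames(m) <- paste0("s", 1:6)
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        condition = rep(c("t", "c"), each = 3),
                        replicate = rep(1:3, 2))
  de <- differential(m, samples, c("t", "c"), prior_df = 4,
                     prior_var = 0.01)
  expect_equal(de$logFC[de$feature_id == "flat"], 0)
  expect_equal(de$t_mod[de$feature_id == "flat"], 0)
  expect_equal(de$AveExpr[de$feature_id == "avg"], 8)
  # sign(logFC) == sign(t_mod)
  expect_true(all(sign(de$logFC) == sign(de$t_mod)))

  expect_error(differential(m, samples, c("t", "x")), "unknown condition")
  s2 <- samples; s2$condition <- c("t", rep("c", 5))
  expect_error(differential(m, s2, c("t", "c")), "2 replicates")

  # zero variance everywhere and zero prior: nonzero logFC maps to p = 0
  expect_warning(
    de0 <- differential(m, samples, c("t", "c"), prior_df = 0),
    "zero-variance")
  expect_identical(de0$p[de0$feature_id == "avg"], 0)
})

test_that("prior_df = 0 reduces to the ordinary pooled two-sample t", {
  withr::with_seed(31, {
    for (rep in 1:3) {
      m <- matrix(rnorm(50 * 6, 8, 1), 50,
                  dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
      samples <- data.frame(sample_id = paste0("s", 1:6),
                            condition = rep(c("t", "c"), each = 3),
                            replicate = rep(1:3, 2))
      de <- differential(m, samples, c("t", "c"), prior_df = 0)
      for (i in c(1, 17, 50)) {
        tt <- t.test(m[i, 1:3], m[i, 4:6], var.equal = TRUE)
        expect_equal(de$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
        expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
      }
    }
  })
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(41, {
    for (rep in 1:10) {
      p <- runif(sample(1:200, 1))
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
  # adjP >= p and order preservation
  withr::with_seed(42, {
    p <- runif(100)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  })
})

test_that("categorize applies strict logFC/adjP and inclusive AveExpr cuts", {
  de <- make_de(c("CAV1", "edgeFC", "dim", "upg", "edgeAE"),
                aveexpr = c(15.28, 10, 6.9, 9, 7.0),
                logfc = c(-1.78, -0.7, -2, 1.2, -1.0),
                adjp = c(0.001, 0.001, 0.001, 0.01, 0.05))
  cs <- categorize(de, de_thresholds(7.0, 0.7, 0.05))
  expect_true("CAV1" %in% cs$down)
  expect_false("edgeFC" %in% cs$down)     # logFC exactly -0.7: strict
  expect_false("dim" %in% cs$background)  # AveExpr 6.9 < 7.0
  expect_true("edgeAE" %in% cs$background) # AveExpr exactly 7.0: inclusive
  expect_false("edgeAE" %in% cs$down)     # adjP exactly 0.05: strict
  expect_identical(cs$up, "upg")
  expect_length(intersect(cs$up, cs$down), 0L)
  expect_true(all(c(cs$up, cs$down) %in% cs$background))
})

test_that("threshold presets expose the two published screens", {
  std <- de_thresholds(preset = "standard")
  expect_equal(c(std$min_aveexpr, std$min_abs_logfc, std$max_adjp),
               c(7, 0.7, 0.05))
  strict <- de_thresholds(preset = "stringent")
  expect_equal(c(strict$min_aveexpr, strict$min_abs_logfc, strict$max_adjp),
               c(7, 1.5, 0.01))
  expect_error(de_thresholds(max_adjp = 0), "max_adjp")
})

test_that("planted down-shifts are recovered by the standard screen", {
  # shift -1.5, noise 0.3, n=3/group: aggregate recovery across seeds >= 95%
  planted <- sprintf("g%03d", 1:50)
  hits <- 0L
  total <- 0L
  for (s in 1:20) {
    g <- gen_expression(500, stats::setNames(rep(-1.5, 50), planted),
                        n_per_group = 3, noise_sd = 0.3, seed = 1000 + s)
    de <- differential(g$matrix, g$samples, c("treatment", "control"))
    cs <- categorize(de, de_thresholds(preset = "standard"))
    hits <- hits + sum(planted %in% cs$down)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.95)
})

test_that("relative_expression_ddct implements 2^-deltaCT", {
  expect_equal(relative_expression_ddct(25, 22), 0.125)
  expect_equal(relative_expression_ddct(20, 20), 1.0)
  expect_equal(relative_expression_ddct(19, 20), 2.0)
  expect_equal(relative_expression_ddct(c(25, 20), c(22, 20)), c(0.125, 1))
  expect_error(relative_expression_ddct(NA, 20), "finite")
})
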