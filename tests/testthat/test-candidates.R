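test_that("candidate_filter keeps consensus targets in the down category", {
  de <- make_de(c("ARHGAP12", "CAV1", "PXN", "weak", "upg", "dimg"),
                aveexpr = c(11.12, 15.28, 14.99, 10, 9, 6.5),
                logfc = c(-1.96, -1.78, -1.41, -1.4, 2.0, -3),
                adjp = rep(0.001, 6))
  res <- list(consensus = c("ARHGAP12", "CAV1", "PXN", "weak", "upg", "dimg"),
              support = stats::setNames(c(3L, 3L, 3L, 3L, 3L, 3L),
                                        c("ARHGAP12", "CAV1", "PXN", "weak",
                                          "upg", "dimg")))
  cand <- candidate_filter(de, res,
                           de_thresholds(preset = "stringent"),
                           min_sources = 3)
  # stringent screen: |logFC| > 1.5, adjP < 0.01, AveExpr >= 7
  expect_setequal(cand$symbol, c("ARHGAP12", "CAV1"))
  # sorted by logFC ascending: -1.96 ranks above -1.78
  expect_identical(cand$symbol, c("ARHGAP12", "CAV1"))
  expect_equal(cand$AveExpr, c(11.12, 15.28))
  expect_equal(cand$logFC, c(-1.96, -1.78))
  expect_identical(cand$n_sources, c(3L, 3L))
  # candidates are always a subset of the down category
  expect_true(all(cand$symbol %in% categorize(
    de, de_thresholds(preset = "stringent"))$down))
})

test_that("candidate_filter honours min_sources and annotations", {
  de <- make_de(c("A", "B"), aveexpr = 10, logfc = c(-2, -2),
                adjp = 0.001)
  res <- list(consensus = c("A", "B"),
              support = c(A = 3L, B = 2L))
  cand <- candidate_filter(de, res, de_thresholds(preset = "stringent"),
                           min_sources = 3,
                           annotations = data.frame(
                             symbol = "A", accession = "NM_000001",
                             description = "gene A"))
  expect_identical(cand$symbol, "A")
  expect_identical(cand$accession, "NM_000001")
  expect_warning(
    empty <- candidate_filter(de, character(0),
                              de_thresholds(preset = "stringent")),
    "empty consensus")
  expect_identical(nrow(empty), 0L)
})

test_that("cross_species_support flags exactly the planted orthologs", {
  # 21 candidates; plant in-vivo down-regulation for 4 of their orthologs
  syms <- sprintf("GENE%02d", 1:21)
  cand <- candidate_filter(
    make_de(syms, aveexpr = 10, logfc = seq(-3, -1.6, length.out = 21),
            adjp = 0.001),
    syms, de_thresholds(preset = "stringent"))
  mouse <- sprintf("Gene%02d", 1:21)
  map <- ortholog_map(syms, mouse)
  supported <- c("GENE03", "GENE07", "GENE11", "GENE19")
  invivo <- make_de(mouse, aveexpr = 10,
                    logfc = ifelse(syms %in% supported, -1.2, -0.9),
                    adjp = ifelse(syms %in% supported, 0.01, 0.4))
  out <- cross_species_support(cand, invivo, map, alpha = 0.05)
  expect_setequal(out$symbol[out$in_vivo_support], supported)
  expect_identical(sum(out$in_vivo_support), 4L)
})

test_that("cross_species_support resolves via the map, not case folding", {
  cand <- candidate_filter(
    make_de(c("CAV1", "NOMAP"), aveexpr = 10, logfc = c(-2, -2),
            adjp = 0.001),
    c("CAV1", "NOMAP"), de_thresholds(preset = "stringent"))
  map <- ortholog_map("CAV1", "Cav1")
  invivo <- make_de(c("Cav1", "nomap"), aveexpr = 10, logfc = c(-2, -2),
                    adjp = 0.001)
  expect_warning(out <- cross_species_support(cand, invivo, map, 0.05),
                 "NOMAP")
  expect_true(out$in_vivo_support[out$symbol == "CAV1"])
  # "nomap" is significantly down in vivo, but without a map entry the
  # candidate NOMAP must not match it by case folding
  expect_false(out$in_vivo_support[out$symbol == "NOMAP"])
})

test_that("model_overlap recovers planted common miRNAs with signs", {
  mir <- paste0("miR-", sprintf("%02d", 1:40))
  g <- gen_model_tables(mir, common_up = c("miR-01", "miR-02"),
                        common_down = c("miR-03", "miR-04", "miR-05"),
                        per_model_extras = 3, seed = 101)
  ov <- model_overlap(g$tables, alpha = 0.01)
  expect_identical(ov$common$mirna_id, sort(c("miR-01", "miR-02", "miR-03",
                                              "miR-04", "miR-05")))
  expect_identical(ov$common$direction[ov$common$mirna_id %in%
                                         c("miR-01", "miR-02")], c(1, 1))
  expect_identical(ov$common$direction[ov$common$mirna_id %in%
                                         c("miR-03", "miR-04", "miR-05")],
                   c(-1, -1, -1))
})

test_that("model_overlap is strict at alpha and order-invariant", {
  mir <- paste0("m", 1:20)
  g <- gen_model_tables(mir, common_up = "m1", per_model_extras = 0,
                        seed = 102)
  stats1 <- mirseed:::model_table_stats(g$tables$lung)
  p_m1 <- stats1$p[stats1$mirna_id == "m1"]
  # alpha equal to the attained p: the strict "<" screen must exclude m1
  ov_strict <- model_overlap(g$tables, alpha = p_m1)
  expect_false("m1" %in% ov_strict$per_model$lung$mirna_id)
  # while any alpha just above it admits m1 in that model
  ov_loose <- model_overlap(g$tables, alpha = min(1 - 1e-9, p_m1 * 1.0001))
  expect_true("m1" %in% ov_loose$per_model$lung$mirna_id)
  # permutation invariance of the common list
  ov_a <- model_overlap(g$tables, alpha = 0.01)
  ov_b <- model_overlap(rev(g$tables), alpha = 0.01)
  expect_identical(ov_a$common, ov_b$common)
})

test_that("discordant miRNAs are surfaced, not silently dropped", {
  # build tables by hand: m1 significant everywhere, up in one model only
  mk <- function(model, up_sign) {
    vals <- rbind(m1 = c(10, 10.1, 9.9, 10, 8, 8.1, 7.9, 8),
                  m2 = c(8, 8.2, 7.9, 8.1, 8, 8.1, 7.9, 8.05))
    if (up_sign < 0) vals["m1", 1:4] <- c(6, 6.1, 5.9, 6)
    mirna_model_table(model, vals, rep(c("treated", "control"), each = 4))
  }
  tabs <- list(mk("a", 1), mk("b", -1), mk("c", 1))
  ov <- model_overlap(tabs, alpha = 0.01)
  expect_identical(ov$discordant, "m1")
  expect_false("m1" %in% ov$common$mirna_id)
  expect_identical(unname(ov$venn[["a&b&c"]]), 1L)
})

test_that("model_overlap validates replicate counts", {
  vals <- rbind(m1 = c(1, 2, 3))
  expect_error(mirna_model_table("x", vals, c("t", "t", "c")),
               "2 replicates")
})
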