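summary_row <- function(mean, scale = "raw_percent") {
  data.frame(subject = "x", mean = mean, se = NA_real_, n = 3L, scale = scale)
}

test_that("additive and combination effects are mean differences on one scale", {
  expect_equal(additive_single(summary_row(56.5), summary_row(29.2)), 27.3)
  expect_equal(additive_single(summary_row(29.2), summary_row(29.2)), 0)
  expect_equal(combination_effect(summary_row(77.1), summary_row(29.2)), 47.9)
  expect_error(additive_single(summary_row(50), summary_row(29.2, "arcsine_sqrt")),
               "scale mismatch")
  # mean over the packaged single-QTL effects reproduces the published grand mean
  eff <- ser_study_effects()
  expect_equal(round_half_up(mean(eff)), 18.9)
  ssl <- ser_study_ssl_summaries()
  hand <- vapply(seq_len(nrow(ssl)), function(r)
    additive_single(ssl[r, ], summary_row(29.2)), 0)
  expect_equal(round_half_up(mean(hand)), 18.9)
})

test_that("epistasis point formula and trivial cases", {
  expect_equal(epistasis_point(30, 50, c(10, 15)), -5)
  expect_equal(epistasis_point(30, 55, c(10, 15)), 0)
  expect_error(epistasis_point(30, 50, 10), "fewer than 2")
})

test_that("per-QTL epistasis and epistasis fraction match published arithmetic", {
  expect_equal(round_half_up(per_qtl_epistasis(-40.4, 5)), -8.1)
  expect_equal(round_half_up(per_qtl_epistasis(-47.7, 6)), -8.0)
  expect_equal(per_qtl_epistasis(0, 4), 0)
  expect_error(per_qtl_epistasis(-5, 1), "n >= 2")
  expect_equal(round_half_up(epistasis_fraction(8.1, 18.9)), 42.9)
  expect_equal(round_half_up(epistasis_fraction(-25.2 / 4, 18.9)), 33.3)
  expect_equal(epistasis_fraction(0, 18.9), 0)
  expect_error(epistasis_fraction(1, 0), "positive")
})

test_that("noise-free epistasis estimation recovers the architecture exactly", {
  panel <- toy_panel()
  cfg <- toy_config(epistasis = list(
    model = "pairwise",
    pairs = c("qA-sat:qB-gla" = -8, "qA-sat:qC-glu" = -2, "qB-gla:qC-glu" = 0)))
  rec <- generate_phenotypes(panel, cfg)
  est <- estimate_epistasis(panel, rec, control = "CTL")
  expect_equal(est$i[est$line_id == "2QL-1"], -8, tolerance = 1e-10)
  expect_equal(est$i[est$line_id == "3QL-1"], -10, tolerance = 1e-10)
  expect_equal(est$combination_effect[est$line_id == "2QL-1"],
               15 + 18 - 8, tolerance = 1e-10)
  # purely additive: i exactly 0; the exact null t = 0 holds on the raw
  # scale (the arcsine transform of raw-additive data is not additive, so
  # the default transformed-scale test sees a tiny deterministic deviation)
  rec0 <- generate_phenotypes(panel, toy_config())
  est0 <- estimate_epistasis(panel, rec0, control = "CTL",
                             test_scale = "raw_percent")
  expect_equal(est0$i, rep(0, 2), tolerance = 1e-12)
  expect_equal(est0$t, rep(0, 2))
  expect_equal(est0$p, rep(1, 2))
})

test_that("the two epistasis routes agree (linearity identity)", {
  panel <- toy_panel()
  cfg <- toy_config(noise_sd = 3, seed = 99L,
                    epistasis = list(model = "diminishing", c = 3.5))
  rec <- suppressMessages(generate_phenotypes(panel, cfg))
  ls_ <- summarize_trait(rec, panel, by = "line")
  m <- stats::setNames(ls_$mean, ls_$subject)
  a_hat <- m[paste0("SSSL-", c("qA-sat", "qB-gla", "qC-glu"))] - m["CTL"]
  names(a_hat) <- c("qA-sat", "qB-gla", "qC-glu")
  est <- estimate_epistasis(panel, rec, control = "CTL")
  for (id in est$line_id) {
    loci <- colnames(panel$presence)[panel$presence[id, ]]
    route1 <- (m[[id]] - m[["CTL"]]) - sum(a_hat[loci])
    route2 <- m[[id]] + (length(loci) - 1) * m[["CTL"]] -
      sum(m[paste0("SSSL-", loci)])
    expect_equal(route1, route2, tolerance = 1e-10)
    expect_equal(est$i[est$line_id == id], unname(route1), tolerance = 1e-10)
  }
})

test_that("missing single effects and linked-segment cover are handled", {
  panel <- toy_panel()
  rec <- generate_phenotypes(panel, toy_config())
  rec <- rec[rec$line_id != "SSSL-qB-gla", ]
  expect_error(estimate_epistasis(panel, rec, control = "CTL"),
               "qB-gla")
  # a joint two-locus entry covers the pair and counts as n = 2
  loci <- c("qA-sat", "qB-gla")
  panel2 <- make_panel(list(CTL = character(0), AB = loci,
                            `2QL-1` = loci), loci)
  cfg <- architecture_config(P0 = 30, additive = c("qA-sat" = 15, "qB-gla" = 18),
                             epistasis = list(model = "none"), noise_sd = 0,
                             seasons = 3L, seed = 5L)
  rec2 <- generate_phenotypes(panel2, cfg)
  rec2 <- rec2[rec2$line_id != "AB", ]
  est <- estimate_epistasis(
    panel2, rbind(rec2, within(rec2[rec2$line_id == "2QL-1", ],
                               line_id <- "AB")),
    control = "CTL", ssl_map = c("qA-sat+qB-gla" = "AB"))
  expect_equal(est$n[est$line_id == "2QL-1"], 2L)
  expect_equal(est$i[est$line_id == "2QL-1"], 0, tolerance = 1e-10)
})

test_that("effect-level classification is the exact least-squares partition", {
  cls <- classify_effect_levels(c(a = 13, b = 14, c = 20, d = 21,
                                  e = 26, f = 27), k = 3)
  expect_equal(cls$assignment$level, rep(c("low", "moderate", "high"), each = 2))
  expect_equal(unname(cls$level_means), c(13.5, 20.5, 26.5))
  # forced top level of the published pair
  eff <- ser_study_effects()
  cls11 <- classify_effect_levels(eff, k = 3)
  expect_equal(as.integer(table(cls11$assignment$level)[c("low", "moderate", "high")]),
               c(7L, 2L, 2L))
  expect_equal(round_half_up(cls11$level_means[["high"]]), 26.4)
  # agreement with brute-force enumeration on random instances
  set.seed(7)
  for (r in 1:25) {
    n <- sample(4:12, 1); k <- sample(2:3, 1)
    x <- round(runif(n, 10, 30), 2)
    if (length(unique(x)) < k) next
    cls_r <- classify_effect_levels(stats::setNames(x, paste0("L", 1:n)), k)
    oracle <- best_contiguous_partition(x, k)
    expect_equal(cls_r$within_ss, oracle$ss, tolerance = 1e-9)
  }
  expect_error(classify_effect_levels(c(1, 2), k = 3), "cannot form")
  expect_error(classify_effect_levels(c(a = 5, b = 5, c = 5), k = 3),
               "smaller k")
})

test_that("donor aggregation summarises per-species effects", {
  md <- ser_study_metadata()
  eff <- ser_study_effects()
  agg <- aggregate_by_donor(eff, md)
  glu <- agg[agg$donor_species == "glumaepatula", ]
  expect_equal(glu$n, 3L)
  expect_equal(round_half_up(glu$mean), 24.3)
  expect_equal(round_half_up(aggregate_by_donor(
    c(`qSER1b-glu` = 20.2, `qSER3b-glu` = 25.5, `qSER5-glu` = 27.3),
    md)$mean), 24.3)
  one <- aggregate_by_donor(c(`qSER5-glu` = 27.3), md)
  expect_equal(one$mean, 27.3)
  sat <- agg[agg$donor_species == "sativa", ]
  expect_gte(sat$mean, 14.8)
  expect_lte(sat$mean, 17.5)
  expect_error(aggregate_by_donor(c(qX = 5), md), "missing donor metadata")
})

test_that("group-level epistasis from summaries matches per-line averaging", {
  panel <- toy_panel()
  cfg <- toy_config(epistasis = list(model = "diminishing", c = 4))
  rec <- generate_phenotypes(panel, cfg)
  est <- estimate_epistasis(panel, rec, control = "CTL")
  gs <- summarize_trait(rec, panel, by = "group")
  gs <- rbind(gs, data.frame(subject = "CTL", mean = 30, se = 0, n = 3L,
                             scale = "raw_percent"))
  ge <- group_epistasis_from_summaries(panel, gs, cfg$additive,
                                       control_subject = "CTL")
  for (g in c("2QL", "3QL")) {
    ids <- lines_by_group(panel)[[g]]
    expect_equal(ge$i[ge$group == g],
                 mean(est$i[est$line_id %in% ids]), tolerance = 1e-10)
  }
})
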