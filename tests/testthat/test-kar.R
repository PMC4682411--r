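binding_fixture <- function() {
  binding_profile(data.frame(
    compound = c("D1", "D1", "D2", "D2", "D3"),
    kinase = c("EGFR", "LYN", "EGFR", "LYN", "AKT1"),
    value = c(0.5, 1.0, 84, 85.1, 2),
    measure = c("Kd_uM", "Kd_uM", "percent_inhibition",
                "percent_inhibition", "Kd_uM")))
}

test_that("dichotomization uses strict thresholds on both readouts", {
  inh <- dichotomize(binding_fixture(), kd_thresh = 1, inh_thresh = 85)
  expect_true(inh["D1", "EGFR"])     # Kd 0.5 < 1
  expect_false(inh["D1", "LYN"])     # Kd 1.0, strict <
  expect_false(inh["D2", "EGFR"])    # 84% <= 85
  expect_true(inh["D2", "LYN"])      # 85.1% > 85
  expect_false(inh["D3", "AKT1"])    # Kd 2
})

test_that("usable compounds need a binding profile and >=1 inhibited kinase", {
  ec50 <- matrix(1, 1, 4, dimnames = list("CL1", c("D1", "D2", "D3", "D4")))
  screen <- drug_screen(ec50)
  inh <- dichotomize(binding_fixture())
  usable <- select_usable_drugs(screen, inh)
  # D3 inhibits nothing above threshold; D4 has no binding profile
  expect_setequal(usable, c("D1", "D2"))

  # identity when every compound qualifies
  screen2 <- drug_screen(ec50[, c("D1", "D2"), drop = FALSE])
  expect_setequal(select_usable_drugs(screen2, inh), c("D1", "D2"))

  # nothing usable is a hard error
  screen3 <- drug_screen(matrix(1, 1, 2, dimnames = list("CL1", c("D3", "D4"))))
  expect_error(select_usable_drugs(screen3, inh), "no usable compounds")
})

test_that("bin assignment partitions compounds over (lo, hi] intervals", {
  sch <- bin_scheme()  # boundaries 0.1, 1, 5, 10
  ec50 <- c(a = 0.05, b = 0.1, c = 0.5, d = 1, e = 4, f = 10, g = 30, h = NA)
  inactive <- c(rep(FALSE, 7), TRUE)
  bins <- assign_bins(ec50, sch, inactive)
  expect_equal(unname(bins), c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L))
  # missing stays unassigned
  bins2 <- assign_bins(c(x = NA, y = 2), sch)
  expect_true(is.na(bins2[["x"]]))
  expect_equal(bins2[["y"]], 3L)
  # partition: every assigned compound lands in exactly one bin 1..5
  set.seed(3)
  v <- 10^runif(200, -3, 2)
  b <- assign_bins(stats::setNames(v, paste0("d", 1:200)), sch)
  expect_true(all(b %in% 1:5))
  expect_equal(sum(table(b)), 200L)
})

test_that("quantile bin boundaries track the cell line's potency range", {
  ec50 <- c(10^seq(-2, 2, length.out = 21), NA)
  q <- quantile_boundaries(ec50)
  expect_equal(q, unname(quantile(ec50, c(.2, .4, .6, .8), na.rm = TRUE)))
  expect_error(quantile_boundaries(rep(1, 10)), "strictly ascending")
})

test_that("bin scheme validation rejects malformed schemes", {
  expect_error(bin_scheme(c(1, 0.1, 5, 10)), "ascending")
  expect_error(bin_scheme(points = c(`1` = 0, `2` = 10, `3` = 5, `4` = 0, `5` = -10)),
               "non-increasing")
  expect_error(bin_scheme(points = c(`1` = 20, `2` = 10)), "five bins|all five|\"1\"")
})

test_that("expression filter drops low kinases but keeps unmeasured ones", {
  expr <- expression_table(matrix(c(8.2, 3.0, 5.0, 7, 7, 7), 3, 2,
                                  dimnames = list(c("EGFR", "LYN", "CDK5"),
                                                  c("CL1", "CL2"))))
  flt <- filter_expressed(c("EGFR", "LYN", "CDK5/P25", "MAP4K4"), expr, "CL1",
                          cutoff = 5, type = "absolute")
  expect_equal(flt$status, c("expressed", "low", "expressed", "unmeasured"))
  expect_equal(flt$kinase[flt$keep], c("EGFR", "CDK5/P25", "MAP4K4"))
  # complex labels filter on their first gene component
  expect_equal(flt$expression[flt$kinase == "CDK5/P25"], 5.0)
  expect_error(filter_expressed("EGFR", expr, "CL9"), "not found")
})

test_that("kinase scores sum bin points over inhibiting compounds", {
  inh <- matrix(c(TRUE, TRUE, TRUE, FALSE,
                  FALSE, FALSE, TRUE, TRUE), 4, 2,
                dimnames = list(c("D1", "D2", "D3", "D4"), c("K1", "K2")))
  sch <- bin_scheme()
  bins <- c(D1 = 1L, D2 = 1L, D3 = 5L, D4 = 4L)
  sc <- score_kinases(bins, inh, scheme = sch)
  expect_equal(sc[["K1"]], 20L + 20L - 10L)  # two bin-1 hits, one bin-5
  expect_equal(sc[["K2"]], -10L + 0L)
  # kinase hit only by bin-4 compounds scores 0 but keeps its record
  sc2 <- score_kinases(c(D4 = 4L), inh, scheme = sch)
  expect_equal(sc2, c(K2 = 0L))
  # kinase inhibited by no assigned compound gets no record
  expect_false("K2" %in% names(score_kinases(c(D1 = 1L, D2 = 2L), inh, scheme = sch)))
})

test_that("scores match brute-force re-summation over random incidence lists", {
  set.seed(42)
  sch <- bin_scheme()
  for (rep in 1:20) {
    nd <- sample(3:12, 1); nk <- sample(2:8, 1)
    inh <- matrix(runif(nd * nk) < 0.4, nd, nk,
                  dimnames = list(paste0("D", 1:nd), paste0("K", 1:nk)))
    bins <- stats::setNames(sample(c(1:5, NA), nd, replace = TRUE),
                            rownames(inh))
    sc <- score_kinases(bins, inh, scheme = sch)
    oracle <- score_oracle(bins, inh, sch)
    expect_equal(sc[sort(names(sc))],
                 stats::setNames(as.integer(oracle[sort(names(sc))]),
                                 sort(names(sc))))
    expect_setequal(names(sc), names(oracle))
  }
})

test_that("association tests behave at the analytic reference points", {
  r <- association_test(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(r$fisher_p, 1 / choose(10, 5), tolerance = 1e-12)  # = 1/252
  r2 <- association_test(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(r2$chi2_p, 1)
  # zero margin: chi-square undefined -> 1, Fisher still computed
  r3 <- association_test(matrix(c(0, 0, 3, 2), 2, byrow = TRUE))
  expect_equal(r3$chi2_p, 1)
  expect_equal(r3$fisher_p, 1)
  # reported p switches to chi-square only when expected counts allow
  big <- association_test(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(big$reported_p, big$chi2_p)
  small <- association_test(matrix(c(3, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(small$reported_p, small$fisher_p)
  expect_error(association_test(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("ranking orders by p, breaks ties by score, flags significance", {
  rec <- data.frame(kinase = c("B", "A", "C"),
                    raw_score = c(90, 160, 150),
                    n_inh_sens = 1L, n_inh_insens = 0L, n_noninh_sens = 1L,
                    n_noninh_insens = 1L, chi2_p = 0.5,
                    fisher_p = c(0.04, 0.01, 0.01),
                    reported_p = c(0.04, 0.01, 0.01),
                    direction = "positive", expressed = "expressed",
                    stringsAsFactors = FALSE)
  rk <- rank_kinases(rec, alpha = 0.05, cell_line = "CL1")
  # equal p broken by larger score first (160 before 150), then the 0.04
  expect_equal(rk$kinase, c("A", "C", "B"))
  expect_true(all(rk$significant))
  expect_equal(attr(rk, "n_significant"), 3L)
  expect_equal(rk$rank, 1:3)
  # ranking is a permutation of the scored kinases
  expect_setequal(rk$kinase, rec$kinase)
  # net-negative kinases are never called significant
  rec$raw_score <- c(90, -10, 150)
  rk2 <- rank_kinases(rec, alpha = 0.05)
  expect_false(rk2$significant[rk2$kinase == "A"])
})

test_that("label tie-break makes equal (p, score) ranks deterministic", {
  rec <- data.frame(kinase = c("ZAP70", "ABL1"), raw_score = c(50, 50),
                    n_inh_sens = 1L, n_inh_insens = 0L, n_noninh_sens = 1L,
                    n_noninh_insens = 1L, chi2_p = 0.2, fisher_p = 0.2,
                    reported_p = 0.2, direction = "positive",
                    expressed = "expressed", stringsAsFactors = FALSE)
  expect_equal(rank_kinases(rec)$kinase, c("ABL1", "ZAP70"))
})

test_that("moving an inhibiting drug to a better bin never lowers the score", {
  set.seed(7)
  sch <- bin_scheme()
  for (rep in 1:25) {
    nd <- sample(4:10, 1)
    inh <- matrix(runif(nd * 3) < 0.5, nd, 3,
                  dimnames = list(paste0("D", 1:nd), c("K1", "K2", "K3")))
    inh[1, "K1"] <- TRUE
    bins <- stats::setNames(sample(1:5, nd, replace = TRUE), rownames(inh))
    bins["D1"] <- 2L
    before <- score_kinases(bins, inh, scheme = sch)[["K1"]]
    bins["D1"] <- 1L
    after <- score_kinases(bins, inh, scheme = sch)[["K1"]]
    expect_gte(after, before)
  }
})

test_that("the pipeline is invariant to input row/column order", {
  d <- toy_dir()
  screen <- read_drug_screen(file.path(d, "screen.tsv"))
  binding <- read_binding(file.path(d, "binding.tsv"))
  expr <- read_expression(file.path(d, "expression.tsv"))
  cfg <- read_kar_config(file.path(d, "config.yaml"))
  res <- run_kar(screen, binding, expr, cfg)

  # permute compounds and cell lines in the screen, rows in binding/expr
  perm_screen <- drug_screen(screen$ec50[rev(cell_lines(screen)), rev(compounds(screen))],
                             screen$inactive[rev(cell_lines(screen)), rev(compounds(screen))])
  perm_bind <- binding[rev(seq_len(nrow(binding))), ]
  class(perm_bind) <- class(binding)
  perm_expr <- expr[rev(rownames(expr)), ]
  res2 <- run_kar(perm_screen, perm_bind, perm_expr, cfg)
  for (cl in names(res)) {
    a <- res[[cl]]; b <- res2[[cl]]
    attributes(a) <- attributes(a)[c("names", "class", "row.names")]
    attributes(b) <- attributes(b)[c("names", "class", "row.names")]
    expect_equal(a, b)
  }
})

test_that("removing a bin-4 drug changes contingencies but not raw scores", {
  d <- toy_dir()
  screen <- read_drug_screen(file.path(d, "screen.tsv"))
  binding <- read_binding(file.path(d, "binding.tsv"))
  expr <- read_expression(file.path(d, "expression.tsv"))
  cfg <- read_kar_config(file.path(d, "config.yaml"))
  # restrict to CL1, where D3 (EC50 8 uM) sits in bin 4
  cl1 <- drug_screen(screen$ec50["CL1", , drop = FALSE],
                     screen$inactive["CL1", , drop = FALSE])
  full <- run_kar(cl1, binding, expr, cfg)[["CL1"]]
  no_d3 <- drug_screen(cl1$ec50[, setdiff(compounds(cl1), "D3"), drop = FALSE],
                       cl1$inactive[, setdiff(compounds(cl1), "D3"), drop = FALSE])
  reduced <- run_kar(no_d3, binding, expr, cfg)[["CL1"]]
  shared <- intersect(full$kinase, reduced$kinase)
  expect_equal(stats::setNames(reduced$raw_score, reduced$kinase)[shared],
               stats::setNames(full$raw_score, full$kinase)[shared])
  # contingency totals drop by one usable compound
  expect_equal(unique(with(reduced, n_inh_sens + n_inh_insens +
                             n_noninh_sens + n_noninh_insens)),
               unique(with(full, n_inh_sens + n_inh_insens +
                             n_noninh_sens + n_noninh_insens)) - 1L)
})

test_that("contingency cells always sum to the number of binned compounds", {
  sim <- simulate_kinase_screen(small_sim_config(seed = 99))
  res <- run_kar(sim$screen, sim$binding, sim$expression)
  cfg <- kar_config()
  inh <- dichotomize(sim$binding, cfg$kd_thresh, cfg$inh_thresh)
  usable <- select_usable_drugs(sim$screen, inh)
  for (cl in names(res)) {
    r <- res[[cl]]
    bins <- assign_bins(sim$screen$ec50[cl, usable], cfg$scheme,
                        sim$screen$inactive[cl, usable])
    expect_true(all(r$n_inh_sens + r$n_inh_insens + r$n_noninh_sens +
                      r$n_noninh_insens == sum(!is.na(bins))))
    # raw scores are integer combinations of the configured point values
    expect_true(all(r$raw_score %% 5 == 0))
  }
})
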