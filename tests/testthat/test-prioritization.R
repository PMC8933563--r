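test_that("signatures encode the licensing conjunction", {
  universe <- c("g1", "g2", "g3", "g4")
  sig <- build_signatures(universe,
                          changed = c("g1", "g2", "g3"),
                          upregulated = c("g1", "g2"),
                          hmc_dp = "g1", hmc_cd4sp = c("g1", "g2"),
                          dev_cre = c("g1", "g2"),
                          novel_th0 = "g1")
  expect_equal(sig$licensed, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sig$hmc_any, sig$hmc_dp | sig$hmc_cd4sp)
  expect_true(all(sig$changed[sig$upregulated]))
  expect_error(build_signatures(universe, changed = "gX",
                                upregulated = character(0),
                                hmc_dp = character(0), hmc_cd4sp = character(0),
                                dev_cre = character(0), novel_th0 = character(0)),
               "outside the universe")
})

test_that("licensed set equals the brute-force 4-way intersection on random inputs", {
  set.seed(31)
  universe <- sprintf("g%03d", 1:60)
  for (i in 1:10) {
    pick <- function() sample(universe, sample.int(40, 1))
    up <- pick(); dp <- pick(); sp <- pick(); cre <- pick(); nov <- pick()
    sig <- build_signatures(universe, changed = union(up, pick()),
                            upregulated = up, hmc_dp = dp, hmc_cd4sp = sp,
                            dev_cre = cre, novel_th0 = nov)
    want <- Reduce(intersect, list(up, union(dp, sp), cre, nov))
    expect_setequal(sig$gene_id[sig$licensed], want)
  }
})

test_that("nested percentages reproduce the printed cascade arithmetic", {
  expect_equal(percentage(333, 409), 81.4)
  expect_equal(percentage(330, 350), 94.3)   # printed as 94% at integer rounding
  expect_equal(round(percentage(330, 350)), 94)
  expect_equal(percentage(0, 10), 0)
  expect_true(is.na(percentage(0, 0)))
})

test_that("venn summary counts are nested monotone", {
  set.seed(8)
  universe <- sprintf("g%03d", 1:80)
  for (i in 1:10) {
    pick <- function(n) sample(universe, n)
    up <- pick(30)
    sig <- build_signatures(universe, changed = union(up, pick(20)),
                            upregulated = up, hmc_dp = pick(25),
                            hmc_cd4sp = pick(25), dev_cre = pick(40),
                            novel_th0 = pick(35))
    v <- venn_summary(sig)
    expect_lte(v$n_hmc_among_changed, v$n_changed)
    expect_lte(v$n_with_dev_cre, v$n_upregulated_hmc)
    expect_lte(v$n_with_novel_th0, v$n_upregulated_hmc)
    expect_lte(v$n_licensed, v$n_with_dev_cre)
    expect_lte(v$n_licensed, v$n_with_novel_th0)
  }
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  # worked example: N=10, K=5, n=4, k=4 -> 5/210
  expect_equal(hypergeom_p(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_p(0, 5, 4, 10), 1)
  expect_equal(hypergeom_p(3, 10, 3, 10), 1)    # K = N
  expect_error(hypergeom_p(5, 4, 5, 10), "inconsistent")
  for (N in 2:8) for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
    expect_equal(hypergeom_p(k, K, n, N), brute_force_hyper(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand computation: sorted p (.01,.04,.9): q3=.9, q2=min(.9,.04*3/2)=.06, q1=min(.06,.03)=.03
  expect_equal(bh_adjust(c(0.9, 0.01, 0.04)), c(0.9, 0.03, 0.06))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- sort(runif(20))
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q) >= 0))
})

test_that("enrichment is deterministic, drops empty overlaps, and ranks exact terms first", {
  universe <- sprintf("g%02d", 1:20)
  query <- universe[1:5]
  terms <- list(exact = query,
                half = universe[c(1:2, 10:12)],
                disjoint = universe[15:20],
                outside = c("zz1", universe[3]))
  res <- enrich(query, terms, universe)
  expect_false("disjoint" %in% res$term_id)
  expect_equal(res$term_id[1], "exact")
  expect_equal(res$k[res$term_id == "exact"], 5L)
  expect_equal(res$K[res$term_id == "outside"], 1L)  # clipped to universe
  expect_true(all(res$q >= res$p))
  # iteration-order invariance
  res2 <- enrich(query, terms[c(3, 1, 4, 2)], universe)
  expect_equal(res, res2)
  expect_error(enrich(query, terms, character(0)), "empty universe")
  expect_error(enrich("nope", terms, universe), "outside universe")
})

test_that("recovery report computes sensitivity and per-class leakage", {
  truth <- data.frame(gene_id = c("a", "b", "c", "d"),
                      class = c("licensed", "licensed", "no_hmc", "null"))
  sig <- data.frame(gene_id = c("a", "b", "c", "d"),
                    licensed = c(TRUE, FALSE, TRUE, FALSE))
  rep <- recovery_report(truth, sig)
  expect_equal(rep$sensitivity, 0.5)
  expect_equal(unname(rep$leakage["no_hmc"]), 1)
  expect_equal(unname(rep$leakage["null"]), 0)
  truth0 <- truth
  truth0$class[1:2] <- "null"
  expect_true(is.na(recovery_report(truth0, sig)$sensitivity))
  expect_error(recovery_report(truth[1:3, ], sig), "universes")
})
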