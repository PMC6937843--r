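mk_group <- function(rows, gene = "G1", cc = "DNA") {
  swlh_group(gene, cc, rows)
}

test_that("agglutination partitions rows by gene, coding and site count", {
  e <- function(name, n, gene = "COX1", cc = "DNA") {
    list(id = strategy_id(gene, ae = name, cc = cc, ed = "UB"),
         loglik = rep(-2, n))
  }
  groups <- group_swlh(list(e("MAFFT", 100L), e("MUSCLE", 100L)))
  expect_length(groups, 1L)
  expect_equal(groups[[1L]]$strategies,
               sort(c("COX1_MAFFT_DNA_UB", "COX1_MUSCLE_DNA_UB")))
  # a deviant site count goes to its own group with a warning
  expect_warning(
    groups <- group_swlh(list(e("MAFFT", 100L), e("MUSCLE", 100L),
                              e("KALIGN", 98L))),
    "site-count mismatch")
  expect_length(groups, 2L)
  expect_equal(attr(groups, "skipped"), "COX1_KALIGN_DNA_UB")
  # different codings never share a group, whatever the lengths
  groups <- group_swlh(list(e("MAFFT", 100L), e("MAFFT", 100L, cc = "RY")))
  expect_length(groups, 2L)
  expect_error(group_swlh(list(e("MAFFT", 10L), e("MAFFT", 10L))),
               "duplicate strategy")
})

test_that("sitelh objects feed agglutination one strategy per tree row", {
  s <- sitelh("Site_Lh", matrix(c(-1, -2, -3), 1L))
  g <- group_swlh(list(list(id = strategy_id("G", ae = "MAFFT", cc = "DNA"),
                            sitelh = s)))
  expect_equal(g[[1L]]$n_sites, 3L)
  s2 <- sitelh(c("a", "b"), matrix(-1, 2L, 3L))
  expect_error(
    group_swlh(list(list(id = strategy_id("G", ae = "MAFFT", cc = "DNA"),
                         sitelh = s2))),
    "one strategy id per tree row")
})

test_that("RELL bootstrap proportions honour dominance and tie-splitting", {
  single <- mk_group(matrix(-1, 1L, 5L, dimnames = list("A", NULL)))
  expect_equal(unname(rell_bp(single, n_rep = 100L, seed = 1L)), 1)
  dom <- mk_group(rbind(A = rep(-1, 20L), B = rep(-1.5, 20L)))
  expect_equal(unname(rell_bp(dom, n_rep = 500L, seed = 1L)), c(1, 0))
  tie <- mk_group(rbind(A = c(-1, -2, -3), B = c(-1, -2, -3)))
  expect_equal(unname(rell_bp(tie, n_rep = 999L, seed = 7L)), c(0.5, 0.5))
  # proportions always sum to one exactly
  set.seed(10)
  noisy <- mk_group(matrix(rnorm(4L * 50L, -2), 4L, 50L,
                           dimnames = list(paste0("s", 1:4), NULL)))
  expect_equal(sum(rell_bp(noisy, n_rep = 1000L, seed = 3L)), 1)
})

test_that("AU p-values follow the multiscale fit and its degenerate rules", {
  # flat bp of one half at every scale implies z == 0, hence au = 1/2
  flat <- phylopcc:::.au_fit(rep(0.5, 10L), seq(0.5, 1.4, by = 0.1), 10000L)
  expect_equal(flat$au, 0.5)
  expect_equal(flat$d, 0, tolerance = 1e-12)
  expect_equal(flat$c, 0, tolerance = 1e-12)
  # a strategy that wins every replicate at every scale gets au = 1
  dom <- mk_group(rbind(A = rep(-1, 30L), B = rep(-2, 30L)))
  res <- au_pvalue(dom, "A", n_rep = 200L, seed = 1L)
  expect_equal(res$au, 1)
  expect_equal(au_pvalue(dom, 2L, n_rep = 200L, seed = 1L)$au, 0)
  # symmetric identical rows: au near 1/2 for both
  tie <- mk_group(rbind(A = rnorm(500L, -2), B = 0))
  tie$loglik["B", ] <- tie$loglik["A", ]
  res_tie <- au_pvalue(tie, "A", n_rep = 2000L, seed = 2L)
  expect_lt(abs(res_tie$au - 0.5), 0.1)
  expect_true(all(res_tie$fit$bp_per_scale >= 0 &
                    res_tie$fit$bp_per_scale <= 1))
})

test_that("stat reports rank by AU with likelihood and label tie-breaks", {
  g <- mk_group(rbind(best = rep(-1, 40L), mid = rep(-1.2, 40L),
                      worst = rep(-1.4, 40L)))
  rep1 <- stat_report(g, n_rep = 300L, seed = 4L)
  expect_equal(rep1$strategy[rep1$rank == 1L], "best")
  expect_equal(rep1$delta_lnl[rep1$strategy == "best"], 0)
  expect_true(all(rep1$delta_lnl >= 0))
  expect_equal(sum(rep1$bp), 1)
  expect_true(all(rep1$au >= 0 & rep1$au <= 1))
  expect_setequal(rep1$rank, 1:3)
  single <- mk_group(matrix(-1, 1L, 10L, dimnames = list("only", NULL)))
  rep2 <- stat_report(single, n_rep = 300L, seed = 1L)
  expect_equal(rep2[, c("bp", "au", "rank")],
               data.frame(bp = 1, au = 1, rank = 1L),
               ignore_attr = TRUE)
})

test_that("reports are deterministic given the seed", {
  set.seed(77)
  g <- mk_group(matrix(rnorm(3L * 100L, -2), 3L, 100L,
                       dimnames = list(c("a", "b", "c"), NULL)))
  r1 <- stat_report(g, n_rep = 500L, seed = 42L)
  r2 <- stat_report(g, n_rep = 500L, seed = 42L)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(r1, f1, row.names = FALSE)
  write.csv(r2, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a uniform per-site boost never hurts a strategy at fixed seed", {
  set.seed(8)
  base <- matrix(rnorm(3L * 200L, -2), 3L, 200L,
                 dimnames = list(c("a", "b", "c"), NULL))
  r0 <- suppressWarnings(stat_report(mk_group(base), n_rep = 400L,
                                     seed = 11L))
  boosted <- base
  boosted["b", ] <- boosted["b", ] + 0.05
  r1 <- suppressWarnings(stat_report(mk_group(boosted), n_rep = 400L,
                                     seed = 11L))
  expect_gte(r1$bp[r1$strategy == "b"], r0$bp[r0$strategy == "b"])
  expect_gte(r1$au[r1$strategy == "b"], r0$au[r0$strategy == "b"])
  expect_lte(r1$rank[r1$strategy == "b"], r0$rank[r0$strategy == "b"])
})

test_that("the advantaged strategy's support grows with alignment length", {
  bps <- vapply(c(100L, 1000L, 5000L), function(n) {
    set.seed(n)
    ll <- matrix(rnorm(2L * n, -2), 2L, n,
                 dimnames = list(c("adv", "other"), NULL))
    ll["adv", ] <- ll["adv", ] + 0.1
    rell_bp(mk_group(ll), n_rep = 500L, seed = 1L)[["adv"]]
  }, numeric(1L))
  expect_gte(bps[3L], 0.99)
  expect_lte(bps[1L], bps[3L])
})
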