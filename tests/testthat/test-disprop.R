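test_that("disproportionality formulas match hand computation", {
  ## hand-evaluated examples
  expect_close(ror(contingency_table(2, 10, 1, 100))$point, 20)
  expect_close(prr(contingency_table(2, 98, 1, 99))$point, 2)
  expect_close(rrr(contingency_table(4, 96, 2, 198))$point, 2)
  ## symmetric table: all measures 1, for any cell size
  for (k in c(1, 7, 250)) {
    tab <- contingency_table(k, k, k, k)
    expect_close(ror(tab)$point, 1)
    expect_close(prr(tab)$point, 1)
    expect_equal(rrr(tab)$point, 1, tolerance = 1e-12)
  }
  ## independent-but-asymmetric rows: PRR and RRR exactly 1, ROR 1
  tab <- contingency_table(3, 97, 6, 194)
  expect_close(prr(tab)$point, 1)
  expect_close(rrr(tab)$point, 1)
})

test_that("measures agree with an independent spreadsheet-style oracle", {
  set.seed(7)
  for (i in 1:50) {
    c4 <- sample(1:20, 4, replace = TRUE)
    tab <- contingency_table(c4[1], c4[2], c4[3], c4[4])
    n11 <- c4[1]; n10 <- c4[2]; n01 <- c4[3]; n00 <- c4[4]
    expect_close(ror(tab)$point, (n11 / n10) / (n01 / n00))
    expect_close(prr(tab)$point,
                 (n11 / (n11 + n10)) / (n01 / (n01 + n00)))
    expect_close(rrr(tab)$point,
                 (n11 / (n11 + n10)) / ((n11 + n01) / sum(c4)))
    ## Woolf interval, reconstructed from scratch
    r <- ror(tab)
    se <- sqrt(sum(1 / c4))
    expect_close(r$ci_low, r$point * exp(-qnorm(0.975) * se), 1e-10)
    expect_close(r$ci_high, r$point * exp(qnorm(0.975) * se), 1e-10)
  }
})

test_that("zero cells yield flagged undefined estimates, not corrections", {
  tab <- contingency_table(0, 10, 5, 100)
  for (f in list(ror, prr, rrr)) {
    est <- f(tab)
    expect_false(est$defined)
    expect_true(is.na(est$point))
    expect_match(est$reason, "zero")
  }
  ## weighted (real-valued) cells keep the same formulas
  expect_close(ror(contingency_table(2.0, 10.0, 1.0, 100.0))$point, 20)
})

test_that("tabulate_panel counts patient-months by exposure x event", {
  ## 2 patients x 10 at-risk months; one exposed throughout with one event
  p <- rbind(
    data.table(participant_id = "X", month = 0:9, exp_X = TRUE,
               event = c(rep(FALSE, 9), TRUE)),
    data.table(participant_id = "Y", month = 0:9, exp_X = FALSE,
               event = FALSE))
  tab <- tabulate_panel(p, "X")
  expect_equal(c(tab$n11, tab$n10, tab$n01, tab$n00), c(1, 9, 0, 10))
  ## all weights 1 equals unweighted; doubling weights doubles cells but
  ## leaves ratio measures unchanged
  tw <- tabulate_panel(p, "X", weights = rep(1, 20))
  expect_identical(unlist(tw[1:4]), unlist(tab[1:4]))
  t2 <- tabulate_panel(p, "X", weights = rep(2, 20))
  expect_equal(t2$n10, 2 * tab$n10)
  ## ratio measures are scale-invariant (RRR is defined here; PRR/ROR have a
  ## zero n01 cell in this fixture and stay flagged undefined)
  expect_close(rrr(t2)$point, rrr(tab)$point)
  expect_false(prr(t2)$defined)
  expect_error(tabulate_panel(p[0], "X"), "empty")
})

test_that("PRR equals IRR exactly on random panels, weighted or not", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_panel(25, 18)
    tab <- tabulate_panel(p, "X")
    if (tab$n11 == 0 || tab$n01 == 0) next
    a <- prr(tab)$point
    b <- irr_from_panel(p, "X")$point
    g <- irr_from_panel(p, "X", method = "glm")$point
    expect_lt(abs(a - b) / a, 1e-12)
    expect_lt(abs(a - g) / a, 1e-10)
    ## weighted identity
    w <- rexp(nrow(p)) + 0.1
    aw <- prr(tabulate_panel(p, "X", weights = w))$point
    gw <- irr_from_panel(p, "X", weights = w, method = "glm")$point
    expect_lt(abs(aw - gw) / aw, 1e-8)
  }
})

test_that("undefined IRR is flagged when a margin is empty", {
  p <- data.table(participant_id = sprintf("p%d", 1:10), month = 0L,
                  exp_X = rep(c(TRUE, FALSE), 5), event = FALSE)
  est <- irr_from_panel(p, "X")
  expect_false(est$defined)
})

test_that("rare-event measures are nearly identical", {
  set.seed(23)
  for (i in 1:50) {
    ## prevalence < 1%
    n1 <- sample(2000:6000, 1); n0 <- sample(5000:20000, 1)
    p1 <- runif(1, 1e-4, 0.009); p0 <- runif(1, 1e-4, 0.009)
    n11 <- rbinom(1, n1, p1); n01 <- rbinom(1, n0, p0)
    if (n11 == 0 || n01 == 0) next
    tab <- contingency_table(n11, n1 - n11, n01, n0 - n01)
    expect_lt(abs(log(ror(tab)$point) - log(prr(tab)$point)), 0.05)
  }
})
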