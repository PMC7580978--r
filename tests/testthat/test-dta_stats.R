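test_that("2x2 construction counts paired indicators", {
  t <- build_two_by_two(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]), c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  t0 <- build_two_by_two(rep(FALSE, 5), rep(FALSE, 5))
  expect_equal(t0$tn, 5L)
  expect_error(build_two_by_two(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("accuracy metrics reproduce the published PCT dichotomization", {
  m_any <- dta_metrics(two_by_two(59, 71, 6, 47))
  expect_equal(round(unname(m_any$sensitivity["est"]), 3), 0.908)
  expect_equal(round(unname(m_any$specificity["est"]), 3), 0.398)
  expect_equal(round(unname(m_any$ppv["est"]), 3), 0.454)
  expect_equal(round(unname(m_any$npv["est"]), 3), 0.887)

  m_acc <- dta_metrics(two_by_two(47, 83, 2, 51))
  expect_equal(round(unname(m_acc$sensitivity["est"]), 3), 0.959)
  expect_equal(round(unname(m_acc$specificity["est"]), 3), 0.381)
  expect_equal(round(unname(m_acc$ppv["est"]), 3), 0.362)
  expect_equal(round(unname(m_acc$npv["est"]), 3), 0.962)

  perfect <- dta_metrics(two_by_two(10, 0, 0, 20))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(unname(perfect[[m]]["est"]), 1.0)
  }
})

test_that("undefined metrics are NA while the rest are computed", {
  m <- dta_metrics(two_by_two(0, 0, 3, 7))  # never test-positive: PPV undefined
  expect_true(is.na(m$ppv["est"]))
  expect_equal(unname(m$specificity["est"]), 1.0)
})

test_that("exact binomial intervals match the binom.test oracle", {
  cases <- expand.grid(x = c(0, 1, 5, 47, 53), n = c(53, 130, 500))
  cases <- cases[cases$x <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; n <- cases$n[i]
    ours <- triplef:::clopper_pearson(x, n, 0.95)
    ref <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(ours["lo"]), ref[1], tolerance = 1e-9)
    expect_equal(unname(ours["hi"]), ref[2], tolerance = 1e-9)
  }
})

test_that("every interval contains its point estimate and narrows with n", {
  for (method in c("clopper-pearson", "wilson")) {
    m_small <- dta_metrics(two_by_two(8, 4, 2, 6), ci_method = method)
    m_big <- dta_metrics(two_by_two(80, 40, 20, 60), ci_method = method)
    for (metric in c("sensitivity", "specificity", "ppv", "npv")) {
      s <- m_small[[metric]]; b <- m_big[[metric]]
      expect_true(s["lo"] <= s["est"] && s["est"] <= s["hi"])
      expect_lt(b["hi"] - b["lo"], s["hi"] - s["lo"])
    }
  }
})

test_that("Youden's index is sensitivity + specificity - 1", {
  t <- two_by_two(59, 71, 6, 47)
  expect_equal(round(youden_index(t), 3), 0.306)
  m <- dta_metrics(t)
  expect_equal(youden_index(t),
               unname(m$sensitivity["est"] + m$specificity["est"] - 1))
  expect_equal(youden_index(two_by_two(10, 0, 0, 10)), 1.0)
  expect_equal(youden_index(two_by_two(5, 5, 5, 5)), 0.0)
  expect_error(youden_index(two_by_two(0, 3, 0, 7)), "undefined")
})

test_that("Youden cutoff selection matches a brute-force threshold scan", {
  sep <- select_youden_cutoff(c(0.1, 0.2, 0.9, 1.4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$cutoff, 0.9)
  expect_equal(sep$youden_j, 1.0)

  brute <- function(values, cond) {
    thrs <- c(sort(unique(values)), Inf)
    js <- vapply(thrs, function(th) {
      pos <- values >= th
      sum(pos & cond) / sum(cond) + sum(!pos & !cond) / sum(!cond) - 1
    }, numeric(1))
    list(cutoff = thrs[which.max(js)], youden_j = max(js))
  }
  withr::with_seed(7, {
    for (rep in 1:25) {
      n <- sample(5:200, 1)
      cond <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      values <- round(stats::rlnorm(n, meanlog = cond * 0.8, sdlog = 1), 2)
      got <- select_youden_cutoff(values, cond)
      want <- brute(values, cond)
      expect_equal(got$youden_j, want$youden_j, tolerance = 1e-9)
      # the selected cutoff attains the brute-force maximum (ties may be
      # broken at different but equally optimal thresholds up to rounding)
      pos <- values >= got$cutoff
      j_at <- sum(pos & cond) / sum(cond) + sum(!pos & !cond) / sum(!cond) - 1
      expect_equal(j_at, want$youden_j, tolerance = 1e-9)
    }
  })
})

test_that("tied Youden maxima resolve to the smallest threshold", {
  # thresholds 2 and 4 both give J = 0.5; the smaller must win
  values <- c(1, 2, 3, 4)
  cond <- c(FALSE, TRUE, FALSE, TRUE)
  brute_j <- function(th) {
    pos <- values >= th
    sum(pos & cond) / 2 + sum(!pos & !cond) / 2 - 1
  }
  expect_equal(brute_j(2), brute_j(4))
  got <- select_youden_cutoff(values, cond)
  expect_equal(got$youden_j, 0.5)
  expect_equal(got$cutoff, 2)
  expect_error(select_youden_cutoff(1:4, rep(TRUE, 4)), "both")
})

test_that("Cohen's kappa matches the hand formula and the e1071 oracle", {
  expect_equal(cohens_kappa(two_by_two(10, 0, 0, 20))$kappa, 1.0)
  expect_equal(cohens_kappa(two_by_two(50, 50, 50, 50))$kappa, 0.0)

  hand <- function(t) {
    n <- t$tp + t$fp + t$fn + t$tn
    po <- (t$tp + t$tn) / n
    pe <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / n^2
    (po - pe) / (1 - pe)
  }
  withr::with_seed(11, {
    for (rep in 1:30) {
      t <- do.call(two_by_two, as.list(sample(0:40, 4, replace = TRUE) + c(1, 0, 0, 1)))
      got <- cohens_kappa(t)
      expect_equal(got$kappa, hand(t), tolerance = 1e-12)
      expect_true(got$conf_lo <= got$kappa && got$kappa <= got$conf_hi)
      mat <- matrix(c(t$tp, t$fn, t$fp, t$tn), 2)
      expect_equal(got$kappa, e1071::classAgreement(mat)$kappa, tolerance = 1e-12)
    }
  })

  degenerate <- cohens_kappa(two_by_two(5, 0, 0, 0))
  expect_true(is.na(degenerate$kappa))
})
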