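# Error summary and the Jonckheere-Terpstra trend test, checked against
# independent brute-force oracles.

# independent JT statistic: plain double loop over all cross-group pairs
jtBrute <- function(groups) {
  jt <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (a in groups[[i]]) for (b in groups[[j]])
      jt <- jt + (a < b) + 0.5 * (a == b)
  jt
}

# independent exact p-value: enumerate every distinct assignment of the
# pooled values to the group sizes via unique label permutations
jtBruteExact <- function(groups) {
  sizes <- vapply(groups, length, 1L)
  pooled <- unlist(groups)
  obs <- jtBrute(groups)
  labs <- rep(seq_along(sizes), sizes)
  perms <- list()
  gen <- function(remaining, acc) {
    if (!length(remaining)) {
      perms[[length(perms) + 1L]] <<- acc
      return(invisible())
    }
    for (u in unique(remaining)) {
      idx <- which(remaining == u)[1]
      gen(remaining[-idx], c(acc, u))
    }
  }
  gen(labs, integer(0))
  stats <- vapply(perms, function(p) {
    jtBrute(split(pooled, factor(p, levels = seq_along(sizes))))
  }, 1)
  mean(stats >= obs - 1e-9)
}

test_that("error summary: hand-computed mean/sd and the n < 2 guard", {
  s <- errorSummary(c(0, 0, 0))
  expect_equal(s, list(mean = 0, sd = 0, n = 3L))
  s2 <- errorSummary(c(0.1, -0.1))
  expect_equal(s2$mean, 0)
  expect_equal(s2$sd, sqrt(0.02), tolerance = 1e-12)
  expect_error(errorSummary(0.5), "at least 2")
})

test_that("textbook case: groups [1,2] vs [3,4] give JT = 4, p = 1/6", {
  ht <- jonckheereTerpstra(list(c(1, 2), c(3, 4)))
  expect_equal(unname(ht$statistic), 4)
  expect_equal(ht$p.value, 1 / 6)
  expect_match(ht$method, "exact")
})

test_that("exact mode matches the brute-force oracle across configurations", {
  set.seed(81)
  configs <- list(c(2, 2), c(3, 3), c(2, 3, 4), c(3, 3, 3), c(4, 5),
                  c(2, 2, 2, 3))
  for (sizes in configs) {
    for (rep in 1:2) {
      vals <- if (rep == 1) rnorm(sum(sizes))
              else sample(1:3, sum(sizes), TRUE)  # heavy ties
      groups <- split(vals, rep(seq_along(sizes), sizes))
      ht <- jonckheereTerpstra(unname(groups), exact = TRUE)
      expect_equal(unname(ht$statistic), jtBrute(groups))
      expect_equal(ht$p.value, jtBruteExact(groups), tolerance = 1e-12)
    }
  }
})

test_that("degenerate all-ties data sit at the null mean with p = 1", {
  groups <- list(rep(2, 3), rep(2, 3), rep(2, 3))
  ht <- jonckheereTerpstra(groups)
  n <- 9; sizes <- c(3, 3, 3)
  expect_equal(unname(ht$statistic), (n^2 - sum(sizes^2)) / 4)
  expect_equal(ht$p.value, 1)
  htN <- jonckheereTerpstra(groups, exact = FALSE)
  expect_equal(htN$p.value, 1)
})

test_that("reversing the group order reflects JT about the pair count", {
  set.seed(82)
  groups <- list(rnorm(4), rnorm(3), rnorm(5))
  jt <- unname(jonckheereTerpstra(groups, exact = FALSE)$statistic)
  jtR <- unname(jonckheereTerpstra(rev(groups), exact = FALSE)$statistic)
  total <- 4 * 3 + 4 * 5 + 3 * 5
  expect_equal(jt + jtR, total)
})

test_that("normal approximation tracks the exact p at n = 9 and n = 12", {
  set.seed(83)
  for (sizes in list(c(3, 3, 3), c(3, 4, 5))) {
    vals <- rnorm(sum(sizes)) + rep(c(0, 0.8, 1.6), sizes)
    groups <- split(vals, rep(seq_along(sizes), sizes))
    pe <- jonckheereTerpstra(unname(groups), exact = TRUE)$p.value
    pn <- jonckheereTerpstra(unname(groups), exact = FALSE)$p.value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("input validation: single or empty groups are rejected", {
  expect_error(jonckheereTerpstra(list(1:3)), "at least 2")
  expect_error(jonckheereTerpstra(list(1:3, numeric(0))), "non-empty")
})

test_that("rank trend report emits JSON and a plot", {
  set.seed(84)
  g <- c(rnorm(6, 0.05), rnorm(6, 0.2), rnorm(6, 0.45))
  r <- rep(1:3, each = 6)
  jp <- tempfile(fileext = ".json"); pp <- tempfile(fileext = ".png")
  out <- rankTrendReport(g, r, jsonPath = jp, plotPath = pp)
  expect_true(file.exists(jp) && file.exists(pp))
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$JT, out$JT)
  expect_equal(unname(j$group_ns), c(6, 6, 6))
})
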