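## Evaluation statistics: same-day error summary and the Jonckheere-Terpstra
## ordered-alternative trend test (exact permutation for small samples,
## tie-corrected normal approximation otherwise).

#' Mean / standard deviation summary of growth rates
#'
#' @param growthRates numeric vector (n >= 2).
#' @return list with `mean`, `sd` (sample, n-1 denominator) and `n`.
#' @export
errorSummary <- function(growthRates) {
  growthRates <- growthRates[is.finite(growthRates)]
  n <- length(growthRates)
  if (n < 2) stop("need at least 2 growth rates (sd undefined)")
  list(mean = mean(growthRates), sd = stats::sd(growthRates), n = n)
}

## JT statistic: sum over ordered group pairs of Mann-Whitney counts
## #(x_i < x_j) + 0.5 #(x_i = x_j)
.jtStatistic <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    jt <- jt + sum(outer(groups[[i]], groups[[j]], "<")) +
      0.5 * sum(outer(groups[[i]], groups[[j]], "=="))
  }
  jt
}

## exhaustive permutation distribution by recursive assignment of the pooled
## values to groups of the observed sizes; returns P(JT >= observed)
.jtExactPvalue <- function(pooled, sizes, observed, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  n <- length(pooled)
  L <- outer(pooled, pooled, "<") + 0.5 * outer(pooled, pooled, "==")
  count <- 0; total <- 0
  rec <- function(S, si, acc) {
    if (si == length(sizes)) {  # last group forced
      total <<- total + 1
      hit <- if (tail == "ge") acc >= observed - 1e-9
             else acc <= observed + 1e-9
      if (hit) count <<- count + 1
      return(invisible())
    }
    cmb <- utils::combn(S, sizes[si], simplify = FALSE)
    for (G in cmb) {
      R <- setdiff(S, G)
      rec(R, si + 1, acc + sum(L[G, R, drop = FALSE]))
    }
  }
  rec(seq_len(n), 1, 0)
  count / total
}

.jtArrangements <- function(sizes) {
  n <- sum(sizes)
  exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' Tests for a monotone trend of a response across groups given in a stated
#' order (here: clinician ranks 1 < 2 < 3). The statistic is the sum of
#' pairwise Mann-Whitney counts `#(x_i < x_j) + 0.5 #(x_i = x_j)` over group
#' pairs i < j. The p-value is computed by exhaustive permutation when the
#' pooled sample size allows (`exact = NULL` auto-selects n <= 10), else by
#' normal approximation with tie-corrected variance.
#'
#' @param groups list of numeric vectors, in increasing hypothesised order.
#' @param alternative "increasing" (default, the direction of a worsening
#'   trend with rank), "decreasing" or "two.sided".
#' @param exact force (`TRUE`) or suppress (`FALSE`) the permutation mode;
#'   `NULL` auto-selects it for pooled n <= 10.
#' @param continuity apply a 0.5 continuity correction in the normal mode
#'   (off by default).
#' @return an object of class `"htest"`.
#' @examples
#' jonckheereTerpstra(list(c(1, 2), c(3, 4)))  # JT = 4, exact p = 1/6
#' @export
jonckheereTerpstra <- function(groups, alternative = c("increasing",
                                                       "decreasing",
                                                       "two.sided"),
                               exact = NULL, continuity = FALSE) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 2)
    stop("need an ordered list of at least 2 groups")
  if (any(!vapply(groups, length, 1L)))
    stop("all groups must be non-empty")
  sizes <- vapply(groups, length, 1L)
  n <- sum(sizes)
  jt <- .jtStatistic(groups)
  pooled <- unlist(groups)

  useExact <- if (is.null(exact)) n <= 10 else isTRUE(exact)
  if (useExact && .jtArrangements(sizes) > 2e5) useExact <- FALSE

  if (useExact) {
    method <- "Jonckheere-Terpstra trend test (exact permutation)"
    p <- switch(alternative,
      increasing = .jtExactPvalue(pooled, sizes, jt, "ge"),
      decreasing = .jtExactPvalue(pooled, sizes, jt, "le"),
      two.sided = min(1, 2 * min(.jtExactPvalue(pooled, sizes, jt, "ge"),
                                 .jtExactPvalue(pooled, sizes, jt, "le"))))
  } else {
    method <- "Jonckheere-Terpstra trend test (normal approximation)"
    mu <- (n^2 - sum(sizes^2)) / 4
    tj <- table(pooled)
    A <- n * (n - 1) * (2 * n + 5) -
      sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
      sum(tj * (tj - 1) * (2 * tj + 5))
    B <- sum(sizes * (sizes - 1) * (sizes - 2)) *
      sum(tj * (tj - 1) * (tj - 2))
    C <- sum(sizes * (sizes - 1)) * sum(tj * (tj - 1))
    v <- A / 72 + B / (36 * n * (n - 1) * (n - 2)) + C / (8 * n * (n - 1))
    if (v <= 0) {
      p <- 1
      z <- 0
    } else {
      cc <- if (continuity) 0.5 * sign(jt - mu) else 0
      z <- (jt - mu - cc) / sqrt(v)
      p <- switch(alternative,
        increasing = stats::pnorm(z, lower.tail = FALSE),
        decreasing = stats::pnorm(z),
        two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    }
  }
  structure(list(statistic = c(JT = jt),
                 parameter = c(n = n, groups = length(groups)),
                 p.value = min(1, p),
                 alternative = alternative,
                 method = method,
                 data.name = deparse(substitute(groups))),
            class = "htest")
}

#' Read pair_id / growth_rate / rank records from CSV
#'
#' @param path CSV with columns `pair_id`, `growth_rate`, `rank`
#'   (rank in 1..3: 1 approximately the same, 2 slightly worse,
#'   3 much worse).
#' @return data.frame with validated columns.
#' @export
readRankedGrowth <- function(path) {
  d <- utils::read.csv(path)
  need <- c("pair_id", "growth_rate", "rank")
  if (!all(need %in% names(d)))
    stop("CSV must have columns ", paste(need, collapse = ","))
  if (!all(d$rank %in% 1:3)) stop("rank must be 1, 2 or 3")
  d
}

#' Run the trend test on ranked growth rates, with JSON/plot output
#'
#' @param growthRates numeric vector.
#' @param ranks integer vector in 1..3, same length.
#' @param jsonPath optional path for a JSON summary
#'   (JT, p, method, group sizes/means/sds).
#' @param plotPath optional PNG path for the box/scatter plot by rank.
#' @param ... passed to [jonckheereTerpstra()].
#' @return the summary list, invisibly.
#' @export
rankTrendReport <- function(growthRates, ranks, jsonPath = NULL,
                            plotPath = NULL, ...) {
  stopifnot(length(growthRates) == length(ranks), all(ranks %in% 1:3))
  groups <- split(growthRates, factor(ranks, levels = sort(unique(ranks))))
  ht <- jonckheereTerpstra(unname(groups), ...)
  out <- list(JT = unname(ht$statistic), p = ht$p.value, method = ht$method,
              group_ns = vapply(groups, length, 1L),
              group_means = vapply(groups, mean, 1),
              group_sds = vapply(groups, stats::sd, 1))
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(plotPath)) {
    grDevices::png(plotPath, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    graphics::boxplot(growthRates ~ ranks, xlab = "Rank",
                      ylab = "Growth rate", outline = FALSE,
                      main = sprintf("JT = %.1f, p = %.3g", out$JT, out$p))
    graphics::stripchart(growthRates ~ ranks, vertical = TRUE, add = TRUE,
                         method = "jitter", pch = 19,
                         col = grDevices::adjustcolor("steelblue", 0.7))
  }
  invisible(out)
}
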