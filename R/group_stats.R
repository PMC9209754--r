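#' Student's t-test (one- or two-sample)
#'
#' Thin wrapper over [stats::t.test()] with explicit handling of degenerate
#' zero-variance input, which `t.test` reports as an opaque error.
#'
#' @param x numeric sample (`>= 2` observations).
#' @param y optional second sample; when `NULL` a one-sample test of
#'   `mean(x) == mu` is run.
#' @param mu null value for the one-sample test.
#' @param var_equal pooled-variance (classical Student) two-sample test when
#'   `TRUE`; Welch when `FALSE`.
#' @param alternative as in [stats::t.test()].
#' @return list with elements `t`, `df`, `p`, `estimate`.
#' @export
students_t <- function(x, y = NULL, mu = 0, var_equal = FALSE,
                       alternative = "two.sided") {
  if (length(x) < 2L || (!is.null(y) && length(y) < 2L))
    stop_("each sample needs at least 2 observations")
  if (stats::sd(x) == 0 && (is.null(y) || stats::sd(y) == 0))
    stop_("degenerate input: zero variance in every sample")
  tt <- if (is.null(y))
    stats::t.test(x, mu = mu, alternative = alternative)
  else
    stats::t.test(x, y, var.equal = var_equal, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, estimate = unname(if (is.null(y)) tt$estimate
                                         else diff(rev(tt$estimate))))
}

#' Dunnett's many-to-one comparison against a control
#'
#' Compares each treatment group with the single control group, adjusting
#' p-values through the joint multivariate-t distribution of the test
#' statistics (correlation `rho_jl = sqrt(n_j n_l / ((n_j + n_0)(n_l +
#' n_0)))`, equicorrelated for balanced designs). The pooled error variance
#' uses all groups including the control; `df = N - k - 1`.
#'
#' The multivariate-t probability is evaluated with [mvtnorm::pmvt()]
#' (randomised quasi-Monte-Carlo); the RNG state is fixed locally so repeat
#' calls are reproducible to the algorithm's reported error (~1e-4).
#'
#' @param groups named list of numeric treatment samples.
#' @param control numeric control sample.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return data frame: `group`, `estimate` (treatment mean minus control
#'   mean), `t`, `df`, `p_raw`, `p_adj`.
#' @export
dunnett_test <- function(groups, control, alternative = "two.sided") {
  if (!is.list(groups) || length(groups) < 1L)
    stop_("`groups` must be a non-empty list of samples")
  if (length(control) < 2L) stop_("control sample needs >= 2 observations")
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop_("every group needs >= 2 observations")
  n0 <- length(control)
  all_s <- c(list(control), groups)
  sse <- sum(vapply(all_s, function(v) sum((v - mean(v))^2), 0))
  df <- sum(vapply(all_s, length, 1L)) - (k + 1L)
  mse <- sse / df
  if (mse == 0) stop_("degenerate input: zero pooled error variance")
  est <- vapply(groups, mean, 0) - mean(control)
  tstat <- est / sqrt(mse * (1 / n + 1 / n0))
  lam <- sqrt(n / (n + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_raw <- switch(alternative,
    two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
    greater   = stats::pt(tstat, df, lower.tail = FALSE),
    less      = stats::pt(tstat, df))
  p_adj <- vapply(seq_len(k), function(j) {
    if (k == 1L) return(p_raw[j])
    b <- abs(tstat[j])
    pr <- withr_seed(1L, {
      if (alternative == "two.sided")
        mvtnorm::pmvt(lower = rep(-b, k), upper = rep(b, k),
                      df = df, corr = corr)
      else
        mvtnorm::pmvt(lower = rep(-Inf, k), upper = rep(b, k),
                      df = df, corr = corr)
    })
    max(0, 1 - as.numeric(pr))
  }, 0)
  p_adj <- pmax(p_adj, p_raw)  # adjustment can never make a p smaller
  data.frame(group = names(groups), estimate = unname(est),
             t = unname(tstat), df = df, p_raw = unname(p_raw),
             p_adj = unname(p_adj), row.names = NULL)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
#' @noRd
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Duncan's least-significant-range quantile
#'
#' Duncan's special studentized-range quantile for a span of `p` means is
#' obtained from the ordinary studentized-range quantile at the protection
#' level `alpha_p = 1 - (1 - alpha)^(p - 1)`.
#'
#' @param alpha nominal per-comparison level.
#' @param p span (number of means covered, `>= 2`).
#' @param df error degrees of freedom.
#' @return the critical studentized range.
#' @export
duncan_q <- function(alpha, p, df) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  stats::qtukey(1 - alpha_p, nmeans = p, df = df)
}

#' Duncan's multiple range test with significance letters
#'
#' Ranks group means and compares every pair against the least significant
#' range for the span separating them in rank order, `LSR_p = q'(alpha, p,
#' df) * sqrt(MSE / n)`, where `q'` is Duncan's protected studentized-range
#' quantile ([duncan_q()]). A pair is declared homogeneous when any rank
#' interval containing both means has a range not exceeding its LSR (the
#' classical stepwise protection rule). Maximal homogeneous stretches are
#' labelled with letters; for two groups the procedure reduces to the LSD
#' t-test.
#'
#' Unbalanced designs use the harmonic mean of the group sizes in the LSR.
#'
#' @param groups named list of numeric samples (each `>= 2` observations).
#' @param alpha significance level.
#' @return object of class `duncan_mrt`: list with `means` (data frame
#'   `group`, `mean`, `n`, `letters`, sorted by descending mean), `lsr`
#'   (named vector by span), `mse`, `df`, `alpha`.
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop_("every group needs >= 2 replicates")
  k <- length(groups)
  sse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df <- sum(n) - k
  mse <- sse / df
  if (mse == 0) stop_("degenerate input: zero within-group variance")
  n_h <- k / sum(1 / n)
  lsr <- vapply(2:k, function(p) duncan_q(alpha, p, df) * sqrt(mse / n_h), 0)
  names(lsr) <- as.character(2:k)
  m <- vapply(groups, mean, 0)
  ord <- order(m, decreasing = TRUE)
  ms <- m[ord]
  blocks <- range_blocks(ms, lsr)
  letters_ <- letters_from_blocks(blocks, k)
  out <- data.frame(group = names(ms), mean = unname(ms),
                    n = unname(n[ord]), letters = letters_,
                    row.names = NULL)
  structure(list(means = out, lsr = lsr, mse = mse, df = df, alpha = alpha),
            class = "duncan_mrt")
}

# Inclusion-maximal rank intervals whose range does not exceed the LSR for
# their span, given means sorted in decreasing order. Singletons not inside
# any such interval become their own block.
#' @noRd
range_blocks <- function(ms, lsr) {
  k <- length(ms)
  ns <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    span <- j - i + 1L
    if (ms[i] - ms[j] <= lsr[[as.character(span)]])
      ns[[length(ns) + 1L]] <- c(i, j)
  }
  if (length(ns)) {
    keep <- vapply(seq_along(ns), function(a) {
      !any(vapply(seq_along(ns), function(b) {
        b != a && ns[[b]][1L] <= ns[[a]][1L] && ns[[b]][2L] >= ns[[a]][2L]
      }, TRUE))
    }, TRUE)
    ns <- ns[keep]
  }
  covered <- rep(FALSE, k)
  for (iv in ns) covered[iv[1L]:iv[2L]] <- TRUE
  for (i in which(!covered)) ns[[length(ns) + 1L]] <- c(i, i)
  ns[order(vapply(ns, `[`, 1L, 1L), vapply(ns, `[`, 1L, 2L))]
}

#' @noRd
letters_from_blocks <- function(blocks, k) {
  lab <- rep("", k)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]][1L]:blocks[[b]][2L]
    lab[idx] <- paste0(lab[idx], LETTERS[b])
  }
  lab
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat("Duncan's multiple range test (alpha = ", x$alpha, ", df = ", x$df,
      ", MSE = ", signif(x$mse, 4), ")\n", sep = "")
  print(x$means, row.names = FALSE)
  invisible(x)
}
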