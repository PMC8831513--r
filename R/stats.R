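# Paired nonparametric comparisons used to summarize sweeps: threshold
# power / optimal Intralipid across conditions (Friedman), eligibility
# between planning strategies (Wilcoxon signed-rank). Thin, convention-
# pinning wrappers over the base R tests.

#' Friedman test across simulation conditions
#'
#' Rank-based comparison of a blocks-by-treatments matrix (e.g. threshold
#' power per geometry across `mu_a_wall` values), with tie-corrected ranks.
#' By default the p-value uses the asymptotic chi-square approximation
#' (via [stats::friedman.test()]); `p_method = "exact"` enumerates all
#' within-block rank permutations (feasible for small tables, at most
#' `factorial(k)^b <= 1e6` orderings) and reports the exact permutation
#' p-value of the chi-square-form statistic. A matrix with no rank
#' variation in any block (all treatments identical) is degenerate: the
#' statistic is 0 and p = 1, with a warning.
#'
#' @param y numeric matrix, rows = blocks (geometries), columns =
#'   treatments (conditions); >= 2 of each.
#' @param p_method `"asymptotic"` (default) or `"exact"`.
#' @return list with `statistic`, `p.value`, `df`, and `method` (records
#'   which approximation produced the p-value).
#' @export
friedman_test <- function(y, p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  y <- as.matrix(y)
  b <- nrow(y); k <- ncol(y)
  if (b < 2 || k < 2)
    stop("need at least 2 blocks and 2 treatments")
  ranks <- t(apply(y, 1, rank))
  if (all(apply(ranks, 1, stats::var) == 0)) {
    warning("degenerate test: no rank variation in any block; p = 1")
    return(list(statistic = 0, p.value = 1, df = k - 1,
                method = "Friedman rank sum test (degenerate: all tied)"))
  }
  if (p_method == "asymptotic") {
    ft <- stats::friedman.test(y)
    list(statistic = unname(ft$statistic), p.value = ft$p.value,
         df = unname(ft$parameter),
         method = "Friedman rank sum test (asymptotic chi-square)")
  } else {
    if (factorial(k)^b > 1e6)
      stop("exact enumeration infeasible for this table size")
    stat_of <- function(r) {
      # tie-corrected chi-square-form statistic, as friedman.test computes
      cs <- colSums(r)
      num <- (12 * sum((cs - b * (k + 1) / 2)^2))
      tie <- sum(apply(r, 1, function(x) {
        t <- table(x); sum(t^3 - t)
      }))
      num / (b * k * (k + 1) - tie / (k - 1))
    }
    observed <- stat_of(ranks)
    perms <- asplit(permutations_of(k), 1)
    grid <- expand.grid(rep(list(seq_along(perms)), b))
    stats_all <- apply(grid, 1, function(sel) {
      r <- do.call(rbind, lapply(seq_len(b), function(i) perms[[sel[i]]]))
      stat_of(r)
    })
    p <- mean(stats_all >= observed - 1e-12)
    list(statistic = observed, p.value = p, df = k - 1,
         method = "Friedman rank sum test (exact permutation enumeration)")
  }
}

# all permutations of 1..k as rows
permutations_of <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}

#' Wilcoxon signed-rank test on paired outcomes
#'
#' Paired comparison (e.g. per-geometry eligibility under two planning
#' strategies) via [stats::wilcox.test()] with `paired = TRUE`. The exact
#' distribution is used when feasible (n < 50, no ties or zero
#' differences), otherwise the normal approximation with continuity
#' correction; `method` records which. All-zero differences are
#' degenerate: statistic 0, p = 1, with a warning.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @param exact force the exact distribution (`TRUE`/`FALSE`), or `NULL`
#'   to let feasibility decide.
#' @return list with `statistic` (V), `p.value`, and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided",
                                 exact = NULL) {
  if (length(x) != length(y)) stop("paired lists must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (all(d == 0)) {
    warning("degenerate test: all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1,
                method = "Wilcoxon signed rank test (degenerate: all tied)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, paired = TRUE, alternative = alternative, exact = exact))
  used_exact <- grepl("exact", wt$method, ignore.case = TRUE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = paste0("Wilcoxon signed rank test (",
                       if (used_exact) "exact"
                       else "normal approximation with continuity correction",
                       ")"))
}
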